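#' Simulation configuration
#'
#' Collects every knob of the synthetic-data generator in one validated
#' object.  The defaults emulate the study design the pipeline was built for:
#' a parental B-cell line plus two clones carrying a tetracycline-inducible
#' dominant-negative IkBa, stimulated for 0/1/4 h with two biological
#' replicates per condition, negative-binomial counts with log-normal
#' library-size factors, replicate ChIP peak sets for RELA and Pol II,
#' Pol II PET interaction clusters, and 1-kb promoter sequences for human
#' plus six ortholog species.
#'
#' @param n_genes number of genes to simulate.
#' @param class_probs named probabilities for the true per-gene class, in the
#'   order `Ad` (direct activated), `Ai` (indirect activated), `Rd` (direct
#'   repressed), `Ri` (indirect repressed), `nonfunctional_bound`,
#'   `unaffected`.  Must sum to 1.
#' @param times stimulation time points in hours.
#' @param n_replicates biological replicates per design cell.
#' @param nb_dispersion negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2).  `0` gives Poisson counts.
#' @param base_mean_log_range range (natural log scale) of per-gene baseline
#'   mean counts.
#' @param libsize_sdlog sd (log scale) of the log-normal library-size factors.
#' @param induction_fold_range range of the per-gene planted induction
#'   (or repression) fold.
#' @param tet_knockdown fraction of the induced component removed by the
#'   dominant-negative perturbation in `+Tet` samples (1 = complete block,
#'   i.e. no induction under Tet).
#' @param noise `"nb"` for stochastic counts, `"deterministic"` for
#'   noise-free counts equal to rounded expected means (library factors 1);
#'   the configuration used for exact truth-recovery checks.
#' @param replicate_reproducibility probability that a planted peak present in
#'   replicate A is also emitted in replicate B.
#' @param planted_score_range,decoy_score_range uniform score ranges for
#'   planted and decoy peaks (the reproducibility filter thresholds at 100).
#' @param peak_width_range uniform range of simulated peak widths (bp).
#' @param n_decoy_peaks number of decoy intergenic peaks per factor/time
#'   (per replicate, placed independently).
#' @param decoys logical; emit decoy peaks and decoy PET clusters at all.
#' @param loop_category_probs named probabilities for the true loop category
#'   `I` (no Pol II), `II` (promoter Pol II, no loop), `III` (single-gene
#'   loop), `IV` (multi-gene promoter-promoter loop).
#' @param transient_loop_probs loop-category probabilities used instead for
#'   transiently induced direct targets (pattern 3 `Ad` genes), emulating the
#'   enrichment of preformed loops at transient targets.
#' @param pet_count_lambda Poisson rate for planted PET counts above the
#'   minimum of 2.
#' @param n_loop_decoys number of decoy single-count / high-FDR clusters.
#' @param divergence named per-species substitution probabilities for
#'   ortholog promoters.
#' @param site_fate `"neutral"` (planted kB sites mutate like any other
#'   base), `"spare"` (never mutated) or `"destroy"` (site scrambled in the
#'   ortholog while flanks evolve neutrally).
#' @param sites_per_target_range range of planted kB site counts for direct
#'   (Ad/Rd) target promoters.
#' @param gene_length_range,intergenic_gap_range,utr5_range,utr3_range
#'   uniform ranges (bp) used when packing gene models.
#' @param chrom_names chromosome names used for packing.
#' @param chrom_length optional fixed chromosome length; if too small for the
#'   requested genes an informative error is raised.  `NULL` sizes
#'   chromosomes automatically.
#' @param seed integer seed; fixing it fixes every generated byte.
#'
#' @return an object of class `kb_sim_config` (a validated list).
#' @export
sim_config <- function(n_genes = 500,
                       class_probs = c(Ad = 0.06, Ai = 0.10, Rd = 0.02,
                                       Ri = 0.04, nonfunctional_bound = 0.12,
                                       unaffected = 0.66),
                       times = c(0, 1, 4),
                       n_replicates = 2,
                       nb_dispersion = 0.05,
                       base_mean_log_range = c(log(20), log(2000)),
                       libsize_sdlog = 0.2,
                       induction_fold_range = c(4, 12),
                       tet_knockdown = 1,
                       noise = c("nb", "deterministic"),
                       replicate_reproducibility = 1,
                       planted_score_range = c(120, 500),
                       decoy_score_range = c(20, 400),
                       peak_width_range = c(200, 600),
                       n_decoy_peaks = 100,
                       decoys = TRUE,
                       loop_category_probs = c(I = 0.4, II = 0.3,
                                               III = 0.2, IV = 0.1),
                       transient_loop_probs = c(I = 0.05, II = 0.15,
                                                III = 0.65, IV = 0.15),
                       pet_count_lambda = 3,
                       n_loop_decoys = 50,
                       divergence = c(chimpanzee = 0.02, rhesus = 0.06,
                                      cattle = 0.15, dog = 0.15,
                                      mouse = 0.25, rat = 0.25),
                       site_fate = c("neutral", "spare", "destroy"),
                       sites_per_target_range = c(1, 3),
                       gene_length_range = c(2000, 10000),
                       intergenic_gap_range = c(10000, 30000),
                       utr5_range = c(100, 300),
                       utr3_range = c(200, 500),
                       chrom_names = c("chr1", "chr2"),
                       chrom_length = NULL,
                       seed = 1L) {
  noise <- match.arg(noise)
  site_fate <- match.arg(site_fate)
  stopifnot(n_genes >= 1, n_replicates >= 2, nb_dispersion >= 0)
  if (abs(sum(class_probs) - 1) > 1e-8)
    stop("class_probs must sum to 1")
  expected_classes <- c("Ad", "Ai", "Rd", "Ri", "nonfunctional_bound",
                        "unaffected")
  if (!identical(names(class_probs), expected_classes))
    stop("class_probs must be named ", paste(expected_classes, collapse = ", "))
  if (any(class_probs < 0)) stop("class_probs must be non-negative")
  if (abs(sum(loop_category_probs) - 1) > 1e-8 ||
      !identical(names(loop_category_probs), c("I", "II", "III", "IV")))
    stop("loop_category_probs must be named I..IV and sum to 1")
  if (abs(sum(transient_loop_probs) - 1) > 1e-8)
    stop("transient_loop_probs must sum to 1")
  if (replicate_reproducibility < 0 || replicate_reproducibility > 1)
    stop("replicate_reproducibility must be a probability in [0, 1]")
  if (any(divergence < 0 | divergence > 1))
    stop("divergence probabilities must lie in [0, 1]")
  if (!all(times %in% c(0, 1, 4)))
    stop("times must be drawn from {0, 1, 4} hours")
  if (tet_knockdown < 0 || tet_knockdown > 1)
    stop("tet_knockdown must lie in [0, 1]")
  cfg <- list(
    n_genes = as.integer(n_genes),
    class_probs = class_probs,
    times = sort(unique(times)),
    n_replicates = as.integer(n_replicates),
    nb_dispersion = nb_dispersion,
    base_mean_log_range = base_mean_log_range,
    libsize_sdlog = libsize_sdlog,
    induction_fold_range = induction_fold_range,
    tet_knockdown = tet_knockdown,
    noise = noise,
    replicate_reproducibility = replicate_reproducibility,
    planted_score_range = planted_score_range,
    decoy_score_range = decoy_score_range,
    peak_width_range = peak_width_range,
    n_decoy_peaks = as.integer(n_decoy_peaks),
    decoys = isTRUE(decoys),
    loop_category_probs = loop_category_probs,
    transient_loop_probs = transient_loop_probs,
    pet_count_lambda = pet_count_lambda,
    n_loop_decoys = as.integer(n_loop_decoys),
    divergence = divergence,
    site_fate = site_fate,
    sites_per_target_range = sites_per_target_range,
    gene_length_range = gene_length_range,
    intergenic_gap_range = intergenic_gap_range,
    utr5_range = utr5_range,
    utr3_range = utr3_range,
    chrom_names = chrom_names,
    chrom_length = chrom_length,
    seed = as.integer(seed)
  )
  class(cfg) <- "kb_sim_config"
  cfg
}

#' @export
print.kb_sim_config <- function(x, ...) {
  cat("kb_sim_config:", x$n_genes, "genes,",
      length(sim_design(x)$sample), "samples, noise =", x$noise,
      ", seed =", x$seed, "\n")
  invisible(x)
}

#' Experimental design table for a configuration
#'
#' Expands the cell line / Tet / time / replicate design implied by a
#' configuration: the parental line is profiled without Tet only, the two
#' dominant-negative clones with and without Tet.
#'
#' @param config a [sim_config()] object.
#' @return data.frame with columns `sample`, `cell_line`, `tet`, `time`,
#'   `replicate`.
#' @export
sim_design <- function(config) {
  cells <- rbind(
    expand.grid(cell_line = "parental", tet = "minus",
                stringsAsFactors = FALSE),
    expand.grid(cell_line = c("clone1", "clone2"), tet = c("minus", "plus"),
                stringsAsFactors = FALSE)
  )
  des <- merge(merge(cells, data.frame(time = config$times)),
               data.frame(replicate = seq_len(config$n_replicates)))
  des <- des[order(des$cell_line, des$tet, des$time, des$replicate), ]
  des$sample <- sprintf("%s_%s_%gh_r%d", des$cell_line, des$tet,
                        des$time, des$replicate)
  rownames(des) <- NULL
  des[, c("sample", "cell_line", "tet", "time", "replicate")]
}
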