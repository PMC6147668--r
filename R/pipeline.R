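# End-to-end driver: simulate -> peaks -> expression -> classify -> loops
# -> motifs, on either a simulated dataset or user-supplied components.

#' Mean trajectories over time for one condition
#'
#' Per-gene replicate-mean normalized expression at each time point for the
#' selected cell line and Tet arm.  The default median-of-ratios
#' normalization keeps trajectory shapes undistorted when a minority of
#' genes is strongly induced (total-count RPM rescales every time point by
#' the inducible fraction of the library); `norm = "rpm"` gives the
#' depth-per-million view.
#'
#' @param expression a [kb_expression] object.
#' @param cell_line,tet condition selectors.
#' @param norm `"size_factor"` (default) or `"rpm"`.
#' @return matrix genes x time points (columns named by time).
#' @export
mean_trajectories <- function(expression, cell_line = "parental",
                              tet = "minus",
                              norm = c("size_factor", "rpm")) {
  norm <- match.arg(norm)
  s <- expression$samples
  rpm <- if (norm == "rpm") normalize_rpm(expression)
  else sweep(expression$counts, 2, size_factors(expression$counts), `/`)
  times <- sort(unique(s$time))
  out <- sapply(times, function(t) {
    cols <- s$sample[s$cell_line == cell_line & s$tet == tet &
                       s$time == t]
    rowMeans(rpm[, cols, drop = FALSE])
  })
  colnames(out) <- as.character(times)
  out
}

#' Reproducible peak sets for every factor/time present
#'
#' @param peaks simulated or read peak table (with `factor`, `time`,
#'   `replicate` columns; replicates 1 and 2 are filtered against each
#'   other).
#' @param min_score score threshold (default 100).
#' @return named list `"<factor>_<time>h"` of reproducible peak
#'   data.frames.
#' @export
reproducible_peak_sets <- function(peaks, min_score = 100) {
  out <- list()
  for (factor in unique(peaks$factor)) {
    for (time in sort(unique(peaks$time[peaks$factor == factor]))) {
      out[[sprintf("%s_%gh", factor, time)]] <- filter_reproducible(
        peak_subset(peaks, factor, time, 1L),
        peak_subset(peaks, factor, time, 2L),
        min_score = min_score)
    }
  }
  out
}

#' Run the full classification pipeline on a simulated dataset
#'
#' Filters replicate peak sets, assigns inducible RELA peaks to genes,
#' builds the contrast panel, classifies every gene into the target
#' taxonomy, flags robust targets, clusters kinetic patterns within each
#' responsive class, categorizes Pol II loops, and (optionally) scores
#' kB-site conservation for direct activated targets.
#'
#' @param sim a `kb_sim` object from [simulate_dataset()], or a
#'   [sim_config()] (which is simulated first).
#' @param min_score reproducibility score threshold (default 100).
#' @param max_distance peak assignment window (default 50 kb).
#' @param fdr significance cutoff (default 0.05).
#' @param conservation run the per-gene conservation scoring for `Ad`
#'   genes (the slowest step; default TRUE).
#' @param pattern_k clusters per class for pattern labels (default 6;
#'   classes smaller than `2 * pattern_k` genes are left unlabelled).
#' @return object of class `kb_pipeline`: list with `sim`, `repro_peaks`,
#'   `rela_map`, `rela_genes`, `panel`, `taxonomy`, `patterns`, `groups`,
#'   `loop_status`, `loop_kinetics`, `baseline_by_category`,
#'   `conservation`.
#' @export
run_kb_pipeline <- function(sim, min_score = 100, max_distance = 50000,
                            fdr = 0.05, conservation = TRUE,
                            pattern_k = 6) {
  if (inherits(sim, "kb_sim_config")) sim <- simulate_dataset(sim)
  stopifnot(inherits(sim, "kb_sim"))
  gm <- sim$gene_models

  repro <- reproducible_peak_sets(sim$peaks, min_score = min_score)
  inducible <- do.call(rbind, repro[grep("^RELA_[14]h$", names(repro))])
  rela_map <- assign_to_genes(inducible, gm, max_distance = max_distance)
  rela_genes <- unique(rela_map$gene_id)

  panel <- contrast_panel(sim$expression, fdr = fdr)
  tax <- classify_targets(panel, rela_genes, fdr = fdr)
  tax <- robust_flag(tax, panel)

  traj <- mean_trajectories(sim$expression, "parental", "minus")
  assignments <- list()
  for (cls in c("Ad", "Ai", "Rd", "Ri")) {
    members <- tax$gene_id[tax$class == cls]
    sub <- traj[members, , drop = FALSE]
    sub <- sub[apply(sub, 1, stats::sd) > 0, , drop = FALSE]
    if (nrow(sub) >= 2 * pattern_k)
      assignments[[cls]] <- kmeans_patterns(sub, k = pattern_k,
                                            seed = sim$config$seed)$cluster
  }
  tax <- pattern_labels(tax, assignments)
  groups <- combined_pattern_groups(tax, panel, fdr = fdr)

  loops_filt <- filter_pet_clusters(sim$interactions)
  polii0 <- repro[["POLII_0h"]]
  if (is.null(polii0)) polii0 <- filter_reproducible(
    sim$peaks[0, ], sim$peaks[0, ], min_score)
  polii_status <- promoter_polII_status(polii0, gm)
  loop_status <- categorize_loops(gm, loops_filt, polii_status)
  loop_kin <- category_kinetics(loop_status, tax)
  rpm <- normalize_rpm(sim$expression)
  s <- sim$expression$samples
  base_cols <- s$sample[s$time == 0 & s$tet == "minus"]
  baseline <- rowMeans(rpm[, base_cols, drop = FALSE])
  base_kw <- baseline_expression_by_category(loop_status, baseline)

  cons <- NULL
  if (conservation) {
    pwms <- sim$pwm_library
    human <- promoter_seqs(sim$promoters, "human", "conservation")
    ad <- tax$gene_id[tax$class == "Ad"]
    cons <- lapply(setNames(ad, ad), function(gid) {
      sites <- do.call(rbind, lapply(pwms, function(p)
        scan_motif(human[[gid]], p)))
      orth <- lapply(setNames(sim$promoters$species,
                              sim$promoters$species), function(sp)
        promoter_seqs(sim$promoters, sp, "conservation")[[gid]])
      conserved_site_fraction(sites, human[[gid]], orth, pwms)
    })
  }

  out <- list(sim = sim, repro_peaks = repro, rela_map = rela_map,
              rela_genes = rela_genes, panel = panel, taxonomy = tax,
              patterns = assignments, groups = groups,
              loop_status = loop_status, loop_kinetics = loop_kin,
              baseline_by_category = base_kw, conservation = cons)
  class(out) <- "kb_pipeline"
  out
}

#' @export
print.kb_pipeline <- function(x, ...) {
  cat("kb_pipeline over", nrow(x$taxonomy), "genes\n")
  print(table(class = x$taxonomy$class))
  cat("loop categories:\n")
  print(table(x$loop_status$category))
  invisible(x)
}

#' Agreement between a classification and the planted truth
#'
#' @param taxonomy a `kb_taxonomy` object.
#' @param truth truth table from [simulate_truth()].
#' @return fraction of genes whose class equals the planted class.
#' @export
truth_agreement <- function(taxonomy, truth) {
  m <- match(taxonomy$gene_id, truth$gene_id)
  mean(taxonomy$class == truth$true_class[m])
}
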