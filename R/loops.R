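# Loop module: PET-cluster filtering, promoter Pol II status, per-gene loop
# categories I-IV, their relation to kinetics/baseline expression, and the
# length-normalized metagene profile.

.anchor_gr <- function(x, which = c("A", "B")) {
  which <- match.arg(which)
  GenomicRanges::GRanges(x[[paste0("chrom", which)]],
                         IRanges::IRanges(x[[paste0("start", which)]],
                                          x[[paste0("end", which)]]))
}

#' Filter PET interaction clusters
#'
#' Retains clusters with at least `min_count` paired-end tags and
#' `FDR <= max_fdr`.  When the input carries no FDR column, a per-cluster
#' p-value is computed under a marginal-frequency random-ligation binomial
#' model - the expected ligation probability of a cluster is proportional to
#' the product of its two anchors' marginal PET totals over the grand total
#' - and Benjamini-Hochberg corrected.
#'
#' @param interactions interaction data.frame (see [read_bedpe()]).
#' @param min_count minimum PET count (default 2).
#' @param max_fdr FDR cutoff (default 0.05).
#' @return the retained clusters, with `p`/`fdr` filled in when computed.
#' @export
filter_pet_clusters <- function(interactions, min_count = 2,
                                max_fdr = 0.05) {
  x <- interactions
  if (is.null(x$fdr)) {
    grA <- .anchor_gr(x, "A"); grB <- .anchor_gr(x, "B")
    anchors <- GenomicRanges::reduce(c(grA, grB))
    regA <- GenomicRanges::findOverlaps(grA, anchors, select = "first")
    regB <- GenomicRanges::findOverlaps(grB, anchors, select = "first")
    tot <- tapply(c(x$pet_count, x$pet_count), c(regA, regB), sum)
    margA <- as.numeric(tot[as.character(regA)])
    margB <- as.numeric(tot[as.character(regB)])
    n <- sum(x$pet_count)
    prob <- pmin(1, (margA * margB) / n^2)
    x$p <- stats::pbinom(x$pet_count - 1L, n, prob, lower.tail = FALSE)
    x$fdr <- p.adjust(x$p, "BH")
  }
  out <- x[x$pet_count >= min_count & x$fdr <= max_fdr, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fraction of clusters reproduced between replicates
#'
#' The fraction of A-clusters for which some B-cluster overlaps both
#' anchors (anchor A with anchor A, anchor B with anchor B, by at least
#' 1 bp).
#'
#' @param setA,setB filtered interaction data.frames.
#' @return numeric fraction in [0, 1] (`NaN` for an empty A set).
#' @export
replicate_overlap <- function(setA, setB) {
  if (!nrow(setA)) return(NaN)
  if (!nrow(setB)) return(0)
  # disjoint chromosome sets are a legitimate comparison, not a warning
  hitA <- suppressWarnings(
    GenomicRanges::findOverlaps(.anchor_gr(setA, "A"),
                                .anchor_gr(setB, "A")))
  hitB <- suppressWarnings(
    GenomicRanges::findOverlaps(.anchor_gr(setA, "B"),
                                .anchor_gr(setB, "B")))
  keyA <- paste(S4Vectors::queryHits(hitA), S4Vectors::subjectHits(hitA))
  keyB <- paste(S4Vectors::queryHits(hitB), S4Vectors::subjectHits(hitB))
  both <- intersect(keyA, keyB)
  matched <- unique(as.integer(sub(" .*", "", both)))
  length(matched) / nrow(setA)
}

#' Promoter Pol II status at time 0
#'
#' TRUE for genes whose promoter window (TSS-1000..TSS+100, stranded)
#' overlaps at least one reproducible Pol II peak from unstimulated cells.
#'
#' @param polii_peaks reproducible Pol II peak data.frame (already passed
#'   through [filter_reproducible()]).
#' @param gene_models a [kb_genes] object.
#' @return named logical vector over all genes.
#' @export
promoter_polII_status <- function(polii_peaks, gene_models) {
  prom <- promoter_windows(gene_models, "annotation")
  status <- setNames(rep(FALSE, nrow(prom)), prom$gene_id)
  if (nrow(polii_peaks)) {
    promgr <- GenomicRanges::GRanges(prom$chrom,
                                     IRanges::IRanges(prom$start, prom$end))
    hits <- GenomicRanges::countOverlaps(promgr, .peaks_gr(polii_peaks))
    status[] <- hits > 0
  }
  status
}

#' Assign loop categories I-IV
#'
#' A cluster involves a gene when an anchor overlaps the gene's promoter
#' window; for single-gene calls, overlap with the gene body also counts.
#' Genes touched by a cluster whose anchors reach promoters of two or more
#' distinct genes are category `IV` (multi-gene, promoter-promoter; multi
#' dominates); genes whose clusters involve only themselves are `III`;
#' loop-free genes are `II` when Pol II sits at their promoter and `I`
#' otherwise.  The result is invariant to the order of the interaction
#' records.
#'
#' @param gene_models a [kb_genes] object.
#' @param interactions filtered interaction data.frame.
#' @param polii_status named logical vector from [promoter_polII_status()].
#' @return data.frame `gene_id`, `polII_at_promoter`, `category`.
#' @export
categorize_loops <- function(gene_models, interactions, polii_status) {
  g <- gene_models$genes
  prom <- promoter_windows(gene_models, "annotation")
  promgr <- GenomicRanges::GRanges(prom$chrom,
                                   IRanges::IRanges(prom$start, prom$end))
  bodygr <- GenomicRanges::GRanges(g$chrom,
                                   IRanges::IRanges(g$start, g$end))
  n <- nrow(g)
  has_single <- rep(FALSE, n); has_multi <- rep(FALSE, n)
  if (nrow(interactions)) {
    grA <- .anchor_gr(interactions, "A")
    grB <- .anchor_gr(interactions, "B")
    ovl <- function(gr, target) {
      h <- GenomicRanges::findOverlaps(gr, target)
      split(S4Vectors::subjectHits(h), S4Vectors::queryHits(h))
    }
    pa <- ovl(grA, promgr); pb <- ovl(grB, promgr)
    ba <- ovl(grA, bodygr); bb <- ovl(grB, bodygr)
    for (k in seq_len(nrow(interactions))) {
      kk <- as.character(k)
      prom_genes <- unique(c(pa[[kk]], pb[[kk]]))
      any_genes <- unique(c(prom_genes, ba[[kk]], bb[[kk]]))
      if (length(prom_genes) >= 2) {
        has_multi[any_genes] <- TRUE
      } else if (length(any_genes) >= 1) {
        has_single[any_genes] <- TRUE
      }
    }
  }
  category <- ifelse(has_multi, "IV",
              ifelse(has_single, "III",
              ifelse(polii_status[g$gene_id], "II", "I")))
  data.frame(gene_id = g$gene_id,
             polII_at_promoter = unname(polii_status[g$gene_id]),
             category = category, stringsAsFactors = FALSE)
}

#' Cross-tabulate loop status with target classes and kinetic patterns
#'
#' @param loop_status data.frame from [categorize_loops()].
#' @param records a `kb_taxonomy` object with `pattern_label` filled.
#' @return data.frame of per-(class, pattern_label) counts of looped
#'   (category III/IV) versus non-looped genes; marginals sum to class
#'   sizes.
#' @export
category_kinetics <- function(loop_status, records) {
  looped <- loop_status$category %in% c("III", "IV")
  names(looped) <- loop_status$gene_id
  keep <- records$class %in% c("Ad", "Ai", "Rd", "Ri")
  r <- records[keep, ]
  agg <- stats::aggregate(
    cbind(looped = as.integer(looped[r$gene_id]),
          total = 1L) ~ class + pattern_label,
    data = data.frame(class = r$class,
                      pattern_label = ifelse(is.na(r$pattern_label),
                                             "unclustered",
                                             r$pattern_label)),
    FUN = sum)
  agg$non_looped <- agg$total - agg$looped
  agg[order(agg$class, agg$pattern_label), ]
}

#' Baseline expression by loop category
#'
#' Kruskal-Wallis rank test of per-gene baseline RPM across loop
#' categories.
#'
#' @param loop_status data.frame from [categorize_loops()].
#' @param baseline_rpm named per-gene baseline (time 0) RPM vector.
#' @return list with `by_category` (named list of RPM vectors), `H`
#'   (Kruskal-Wallis statistic), `p`.
#' @export
baseline_expression_by_category <- function(loop_status, baseline_rpm) {
  x <- baseline_rpm[loop_status$gene_id]
  groups <- split(x, loop_status$category)
  groups <- groups[vapply(groups, length, 1L) >= 1]
  if (length(groups) < 2)
    stop("need at least 2 nonempty categories")
  kw <- kruskal.test(groups)
  list(by_category = groups,
       H = unname(kw$statistic), p = kw$p.value)
}

#' Length-normalized metagene coverage profile
#'
#' Rescales each gene's TSS-to-TTS coverage to `n_bins` equal-length bins
#' (bin 1 at the TSS, strand-oriented; each bin value is the
#' base-pair-weighted mean coverage over its genomic sub-interval) and
#' averages the per-gene profiles.
#'
#' @param coverage bedGraph-style data.frame (`chrom`, `start`, `end`,
#'   `value`; 0-based half-open as on disk).
#' @param gene_models a [kb_genes] object; every gene must span at least
#'   `n_bins` bp.
#' @param n_bins number of bins (default 100).
#' @return list with `profile` (length `n_bins` average) and `matrix`
#'   (genes x bins).
#' @export
metagene_profile <- function(coverage, gene_models, n_bins = 100) {
  g <- gene_models$genes
  lens <- g$end - g$start + 1L
  if (any(lens < n_bins))
    stop("gene(s) shorter than n_bins: ",
         paste(g$gene_id[lens < n_bins], collapse = ", "))
  if (any(lens <= 0)) stop("zero-length gene")
  cov_chr <- split(coverage, coverage$chrom)
  prof <- matrix(0, nrow(g), n_bins,
                 dimnames = list(g$gene_id, NULL))
  for (i in seq_len(nrow(g))) {
    cc <- cov_chr[[g$chrom[i]]]
    # gene body in 0-based half-open coordinates
    gs <- g$start[i] - 1L; ge <- g$end[i]
    edges <- gs + (ge - gs) * (0:n_bins) / n_bins
    vals <- numeric(n_bins)
    if (!is.null(cc) && nrow(cc)) {
      for (b in seq_len(n_bins)) {
        lo <- edges[b]; hi <- edges[b + 1]
        ov <- pmin(cc$end, hi) - pmax(cc$start, lo)
        w <- pmax(ov, 0)
        vals[b] <- sum(w * cc$value) / (hi - lo)
      }
    }
    if (g$strand[i] == "-") vals <- rev(vals)
    prof[i, ] <- vals
  }
  list(profile = colMeans(prof), matrix = prof)
}
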