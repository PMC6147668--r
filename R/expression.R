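# Expression module: depth normalization, fold changes, the differential
# test behind the pluggable contract, and qPCR relative expression.

#' Reads-per-million normalization
#'
#' Scales every sample (column) so that its total equals `per` (default one
#' million), preserving within-sample proportions.
#'
#' @param counts count matrix (genes x samples) or a [kb_expression] object.
#' @param per target column total.
#' @return matrix of normalized values with column sums equal to `per`.
#' @export
normalize_rpm <- function(counts, per = 1e6) {
  if (inherits(counts, "kb_expression")) counts <- counts$counts
  tot <- colSums(counts)
  if (any(tot == 0))
    stop("all-zero sample(s): ",
         paste(colnames(counts)[tot == 0], collapse = ", "))
  sweep(counts, 2, tot / per, `/`)
}

#' Per-gene log2 fold change between two sample groups
#'
#' `log2((mean(treated) + pseudocount) / (mean(control) + pseudocount))` on
#' normalized values; the pseudocount (default 1) keeps zero-mean genes
#' defined (0 vs 0 gives a fold change of 0).  A "2-fold or more" change
#' corresponds to `|log2FC| >= 1`.
#'
#' @param normalized normalized matrix (see [normalize_rpm()]).
#' @param treated,control column names or indices of the two arms.
#' @param pseudocount added to both means.
#' @return named numeric vector of log2 fold changes.
#' @export
fold_change <- function(normalized, treated, control, pseudocount = 1) {
  mt <- rowMeans(normalized[, treated, drop = FALSE])
  mc <- rowMeans(normalized[, control, drop = FALSE])
  setNames(log2((mt + pseudocount) / (mc + pseudocount)),
           rownames(normalized))
}

#' Median-of-ratios size factors
#'
#' Per-sample scaling factors computed as the median across genes of the
#' ratio of each count to the gene's geometric mean over samples
#' (genes with a zero count anywhere are excluded from the reference).
#' Robust to compositional shifts when a minority of genes changes
#' strongly, unlike total-count scaling.
#'
#' @param counts count matrix (genes x samples).
#' @return named numeric vector of size factors (total-count factors,
#'   rescaled to geometric mean 1, when no gene is everywhere nonzero).
#' @export
size_factors <- function(counts) {
  lg <- log(counts)
  ok <- is.finite(rowSums(lg))
  if (!any(ok)) {
    sf <- colSums(counts)
    return(sf / exp(mean(log(sf))))
  }
  ref <- rowMeans(lg[ok, , drop = FALSE])
  apply(counts[ok, , drop = FALSE], 2, function(cnt)
    exp(stats::median(log(cnt) - ref)))
}

#' Differential expression test between two sample groups
#'
#' The default engine of the pluggable differential contract: a Wald test
#' on per-gene means of `log2(normalized count + 1)`.  Counts are
#' normalized by median-of-ratios [size_factors()] computed over the
#' contrast's samples (total-count scaling is misled by compositional
#' shifts when a minority of genes responds strongly, which is exactly the
#' regime of an induction time course).  The per-gene pooled within-group
#' variance is floored at `max(median across genes, min_var)` (the
#' pooled-dispersion variance floor), the Wald statistic is referred to the
#' normal distribution, and p-values are Benjamini-Hochberg adjusted within
#' the contrast.  Deterministic given its input; any per-gene
#' (log2FC, p, FDR) table with the same columns can be swapped in
#' downstream.
#'
#' @param counts count matrix or [kb_expression] object.
#' @param treated,control column names/indices of the two arms (at least 2
#'   replicates each).
#' @param pseudocount pseudocount for the reported fold change.
#' @param min_var lower bound on the variance floor (log2 scale).
#' @param norm `"median_ratio"` (default) or `"rpm"` normalization.
#' @return data.frame with `gene_id`, `log2FC`, `p`, `fdr`.
#' @export
test_differential <- function(counts, treated, control, pseudocount = 1,
                              min_var = 0.05,
                              norm = c("median_ratio", "rpm")) {
  if (inherits(counts, "kb_expression")) counts <- counts$counts
  norm <- match.arg(norm)
  if (length(treated) < 2 || length(control) < 2)
    stop("need >= 2 replicates per arm")
  sub <- counts[, c(treated, control), drop = FALSE]
  tot <- colSums(sub)
  if (any(tot == 0))
    stop("all-zero sample(s): ",
         paste(colnames(sub)[tot == 0], collapse = ", "))
  nrm <- if (norm == "median_ratio")
    sweep(sub, 2, size_factors(sub), `/`)
  else
    normalize_rpm(sub)
  treated <- seq_along(treated)
  control <- length(treated) + seq_len(ncol(sub) - length(treated))
  x <- log2(nrm + 1)
  xt <- x[, treated, drop = FALSE]; xc <- x[, control, drop = FALSE]
  nt <- ncol(xt); nc <- ncol(xc)
  vt <- apply(xt, 1, stats::var); vc <- apply(xc, 1, stats::var)
  pooled <- ((nt - 1) * vt + (nc - 1) * vc) / (nt + nc - 2)
  floor_var <- max(stats::median(pooled), min_var)
  v <- pmax(pooled, floor_var)
  se <- sqrt(v * (1 / nt + 1 / nc))
  z <- (rowMeans(xt) - rowMeans(xc)) / se
  p <- 2 * pnorm(-abs(z))
  data.frame(gene_id = rownames(counts),
             log2FC = fold_change(nrm, treated, control, pseudocount),
             p = p, fdr = p.adjust(p, "BH"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' qPCR relative expression
#'
#' `RE = 2^-(CT_target - CT_reference)`: one cycle more than the reference
#' halves the relative expression.
#'
#' @param ct_target,ct_reference threshold-cycle values (finite).
#' @return relative expression, vectorized.
#' @export
qpcr_relative_expression <- function(ct_target, ct_reference) {
  stopifnot(all(is.finite(ct_target)), all(is.finite(ct_reference)))
  2^-(ct_target - ct_reference)
}
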