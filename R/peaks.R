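# Peak module: reproducibility filtering, genomic annotation, and
# peak-to-gene assignment.

.peaks_gr <- function(peaks) {
  GenomicRanges::GRanges(peaks$chrom,
                         IRanges::IRanges(peaks$start, peaks$end),
                         score = peaks$score)
}

#' Filter peaks to those reproduced in both replicates
#'
#' Keeps the signal supported in both replicate peak sets: a support pair is
#' a replicate-A peak and a replicate-B peak, each with score at or above
#' `min_score`, that overlap by at least 1 bp.  Each pair contributes the
#' union of the two intervals with the smaller of the two scores; overlapping
#' contributions are then merged (again keeping the minimum score), which
#' makes the result exactly symmetric in the two replicates.
#'
#' @param repA,repB peak data.frames for the two replicates (same factor and
#'   time; mismatches raise an error when the columns are present).
#' @param min_score peak-score threshold (default 100).
#' @return data.frame of reproducible peaks with columns `chrom`, `start`,
#'   `end`, `name`, `score`, `strand`, and `factor`/`time` carried over.
#' @export
filter_reproducible <- function(repA, repB, min_score = 100) {
  for (col in c("factor", "time")) {
    a <- unique(stats::na.omit(repA[[col]]))
    b <- unique(stats::na.omit(repB[[col]]))
    if (length(a) == 1 && length(b) == 1 && !identical(a, b))
      stop("replicate peak sets disagree on ", col, ": ", a, " vs ", b)
  }
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), name = character(),
                      score = numeric(), strand = character(),
                      factor = character(), time = numeric(),
                      stringsAsFactors = FALSE)
  a <- repA[repA$score >= min_score, , drop = FALSE]
  b <- repB[repB$score >= min_score, , drop = FALSE]
  if (!nrow(a) || !nrow(b)) return(empty)
  gra <- .peaks_gr(a); grb <- .peaks_gr(b)
  hits <- GenomicRanges::findOverlaps(gra, grb)
  if (!length(hits)) return(empty)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  cand <- GenomicRanges::punion(gra[qi], grb[si], fill.gap = FALSE)
  cand$score <- pmin(a$score[qi], b$score[si])
  merged <- GenomicRanges::reduce(cand, with.revmap = TRUE)
  score <- vapply(merged$revmap, function(ii) min(cand$score[ii]),
                  numeric(1))
  fac <- unique(stats::na.omit(c(repA$factor, repB$factor)))
  tim <- unique(stats::na.omit(c(repA$time, repB$time)))
  data.frame(chrom = as.character(GenomicRanges::seqnames(merged)),
             start = GenomicRanges::start(merged),
             end = GenomicRanges::end(merged),
             name = sprintf("reppk%05d", seq_along(merged)),
             score = score, strand = ".",
             factor = if (length(fac) == 1) fac else NA_character_,
             time = if (length(tim) == 1) tim else NA_real_,
             stringsAsFactors = FALSE)
}

# midpoint of a peak (left-median base for even widths)
.peak_mid <- function(peaks) (peaks$start + peaks$end) %/% 2L

# genomic 5'UTR / 3'UTR intervals from the transcript-end UTR lengths
.utr_intervals <- function(gene_models) {
  g <- gene_models$genes
  plus <- g$strand == "+"
  list(
    utr5 = data.frame(gene_id = g$gene_id, chrom = g$chrom,
                      start = ifelse(plus, g$start, g$end - g$utr5_len + 1L),
                      end = ifelse(plus, g$start + g$utr5_len - 1L, g$end)),
    utr3 = data.frame(gene_id = g$gene_id, chrom = g$chrom,
                      start = ifelse(plus, g$end - g$utr3_len + 1L, g$start),
                      end = ifelse(plus, g$end, g$start + g$utr3_len - 1L)))
}

#' Annotate peaks by genomic location
#'
#' Assigns each peak a category from the location of its midpoint, with the
#' fixed priority `promoter` (stranded TSS-1000..TSS+100) > `5' UTR` >
#' `3' UTR` > `exon` > `intron` > `TTS` (within 100 bp of the transcription
#' end) > `intergenic`.
#'
#' @param peaks peak data.frame.
#' @param gene_models a [kb_genes] object.
#' @return the input with an added `annotation` column.
#' @export
annotate_peaks <- function(peaks, gene_models) {
  if (!nrow(peaks)) {
    peaks$annotation <- character(0)
    return(peaks)
  }
  mid <- .peak_mid(peaks)
  midgr <- GenomicRanges::GRanges(peaks$chrom, IRanges::IRanges(mid, mid))
  in_any <- function(df) {
    df <- df[df$start <= df$end, , drop = FALSE]  # drop zero-length UTRs
    if (!nrow(df)) return(rep(FALSE, length(midgr)))
    gr <- GenomicRanges::GRanges(df$chrom,
                                 IRanges::IRanges(df$start, df$end))
    GenomicRanges::countOverlaps(midgr, gr) > 0
  }
  g <- gene_models$genes
  prom <- promoter_windows(gene_models, "annotation")
  utr <- .utr_intervals(gene_models)
  tts <- data.frame(chrom = g$chrom, start = g$tts - 100L,
                    end = g$tts + 100L)
  body <- data.frame(chrom = g$chrom, start = g$start, end = g$end)
  exons <- data.frame(
    chrom = g$chrom[match(gene_models$exons$gene_id, g$gene_id)],
    start = gene_models$exons$start, end = gene_models$exons$end)

  ann <- rep("intergenic", nrow(peaks))
  ann[in_any(tts)] <- "TTS"
  ann[in_any(body)] <- "intron"
  ann[in_any(exons)] <- "exon"
  ann[in_any(utr$utr3)] <- "3' UTR"
  ann[in_any(utr$utr5)] <- "5' UTR"
  ann[in_any(prom)] <- "promoter"
  peaks$annotation <- ann
  peaks
}

#' Annotation category of a single peak
#'
#' Convenience scalar wrapper around [annotate_peaks()].
#'
#' @param peak one-row peak data.frame.
#' @param gene_models a [kb_genes] object.
#' @return character scalar.
#' @export
annotate_peak <- function(peak, gene_models)
  annotate_peaks(peak, gene_models)$annotation

#' Assign peaks to genes
#'
#' A peak whose midpoint lies inside a gene body or promoter window is
#' assigned to that gene; any other peak is assigned to the gene with the
#' nearest TSS, provided the midpoint-to-TSS distance does not exceed
#' `max_distance`.  Distances are signed in stranded orientation (negative =
#' upstream of the TSS).  Ties go to the lexicographically smaller gene id.
#'
#' @param peaks peak data.frame.
#' @param gene_models a [kb_genes] object.
#' @param max_distance maximum |midpoint - TSS| for distal assignment
#'   (default 50 kb).
#' @return data.frame (one row per assigned peak) with peak columns plus
#'   `gene_id`, `distance` and `annotation`.
#' @export
assign_to_genes <- function(peaks, gene_models, max_distance = 50000) {
  peaks <- annotate_peaks(peaks, gene_models)
  if (!nrow(peaks)) {
    out <- peaks
    out$gene_id <- character(0); out$distance <- integer(0)
    return(out)
  }
  g <- gene_models$genes
  prom <- promoter_windows(gene_models, "annotation")
  mid <- .peak_mid(peaks)

  assign_one <- function(k) {
    same_chr <- which(g$chrom == peaks$chrom[k])
    if (!length(same_chr)) return(NA_integer_)
    inside <- same_chr[
      (mid[k] >= g$start[same_chr] & mid[k] <= g$end[same_chr]) |
      (mid[k] >= prom$start[same_chr] & mid[k] <= prom$end[same_chr])]
    cand <- if (length(inside)) inside else same_chr
    d <- abs(mid[k] - g$tss[cand])
    if (!length(inside) && min(d) > max_distance) return(NA_integer_)
    best <- cand[d == min(d)]
    if (length(best) > 1) best <- best[order(g$gene_id[best])][1]
    best
  }
  idx <- vapply(seq_len(nrow(peaks)), assign_one, integer(1))
  keep <- !is.na(idx)
  out <- peaks[keep, , drop = FALSE]
  gi <- idx[keep]
  raw_d <- mid[keep] - g$tss[gi]
  out$gene_id <- g$gene_id[gi]
  out$distance <- as.integer(ifelse(g$strand[gi] == "+", raw_d, -raw_d))
  rownames(out) <- NULL
  out
}

#' Count annotated peaks per category (and per time)
#'
#' @param peaks annotated peak data.frame (see [annotate_peaks()]); a `time`
#'   column, when present, produces one count column per time point.
#' @return table of counts; categories sum to the total number of peaks.
#' @export
category_summary <- function(peaks) {
  cats <- c("promoter", "5' UTR", "3' UTR", "exon", "intron", "TTS",
            "intergenic")
  ann <- factor(peaks$annotation, levels = cats)
  if ("time" %in% names(peaks) && length(unique(peaks$time)) > 1)
    table(annotation = ann, time = peaks$time)
  else
    table(annotation = ann)
}
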