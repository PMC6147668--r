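#' Gene model container
#'
#' A light container for gene models: a `genes` table (gene_id, chrom,
#' start, end, strand, tss, tts, utr5_len, utr3_len), an `exons` table
#' (gene_id, rank, start, end) and named `chrom_sizes`.  All coordinates are
#' 1-based closed; BED-like inputs are converted on read.
#'
#' @param genes data.frame as described above.
#' @param exons data.frame of exon intervals.
#' @param chrom_sizes named integer vector of chromosome lengths.
#' @return an object of class `kb_genes`.
#' @export
kb_genes <- function(genes, exons, chrom_sizes) {
  need <- c("gene_id", "chrom", "start", "end", "strand", "tss", "tts")
  if (!all(need %in% names(genes)))
    stop("genes table must contain columns: ", paste(need, collapse = ", "))
  stopifnot(all(genes$strand %in% c("+", "-")),
            all(genes$start <= genes$end),
            !anyDuplicated(genes$gene_id))
  # TSS/TTS orientation follows strand: TSS < TTS on '+', TSS > TTS on '-'
  plus <- genes$strand == "+"
  stopifnot(all(genes$tss[plus] < genes$tts[plus]),
            all(genes$tss[!plus] > genes$tts[!plus]))
  obj <- list(genes = genes, exons = exons,
              chrom_sizes = chrom_sizes)
  class(obj) <- "kb_genes"
  obj
}

#' @export
print.kb_genes <- function(x, ...) {
  cat("kb_genes:", nrow(x$genes), "genes on",
      length(x$chrom_sizes), "chromosome(s)\n")
  invisible(x)
}

#' Stranded promoter windows
#'
#' Returns one of the three promoter windows used throughout the pipeline,
#' oriented by strand (upstream means 5' of the TSS on the coding strand):
#' * `annotation`: TSS-1000 .. TSS+100 (peak annotation / Pol II status),
#' * `scan`: TSS-400 .. TSS+100 (motif prevalence screens),
#' * `conservation`: TSS-1000 .. TSS-1 (the 1-kb upstream window used for
#'   cross-species conservation; excludes the TSS itself).
#'
#' @param gene_models a [kb_genes] object.
#' @param type which window to compute.
#' @return data.frame with `gene_id`, `chrom`, `start`, `end`, `strand`
#'   (1-based closed, clipped to chromosome bounds).
#' @export
promoter_windows <- function(gene_models,
                             type = c("annotation", "scan", "conservation")) {
  type <- match.arg(type)
  g <- gene_models$genes
  up <- switch(type, annotation = 1000L, scan = 400L, conservation = 1000L)
  down <- switch(type, annotation = 100L, scan = 100L, conservation = -1L)
  plus <- g$strand == "+"
  start <- ifelse(plus, g$tss - up, g$tss - down)
  end <- ifelse(plus, g$tss + down, g$tss + up)
  lim <- gene_models$chrom_sizes[g$chrom]
  data.frame(gene_id = g$gene_id, chrom = g$chrom,
             start = pmax(1L, as.integer(start)),
             end = pmin(as.integer(lim), as.integer(end)),
             strand = g$strand, stringsAsFactors = FALSE)
}

#' Generate non-overlapping gene models
#'
#' Packs `n_genes` gene bodies with random lengths, strands and intergenic
#' gaps onto the configured chromosomes, leaving a 60-kb margin at both ends
#' so that every gene plus its 50-kb assignment neighbourhood fits.  Each
#' gene gets two exons separated by one intron, with 5'/3' UTR segments at
#' the transcript ends.
#'
#' @param config a [sim_config()] object.
#' @return a [kb_genes] object.
#' @export
generate_gene_models <- function(config) {
  set.seed(config$seed)
  n <- config$n_genes
  lens <- round(runif(n, config$gene_length_range[1],
                      config$gene_length_range[2]))
  gaps <- round(runif(n, config$intergenic_gap_range[1],
                      config$intergenic_gap_range[2]))
  strand <- sample(c("+", "-"), n, replace = TRUE)
  n_chr <- length(config$chrom_names)
  chrom_idx <- rep(seq_len(n_chr), length.out = n)
  chrom_idx <- sort(chrom_idx)
  margin <- 60000L

  start <- integer(n); end <- integer(n)
  chrom_sizes <- setNames(integer(n_chr), config$chrom_names)
  for (ci in seq_len(n_chr)) {
    idx <- which(chrom_idx == ci)
    pos <- margin
    for (i in idx) {
      start[i] <- pos + 1L
      end[i] <- pos + lens[i]
      pos <- pos + lens[i] + gaps[i]
    }
    chrom_sizes[ci] <- pos + margin
    if (!is.null(config$chrom_length)) {
      if (chrom_sizes[ci] > config$chrom_length)
        stop(sprintf(
          "infeasible packing: %d genes need %d bp on %s but chrom_length is %d",
          length(idx), chrom_sizes[ci], config$chrom_names[ci],
          config$chrom_length))
      chrom_sizes[ci] <- as.integer(config$chrom_length)
    }
  }

  gene_id <- sprintf("G%04d", seq_len(n))
  tss <- ifelse(strand == "+", start, end)
  tts <- ifelse(strand == "+", end, start)
  utr5 <- round(runif(n, config$utr5_range[1], config$utr5_range[2]))
  utr3 <- round(runif(n, config$utr3_range[1], config$utr3_range[2]))

  # two exons: exon1 covers the first 35-45% of the body, exon2 the last
  e1_frac <- runif(n, 0.35, 0.45)
  e1_len <- pmax(utr5 + 200L, round(lens * e1_frac))
  e2_len <- pmax(utr3 + 200L, round(lens * 0.35))
  # keep at least a 200 bp intron
  e2_len <- pmin(e2_len, lens - e1_len - 200L)
  stopifnot(all(e2_len > 0))

  genes <- data.frame(gene_id = gene_id,
                      chrom = config$chrom_names[chrom_idx],
                      start = start, end = end, strand = strand,
                      tss = as.integer(tss), tts = as.integer(tts),
                      utr5_len = as.integer(utr5),
                      utr3_len = as.integer(utr3),
                      stringsAsFactors = FALSE)
  plus <- strand == "+"
  exon1 <- data.frame(gene_id = gene_id, rank = 1L,
                      start = ifelse(plus, start, end - e1_len + 1L),
                      end = ifelse(plus, start + e1_len - 1L, end))
  exon2 <- data.frame(gene_id = gene_id, rank = 2L,
                      start = ifelse(plus, end - e2_len + 1L, start),
                      end = ifelse(plus, end, start + e2_len - 1L))
  exons <- rbind(exon1, exon2)
  exons <- exons[order(exons$gene_id, exons$start), ]
  rownames(exons) <- NULL
  kb_genes(genes, exons, chrom_sizes)
}

#' Write gene models as GTF
#'
#' Emits one `gene` and two `exon` records per gene (1-based closed, per the
#' GTF standard) through \pkg{rtracklayer}.
#'
#' @param gene_models a [kb_genes] object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(gene_models, path) {
  g <- gene_models$genes
  e <- gene_models$exons
  gr_gene <- GenomicRanges::GRanges(
    g$chrom, IRanges::IRanges(g$start, g$end), strand = g$strand,
    type = "gene", gene_id = g$gene_id,
    utr5_len = g$utr5_len, utr3_len = g$utr3_len)
  strand_e <- g$strand[match(e$gene_id, g$gene_id)]
  chrom_e <- g$chrom[match(e$gene_id, g$gene_id)]
  gr_exon <- GenomicRanges::GRanges(
    chrom_e, IRanges::IRanges(e$start, e$end), strand = strand_e,
    type = "exon", gene_id = e$gene_id,
    utr5_len = NA_integer_, utr3_len = NA_integer_)
  gr <- c(gr_gene, gr_exon)
  GenomeInfoDb::seqlengths(gr) <-
    gene_models$chrom_sizes[GenomeInfoDb::seqlevels(gr)]
  rtracklayer::export(sort(gr), path, format = "gtf")
  invisible(path)
}

#' Read gene models from GTF
#'
#' Inverse of [write_gtf()].  Chromosome sizes default to the furthest
#' annotated coordinate plus a 60-kb margin when the GTF carries none.
#'
#' @param path GTF file with `gene` and `exon` records carrying `gene_id`.
#' @return a [kb_genes] object.
#' @export
read_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  df <- as.data.frame(gr)
  gene_rows <- df[df$type == "gene", ]
  exon_rows <- df[df$type == "exon", ]
  strand <- as.character(gene_rows$strand)
  genes <- data.frame(
    gene_id = gene_rows$gene_id,
    chrom = as.character(gene_rows$seqnames),
    start = gene_rows$start, end = gene_rows$end, strand = strand,
    tss = ifelse(strand == "+", gene_rows$start, gene_rows$end),
    tts = ifelse(strand == "+", gene_rows$end, gene_rows$start),
    utr5_len = if ("utr5_len" %in% names(gene_rows))
      as.integer(gene_rows$utr5_len) else 0L,
    utr3_len = if ("utr3_len" %in% names(gene_rows))
      as.integer(gene_rows$utr3_len) else 0L,
    stringsAsFactors = FALSE)
  genes <- genes[order(genes$gene_id), ]
  rownames(genes) <- NULL
  exons <- data.frame(gene_id = exon_rows$gene_id,
                      rank = NA_integer_,
                      start = exon_rows$start, end = exon_rows$end)
  exons <- exons[order(exons$gene_id, exons$start), ]
  exons$rank <- stats::ave(exons$start, exons$gene_id,
                           FUN = seq_along)
  rownames(exons) <- NULL
  sl <- GenomeInfoDb::seqlengths(gr)
  if (all(is.na(sl))) {
    sl <- tapply(genes$end, genes$chrom, max) + 60000L
    sl <- setNames(as.integer(sl), names(sl))
  }
  kb_genes(genes, exons, sl)
}
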