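# File interfaces.  On-disk conventions follow the format standards:
# BED/BEDPE are 0-based half-open, GTF is 1-based closed; everything is
# converted to the package-internal 1-based closed convention on read.

#' Write a peak set as BED6
#'
#' @param peaks peak data.frame (columns `chrom`, `start`, `end`, `name`,
#'   `score`, `strand`; 1-based closed).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_peaks_bed <- function(peaks, path) {
  gr <- GenomicRanges::GRanges(
    peaks$chrom, IRanges::IRanges(peaks$start, peaks$end),
    name = if ("name" %in% names(peaks)) peaks$name else
      sprintf("pk%05d", seq_len(nrow(peaks))),
    score = peaks$score)
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Read a BED6 peak file
#'
#' @param path BED file (score in column 5).
#' @param factor,time,replicate metadata attached to every peak.
#' @return peak data.frame in the internal convention.
#' @export
read_peaks_bed <- function(path, factor = NA_character_, time = NA_real_,
                           replicate = NA_integer_) {
  gr <- rtracklayer::import(path, format = "bed")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             name = if (!is.null(gr$name)) gr$name else
               sprintf("pk%05d", seq_along(gr)),
             score = if (!is.null(gr$score)) as.numeric(gr$score) else 0,
             strand = ".",
             factor = factor, time = time, replicate = replicate,
             stringsAsFactors = FALSE)
}

#' Write PET clusters as BEDPE
#'
#' Columns: the six BEDPE coordinates, `name`, `pet_count` (score slot),
#' both strands, then optional `p` and `fdr`.
#'
#' @param interactions interaction data.frame (internal 1-based convention).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bedpe <- function(interactions, path) {
  x <- interactions
  out <- data.frame(x$chromA, x$startA - 1L, x$endA,
                    x$chromB, x$startB - 1L, x$endB,
                    x$name, x$pet_count, x$strandA, x$strandB)
  if (!is.null(x$p)) out <- cbind(out, x$p, x$fdr)
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BEDPE interaction file
#'
#' Expects at least 8 columns (anchors, name, PET count); columns 11 and 12,
#' when present, are taken as per-cluster `p` and `fdr`.  Malformed rows
#' raise an error naming the offending line.
#'
#' @param path BEDPE file.
#' @return interaction data.frame in the internal convention.
#' @export
read_bedpe <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 8))
    stop("malformed BEDPE row (fewer than 8 fields) at line ",
         which(nf < 8)[1])
  get <- function(k) vapply(fields, `[[`, "", k)
  num <- function(k, line_label) {
    v <- suppressWarnings(as.numeric(get(k)))
    if (anyNA(v))
      stop("malformed BEDPE ", line_label, " at line ", which(is.na(v))[1])
    v
  }
  out <- data.frame(
    chromA = get(1), startA = as.integer(num(2, "startA")) + 1L,
    endA = as.integer(num(3, "endA")),
    chromB = get(4), startB = as.integer(num(5, "startB")) + 1L,
    endB = as.integer(num(6, "endB")),
    name = get(7), pet_count = as.integer(num(8, "pet_count")),
    strandA = ifelse(nf >= 9, vapply(fields, function(f)
      if (length(f) >= 9) f[[9]] else ".", ""), "."),
    strandB = ifelse(nf >= 10, vapply(fields, function(f)
      if (length(f) >= 10) f[[10]] else ".", ""), "."),
    stringsAsFactors = FALSE)
  if (all(nf >= 12)) {
    out$p <- num(11, "p")
    out$fdr <- num(12, "fdr")
  }
  bad <- out$startA > out$endA | out$startB > out$endB
  if (any(bad))
    stop("malformed BEDPE interval (start > end) at line ", which(bad)[1])
  out
}

#' Write a count matrix as TSV
#'
#' Header columns encode cell line, Tet arm, time and replicate
#' (e.g. `clone1_plus_1h_r2`).
#'
#' @param expression a [kb_expression] object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_counts_tsv <- function(expression, path) {
  df <- data.frame(gene_id = rownames(expression$counts),
                   expression$counts, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a count matrix written by [write_counts_tsv()]
#'
#' Sample metadata are reconstructed from the header names.
#'
#' @param path TSV file.
#' @return a [kb_expression] object.
#' @export
read_counts_tsv <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  counts <- as.matrix(df[, -1, drop = FALSE])
  rownames(counts) <- df$gene_id
  parts <- strsplit(colnames(counts), "_", fixed = TRUE)
  samples <- data.frame(
    sample = colnames(counts),
    cell_line = vapply(parts, `[[`, "", 1),
    tet = vapply(parts, `[[`, "", 2),
    time = as.numeric(sub("h$", "", vapply(parts, `[[`, "", 3))),
    replicate = as.integer(sub("^r", "", vapply(parts, `[[`, "", 4))),
    stringsAsFactors = FALSE)
  kb_expression(counts, samples)
}

#' Write promoter sequences as FASTA
#'
#' @param promoters a `kb_promoters` object.
#' @param species species to write.
#' @param path output file.
#' @param window promoter window to export (default: the 1-kb upstream
#'   conservation window).
#' @return `path`, invisibly.
#' @export
write_promoters_fasta <- function(promoters, species, path,
                                  window = "conservation") {
  s <- promoter_seqs(promoters, species, window)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(s), path)
  invisible(path)
}

#' Read promoter sequences from FASTA
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_promoters_fasta <- function(path) {
  s <- Biostrings::readDNAStringSet(path)
  setNames(as.character(s), names(s))
}

#' Write every simulated input to a directory
#'
#' Emits `genes.gtf`, `counts.tsv`, `truth.tsv`,
#' `peaks_<factor>_<time>h_rep<k>.bed`, `interactions_rep1.bedpe` and
#' `promoters_<species>.fasta`.
#'
#' @param sim a `kb_sim` object from [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_gtf(sim$gene_models, file.path(dir, "genes.gtf"))
  write_counts_tsv(sim$expression, file.path(dir, "counts.tsv"))
  truth <- sim$truth
  sites <- sim$promoters$sites
  truth$planted_sites <- vapply(truth$gene_id, function(gid) {
    s <- sites[sites$gene_id == gid, ]
    if (!nrow(s)) "" else paste(sprintf("%d:%s", s$offset, s$strand),
                                collapse = ";")
  }, "")
  write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  pk <- sim$peaks
  for (factor in unique(pk$factor)) for (time in unique(pk$time))
    for (rep in unique(pk$replicate)) {
      sub <- peak_subset(pk, factor, time, rep)
      if (!nrow(sub)) next
      write_peaks_bed(sub, file.path(
        dir, sprintf("peaks_%s_%gh_rep%d.bed", factor, time, rep)))
    }
  write_bedpe(sim$interactions, file.path(dir, "interactions_rep1.bedpe"))
  for (sp in names(sim$promoters$seqs))
    write_promoters_fasta(sim$promoters, sp,
                          file.path(dir, sprintf("promoters_%s.fasta", sp)))
  invisible(dir)
}
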