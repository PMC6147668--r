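# Motif module: PWMs, promoter scanning at a relative-score threshold,
# motif prevalence, and cross-species conservation of kB sites.

.base_order <- c("A", "C", "G", "T")

#' Position weight matrix object
#'
#' Wraps a 4 x width count (or probability) matrix with background base
#' frequencies and the derived log-odds matrix.  Probabilities use the
#' JASPAR-style pseudocount (default 0.8) divided evenly over the four
#' bases.
#'
#' @param counts 4 x width numeric matrix with rownames A, C, G, T.
#' @param motif_id identifier.
#' @param name human-readable motif name.
#' @param background named background base frequencies (default uniform).
#' @param pseudocount total pseudocount per column.
#' @return object of class `kb_pwm` with elements `motif_id`, `name`,
#'   `counts`, `prob`, `logodds` (log2), `width`, `min_score`, `max_score`.
#' @export
kb_pwm <- function(counts, motif_id = "motif", name = motif_id,
                   background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                   pseudocount = 0.8) {
  counts <- as.matrix(counts)
  if (!identical(rownames(counts), .base_order))
    stop("counts must have rownames A, C, G, T")
  if (any(counts < 0)) stop("negative counts")
  prob <- sweep(counts + pseudocount / 4, 2,
                colSums(counts) + pseudocount, `/`)
  lo <- log2(sweep(prob, 1, background[.base_order], `/`))
  obj <- list(motif_id = motif_id, name = name, counts = counts,
              prob = prob, logodds = lo, width = ncol(counts),
              min_score = sum(apply(lo, 2, min)),
              max_score = sum(apply(lo, 2, max)))
  if (!all(is.finite(lo))) stop("log-odds not finite; check background")
  class(obj) <- "kb_pwm"
  obj
}

#' @export
print.kb_pwm <- function(x, ...) {
  cat("kb_pwm", x$motif_id, "(", x$name, "), width", x$width,
      ", consensus", pwm_consensus(x), "\n")
  invisible(x)
}

#' Consensus sequence of a PWM (highest-count base per position)
#'
#' @param pwm a `kb_pwm` object.
#' @return character scalar.
#' @export
pwm_consensus <- function(pwm) {
  paste(.base_order[apply(pwm$counts, 2, which.max)], collapse = "")
}

#' Reverse complement
#'
#' @param x DNA string(s) over A/C/G/T/N.
#' @return reverse-complemented string(s).
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Synthetic kB-family motif library
#'
#' Four PWMs representing the NF-kB family members NFKB1, NFKB2, REL and
#' RELA, constructed in code from the GGGRNYYYCC kB consensus with
#' member-specific weighting of the degenerate positions.  These are
#' synthetic stand-ins built from the published consensus, not database
#' matrices; any JASPAR-format library read with [read_jaspar()] can be
#' used instead.
#'
#' @return named list of `kb_pwm` objects.
#' @export
kb_motif_library <- function() {
  # columns follow GGGRNYYYCC; counts out of 100 sequences
  kb_counts <- function(r_weight, y_weight) {
    cols <- list(
      G = c(2, 2, 94, 2), G = c(2, 2, 94, 2), G = c(2, 2, 94, 2),
      R = c(r_weight, 2, 96 - r_weight, 2),
      N = c(25, 25, 25, 25),
      Y = c(2, y_weight, 2, 96 - y_weight),
      Y = c(2, y_weight, 2, 96 - y_weight),
      Y = c(2, 96 - y_weight, 2, y_weight),
      C = c(2, 94, 2, 2), C = c(2, 94, 2, 2))
    m <- do.call(cbind, cols)
    rownames(m) <- .base_order
    m
  }
  specs <- list(NFKB1 = c(70, 30), NFKB2 = c(55, 45),
                REL = c(40, 60), RELA = c(25, 70))
  out <- lapply(names(specs), function(nm)
    kb_pwm(kb_counts(specs[[nm]][1], specs[[nm]][2]),
           motif_id = paste0("KB_", nm), name = nm))
  setNames(out, names(specs))
}

#' Read PWMs from a JASPAR-format text file
#'
#' Parses the standard JASPAR flat format: a `>ID name` header followed by
#' four rows `A [ 1 2 ... ]` (brackets optional).
#'
#' @param path JASPAR-format file.
#' @return named list of `kb_pwm` objects (names = motif ids).
#' @export
read_jaspar <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  starts <- grep("^>", lines)
  if (!length(starts)) stop("no JASPAR records in ", path)
  out <- list()
  for (s in starts) {
    hdr <- strsplit(sub("^>\\s*", "", lines[s]), "\\s+")[[1]]
    rows <- lines[(s + 1):(s + 4)]
    mat <- do.call(rbind, lapply(rows, function(r) {
      nums <- sub("^[ACGT]\\s*\\[?", "", r)
      nums <- sub("\\]\\s*$", "", nums)
      as.numeric(strsplit(trimws(nums), "\\s+")[[1]])
    }))
    base_letters <- substr(rows, 1, 1)
    rownames(mat) <- base_letters
    mat <- mat[.base_order, , drop = FALSE]
    id <- hdr[1]
    out[[id]] <- kb_pwm(mat, motif_id = id,
                        name = if (length(hdr) > 1) hdr[2] else id)
  }
  out
}

#' Write PWMs in JASPAR format
#'
#' @param pwms a `kb_pwm` or list of them.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_jaspar <- function(pwms, path) {
  if (inherits(pwms, "kb_pwm")) pwms <- list(pwms)
  con <- file(path, "w")
  on.exit(close(con))
  for (p in pwms) {
    writeLines(sprintf(">%s %s", p$motif_id, p$name), con)
    for (b in .base_order)
      writeLines(sprintf("%s [ %s ]", b,
                         paste(format(p$counts[b, ]), collapse = " ")),
                 con)
  }
  invisible(path)
}

# integer-encode a sequence; N and other letters -> NA
.seq_int <- function(seq) {
  v <- strsplit(toupper(seq), "")[[1]]
  match(v, .base_order)
}

#' Scan a sequence with a PWM
#'
#' Slides the PWM over both strands and reports windows whose relative
#' log-odds score, `(score - min) / (max - min)`, reaches `rel_threshold`.
#' Offsets are 0-based positions of the window start on the forward
#' (given) sequence; windows containing `N` are skipped.
#'
#' @param seq DNA string over A/C/G/T/N.
#' @param pwm a `kb_pwm` object.
#' @param rel_threshold relative score threshold in [0, 1] (default 0.80).
#' @return data.frame `offset` (0-based), `strand`, `relative_score`,
#'   `motif_id`; empty (with a warning) when the sequence is shorter than
#'   the motif.
#' @export
scan_motif <- function(seq, pwm, rel_threshold = 0.80) {
  empty <- data.frame(offset = integer(), strand = character(),
                      relative_score = numeric(), motif_id = character(),
                      stringsAsFactors = FALSE)
  w <- pwm$width
  x <- .seq_int(seq)
  L <- length(x)
  if (L < w) {
    warning("sequence shorter than motif width; no sites")
    return(empty)
  }
  n_win <- L - w + 1L
  score_with <- function(lo) {
    sc <- numeric(n_win)
    ok <- rep(TRUE, n_win)
    for (j in seq_len(w)) {
      b <- x[j:(j + n_win - 1L)]
      bad <- is.na(b)
      ok <- ok & !bad
      b[bad] <- 1L
      sc <- sc + lo[cbind(b, j)]
    }
    sc[!ok] <- -Inf
    sc
  }
  rel <- function(sc) (sc - pwm$min_score) / (pwm$max_score - pwm$min_score)
  fwd <- rel(score_with(pwm$logodds))
  # reverse strand: score the reverse-complement motif on the forward seq
  lo_rc <- pwm$logodds[4:1, w:1]
  rownames(lo_rc) <- .base_order
  rev <- rel(score_with(lo_rc))
  strand_hits <- function(sc, strand) {
    keep <- which(sc >= rel_threshold)
    data.frame(offset = keep - 1L,
               strand = rep(strand, length(keep)),
               relative_score = sc[keep], stringsAsFactors = FALSE)
  }
  hits <- rbind(strand_hits(fwd, "+"), strand_hits(rev, "-"))
  if (!nrow(hits)) return(empty)
  hits$motif_id <- pwm$motif_id
  hits <- hits[order(hits$offset, hits$strand), ]
  rownames(hits) <- NULL
  hits
}

#' Motifs present in more than a threshold fraction of promoters
#'
#' A motif counts once per promoter regardless of site multiplicity; the
#' "present" boundary is a strict inequality (`fraction > threshold`).
#'
#' @param promoters named character vector of promoter sequences (the
#'   -400..+100 scan window in the standard screen).
#' @param pwms list of `kb_pwm` objects.
#' @param rel_threshold per-site relative-score threshold (default 0.80).
#' @param prevalence_threshold prevalence cutoff (default 0.20).
#' @return data.frame `motif_id`, `n_promoters`, `fraction`, restricted to
#'   motifs with `fraction > prevalence_threshold`.
#' @export
motif_prevalence <- function(promoters, pwms, rel_threshold = 0.80,
                             prevalence_threshold = 0.20) {
  if (!length(promoters)) stop("empty promoter set")
  if (inherits(pwms, "kb_pwm")) pwms <- list(pwms)
  rows <- lapply(pwms, function(p) {
    present <- vapply(promoters, function(s)
      nrow(scan_motif(s, p, rel_threshold)) > 0, logical(1))
    data.frame(motif_id = p$motif_id, n_promoters = sum(present),
               fraction = mean(present), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[out$fraction > prevalence_threshold, , drop = FALSE]
}

#' Global pairwise alignment (Needleman-Wunsch)
#'
#' Linear gap penalty with deterministic tie-breaking (diagonal preferred
#' over a gap in the second sequence, over a gap in the first).
#'
#' @param a,b DNA strings over A/C/G/T/N (nonempty).
#' @param match,mismatch,gap scoring parameters (defaults +1/-1/-2).
#' @return object of class `kb_alignment`: list with `aligned_a`,
#'   `aligned_b` (gapped strings), `score`, `identity` (matches over
#'   alignment columns).
#' @export
align_pair <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be nonempty")
  if (grepl("[^ACGTNacgtn]", a) || grepl("[^ACGTNacgtn]", b))
    stop("sequences must be over A/C/G/T/N")
  res <- nw_align_cpp(toupper(a), toupper(b), match, mismatch, gap)
  va <- strsplit(res$aligned_a, "")[[1]]
  vb <- strsplit(res$aligned_b, "")[[1]]
  res$identity <- mean(va == vb & va != "-")
  class(res) <- "kb_alignment"
  res
}

#' @export
print.kb_alignment <- function(x, ...) {
  cat("kb_alignment: score", x$score, ", identity",
      format(x$identity, digits = 3), ",", nchar(x$aligned_a),
      "columns\n")
  invisible(x)
}

#' Window identity around a human site, through an alignment
#'
#' Computes the fraction of identical positions over the `window`-bp window
#' of *human* coordinates centered on `site_center` (0-based), mapped
#' through the alignment; human positions aligned to a gap count as
#' mismatches.  The window is truncated at the sequence ends and the
#' denominator is the truncated window length.
#'
#' @param alignment a `kb_alignment` of (human, ortholog).
#' @param site_center 0-based human position at the window center.
#' @param window odd window size (default 51).
#' @return identity fraction in [0, 1].
#' @export
window_conservation <- function(alignment, site_center, window = 51) {
  if (window %% 2 == 0) stop("window must be odd")
  va <- strsplit(alignment$aligned_a, "")[[1]]
  vb <- strsplit(alignment$aligned_b, "")[[1]]
  hpos <- cumsum(va != "-") - 1L   # 0-based human coordinate per column
  hpos[va == "-"] <- NA
  L <- sum(va != "-")
  half <- (window - 1L) %/% 2L
  lo <- max(0L, site_center - half)
  hi <- min(L - 1L, site_center + half)
  cols <- which(!is.na(hpos) & hpos >= lo & hpos <= hi)
  mean(va[cols] == vb[cols] & va[cols] != "-")
}

# ortholog subsequence spanning the aligned image of a human window
.ortholog_window_seq <- function(alignment, lo, hi) {
  va <- strsplit(alignment$aligned_a, "")[[1]]
  vb <- strsplit(alignment$aligned_b, "")[[1]]
  hpos <- cumsum(va != "-") - 1L
  hpos[va == "-"] <- NA
  cols <- which(!is.na(hpos) & hpos >= lo & hpos <= hi)
  if (!length(cols)) return("")
  seg <- vb[min(cols):max(cols)]
  paste(seg[seg != "-"], collapse = "")
}

#' Per-gene fraction of conserved kB sites
#'
#' A site is conserved with respect to a species when (a) the 51-bp window
#' identity around the site midpoint reaches `cons_cutoff` and (b) the
#' orthologous window carries a PWM hit at the `rel_threshold` relative
#' score (each criterion can be toggled).  The per-gene percentage is
#' `100 * conserved / total`, computed per species and combined with
#' `combine` (default: mean across species).  Genes with zero sites are
#' reported as missing (`NA`).
#'
#' @param sites data.frame from [scan_motif()] (columns `offset`, `strand`,
#'   `motif_id`), sites of one gene's promoter.
#' @param human human promoter sequence.
#' @param orthologs named character vector/list of ortholog promoter
#'   sequences (one per species).
#' @param pwms list of `kb_pwm` used for the ortholog re-scan.
#' @param cons_cutoff window-identity cutoff (default 0.40).
#' @param rel_threshold relative score for the ortholog hit (default 0.80).
#' @param window window size (default 51).
#' @param require_identity,require_ortholog_hit criterion toggles.
#' @param combine function combining per-species percentages (default
#'   `mean`).
#' @param align_params list of [align_pair()] scoring parameters.
#' @return list with `n_total`, `per_species` (named percent conserved),
#'   `percent_conserved` (combined; `NA` when no sites).
#' @export
conserved_site_fraction <- function(sites, human, orthologs, pwms,
                                    cons_cutoff = 0.40,
                                    rel_threshold = 0.80, window = 51,
                                    require_identity = TRUE,
                                    require_ortholog_hit = TRUE,
                                    combine = mean,
                                    align_params = list()) {
  if (inherits(pwms, "kb_pwm")) pwms <- list(pwms)
  n <- nrow(sites)
  if (n == 0)
    return(list(n_total = 0L,
                per_species = setNames(rep(NA_real_, length(orthologs)),
                                       names(orthologs)),
                percent_conserved = NA_real_))
  widths <- vapply(sites$motif_id, function(id) {
    w <- vapply(pwms, function(p) if (p$motif_id == id) p$width else NA_integer_,
                integer(1))
    w <- w[!is.na(w)]
    if (length(w)) w[1] else pwms[[1]]$width
  }, integer(1))
  centers <- sites$offset + widths %/% 2L
  half <- (window - 1L) %/% 2L
  per_species <- vapply(names(orthologs), function(sp) {
    al <- do.call(align_pair,
                  c(list(a = human, b = orthologs[[sp]]), align_params))
    conserved <- vapply(seq_len(n), function(k) {
      ok <- TRUE
      if (require_identity)
        ok <- window_conservation(al, centers[k], window) >= cons_cutoff
      if (ok && require_ortholog_hit) {
        lo <- max(0L, centers[k] - half)
        hi <- min(nchar(human) - 1L, centers[k] + half)
        oseq <- .ortholog_window_seq(al, lo, hi)
        ok <- nchar(oseq) >= min(vapply(pwms, `[[`, 1L, "width")) &&
          any(vapply(pwms, function(p)
            nchar(oseq) >= p$width &&
              nrow(scan_motif(oseq, p, rel_threshold)) > 0, logical(1)))
      }
      ok
    }, logical(1))
    100 * sum(conserved) / n
  }, numeric(1))
  list(n_total = n, per_species = per_species,
       percent_conserved = combine(per_species))
}
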