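# Synthetic-data generator: plants a known per-gene ground truth (target
# class, kinetic pattern, loop category, kB sites) and emits every input the
# downstream modules consume.  Fixing config$seed fixes every output byte.

#' Canonical kinetic trajectory shapes
#'
#' Six distinguishable induction profiles over 0/1/4 h, expressed as fold
#' multipliers of the baseline mean.  Pattern 3 is the transient spike
#' (induced at 1 h, back to baseline by 4 h); patterns 1, 2 and 4-6 cover
#' late-only, steady, peak-then-partial-decline, early-plateau and
#' primed-peak-decline shapes.  Repressed genes use the reciprocal profiles.
#'
#' @param fold peak fold change (> 1).
#' @param times time points (subset of 0/1/4 h).
#' @return 6 x length(times) matrix of fold multipliers.
#' @export
kinetic_shapes <- function(fold, times = c(0, 1, 4)) {
  f <- fold
  m <- rbind(
    c(1,           1,           f),
    c(1,           (1 + f) / 2, f),
    c(1,           f,           1),
    c(1,           f,           (1 + f) / 2),
    c(1,           f,           f),
    c((1 + f) / 2, f,           1))
  colnames(m) <- c("0", "1", "4")
  rownames(m) <- as.character(1:6)
  m[, as.character(times), drop = FALSE]
}

#' Generate the ground-truth table
#'
#' Draws a class for every gene (multinomial at the configured proportions),
#' a kinetic pattern for responsive classes, a planted induction fold, and a
#' loop category.  Transient direct targets (pattern 3 Ad) draw their loop
#' category from `transient_loop_probs`, emulating the enrichment of
#' preformed Pol II loops at transiently induced targets.  Multi-gene (IV)
#' loop counts are made even per chromosome (odd leftovers demoted to III)
#' so every IV gene can be paired in a promoter-promoter cluster.
#'
#' @param gene_models a [kb_genes] object.
#' @param config a [sim_config()] object.
#' @return data.frame with columns `gene_id`, `true_class`, `true_pattern`,
#'   `true_loop_category`, `induction_fold`.
#' @export
simulate_truth <- function(gene_models, config) {
  set.seed(config$seed + 1L)
  g <- gene_models$genes
  n <- nrow(g)
  classes <- sample(names(config$class_probs), n, replace = TRUE,
                    prob = config$class_probs)
  responsive <- classes %in% c("Ad", "Ai", "Rd", "Ri")
  pattern <- ifelse(responsive, sample(1:6, n, replace = TRUE), NA_integer_)
  fold <- runif(n, config$induction_fold_range[1],
                config$induction_fold_range[2])
  fold[!responsive] <- 1

  cat_names <- names(config$loop_category_probs)
  loop_cat <- character(n)
  transient_direct <- classes == "Ad" & !is.na(pattern) & pattern == 3L
  for (i in seq_len(n)) {
    p <- if (transient_direct[i]) config$transient_loop_probs
         else config$loop_category_probs
    loop_cat[i] <- sample(cat_names, 1L, prob = p)
  }
  # pair IV genes within chromosomes; demote odd leftovers to III
  for (chr in unique(g$chrom)) {
    iv <- which(loop_cat == "IV" & g$chrom == chr)
    if (length(iv) %% 2 == 1) loop_cat[iv[length(iv)]] <- "III"
  }
  data.frame(gene_id = g$gene_id,
             true_class = classes,
             true_pattern = as.integer(pattern),
             true_loop_category = loop_cat,
             induction_fold = fold,
             stringsAsFactors = FALSE)
}

# expected mean matrix (genes x samples) before library-size factors
.expected_means <- function(gene_models, truth, config, design, base) {
  n <- nrow(truth)
  mu <- matrix(base, nrow = n, ncol = nrow(design))
  kd <- config$tet_knockdown
  for (i in seq_len(n)) {
    cls <- truth$true_class[i]
    if (!cls %in% c("Ad", "Ai", "Rd", "Ri")) next
    shp <- kinetic_shapes(truth$induction_fold[i], config$times)
    phi <- shp[truth$true_pattern[i], ]
    if (cls %in% c("Rd", "Ri")) phi <- 1 / phi
    phi_tet <- 1 + (phi - 1) * (1 - kd)
    t_idx <- match(design$time, config$times)
    use_tet <- design$tet == "plus"
    mu[i, ] <- base[i] * ifelse(use_tet, phi_tet[t_idx], phi[t_idx])
  }
  mu
}

#' Simulate the time-course count matrix
#'
#' Counts are negative binomial around class-specific mean trajectories.
#' Activated targets (Ad/Ai) carry their planted induction at `-Tet` which is
#' attenuated by `tet_knockdown` at `+Tet` in both clones; repressed targets
#' (Rd/Ri) are repressed at `-Tet` and de-repressed at `+Tet`; unaffected and
#' nonfunctional-bound genes share one mean across all conditions.
#' Log-normal library-size factors are applied so RPM normalization is
#' exercised non-trivially.  With `noise = "deterministic"` counts equal the
#' rounded expected means and library factors are 1.
#'
#' @param gene_models a [kb_genes] object.
#' @param truth output of [simulate_truth()]; must cover every gene.
#' @param config a [sim_config()] object.
#' @param design optional design table (defaults to [sim_design()]); every
#'   (cell line, Tet, time) cell must have at least 2 replicates.
#' @return a [kb_expression] object.
#' @export
simulate_expression <- function(gene_models, truth, config,
                                design = sim_design(config)) {
  if (!setequal(truth$gene_id, gene_models$genes$gene_id))
    stop("truth table must cover exactly the genes in gene_models")
  cell_tab <- table(paste(design$cell_line, design$tet, design$time,
                          sep = "/"))
  if (any(cell_tab < 2))
    stop("design cell(s) with < 2 replicates: ",
         paste(names(cell_tab)[cell_tab < 2], collapse = ", "))
  set.seed(config$seed + 2L)
  truth <- truth[match(gene_models$genes$gene_id, truth$gene_id), ]
  n <- nrow(truth)
  base <- exp(runif(n, config$base_mean_log_range[1],
                    config$base_mean_log_range[2]))
  mu <- .expected_means(gene_models, truth, config, design, base)

  if (config$noise == "deterministic") {
    counts <- round(mu)
  } else {
    lib <- rlnorm(nrow(design), 0, config$libsize_sdlog)
    mu <- sweep(mu, 2, lib, `*`)
    counts <- matrix(0L, n, nrow(design))
    if (config$nb_dispersion == 0) {
      counts[] <- rpois(length(mu), lambda = mu)
    } else {
      counts[] <- rnbinom(length(mu), mu = mu,
                          size = 1 / config$nb_dispersion)
    }
  }
  dimnames(counts) <- list(truth$gene_id, design$sample)
  kb_expression(counts, design)
}

#' Expression matrix container
#'
#' @param counts non-negative integer matrix, genes x samples.
#' @param samples sample metadata with columns `sample`, `cell_line`, `tet`,
#'   `time`, `replicate` matching `colnames(counts)`.
#' @return object of class `kb_expression`.
#' @export
kb_expression <- function(counts, samples) {
  stopifnot(is.matrix(counts), all(counts >= 0),
            identical(colnames(counts), samples$sample))
  obj <- list(counts = counts, samples = samples)
  class(obj) <- "kb_expression"
  obj
}

#' @export
print.kb_expression <- function(x, ...) {
  cat("kb_expression:", nrow(x$counts), "genes x", ncol(x$counts),
      "samples\n")
  invisible(x)
}

# place a position guaranteed intergenic (not within pad of any gene body)
.intergenic_positions <- function(gene_models, chrom, k, pad = 2000L) {
  g <- gene_models$genes[gene_models$genes$chrom == chrom, ]
  size <- gene_models$chrom_sizes[[chrom]]
  out <- integer(0)
  while (length(out) < k) {
    cand <- as.integer(runif(2L * k, 1, size))
    bad <- vapply(cand, function(p)
      any(p >= g$start - pad & p <= g$end + pad), logical(1))
    out <- c(out, cand[!bad])
  }
  out[seq_len(k)]
}

#' Simulate replicate ChIP peak sets
#'
#' Every direct-target (Ad/Rd) and nonfunctional-bound gene receives at least
#' one RELA peak at 1 h near its TSS (70% promoter-proximal, 30% intronic),
#' always present in replicate 1 and present in replicate 2 with probability
#' `replicate_reproducibility` (replicate-2 intervals are jittered by up to
#' 50 bp so the overlap filter is exercised).  A configurable fraction
#' persists at 4 h.  Pol II peaks are placed at 0 h on promoters of genes
#' with loop category II/III/IV.  Decoy intergenic peaks are added per
#' factor/time/replicate unless `decoys = FALSE`.
#'
#' @param gene_models a [kb_genes] object.
#' @param truth output of [simulate_truth()].
#' @param config a [sim_config()] object.
#' @return data.frame of peaks with columns `chrom`, `start`, `end`, `name`,
#'   `score`, `strand`, `factor`, `time`, `replicate` (1-based closed
#'   coordinates), plus a `planted_gene` column (`NA` for decoys).
#' @export
simulate_peaks <- function(gene_models, truth, config) {
  set.seed(config$seed + 3L)
  g <- gene_models$genes
  truth <- truth[match(g$gene_id, truth$gene_id), ]
  rows <- list()
  add <- function(chrom, start, end, score, factor, time, replicate, gene) {
    rows[[length(rows) + 1L]] <<- data.frame(
      chrom = chrom, start = as.integer(start), end = as.integer(end),
      score = score, factor = factor, time = time, replicate = replicate,
      planted_gene = gene, stringsAsFactors = FALSE)
  }
  plant <- function(idx, factor, time, center_fun) {
    for (i in idx) {
      ctr <- center_fun(i)
      w <- round(runif(1, config$peak_width_range[1],
                       config$peak_width_range[2]))
      s1 <- as.integer(ctr - w %/% 2); e1 <- s1 + w - 1L
      sc1 <- runif(1, config$planted_score_range[1],
                   config$planted_score_range[2])
      add(g$chrom[i], s1, e1, sc1, factor, time, 1L, g$gene_id[i])
      if (runif(1) <= config$replicate_reproducibility &&
          config$replicate_reproducibility > 0) {
        jit <- as.integer(round(runif(1, -50, 50)))
        sc2 <- runif(1, config$planted_score_range[1],
                     config$planted_score_range[2])
        add(g$chrom[i], s1 + jit, e1 + jit, sc2, factor, time, 2L,
            g$gene_id[i])
      }
    }
  }
  rela_idx <- which(truth$true_class %in%
                      c("Ad", "Rd", "nonfunctional_bound"))
  rela_center <- function(i) {
    if (runif(1) < 0.7) {
      off <- round(runif(1, -800, 200))
      if (g$strand[i] == "+") g$tss[i] + off else g$tss[i] - off
    } else {
      # intronic: between the two exons
      e <- gene_models$exons[gene_models$exons$gene_id == g$gene_id[i], ]
      as.integer(round(runif(1, min(e$end) + 50, max(e$start) - 50)))
    }
  }
  plant(rela_idx, "RELA", 1, rela_center)
  persist <- rela_idx[runif(length(rela_idx)) < 0.3]
  plant(persist, "RELA", 4, rela_center)

  polii_idx <- which(truth$true_loop_category %in% c("II", "III", "IV"))
  polii_center <- function(i)
    if (g$strand[i] == "+") g$tss[i] - 50L else g$tss[i] + 50L
  plant(polii_idx, "POLII", 0, polii_center)

  if (config$decoys && config$n_decoy_peaks > 0) {
    for (factor in c("RELA", "POLII")) for (time in config$times)
      for (rep in 1:2) {
        k <- config$n_decoy_peaks
        chrom <- sample(names(gene_models$chrom_sizes), k, replace = TRUE)
        for (chr in unique(chrom)) {
          kk <- sum(chrom == chr)
          pos <- .intergenic_positions(gene_models, chr, kk)
          w <- round(runif(kk, config$peak_width_range[1],
                           config$peak_width_range[2]))
          sc <- runif(kk, config$decoy_score_range[1],
                      config$decoy_score_range[2])
          for (j in seq_len(kk))
            add(chr, pos[j] - w[j] %/% 2, pos[j] + w[j] %/% 2, sc[j],
                factor, time, rep, NA_character_)
        }
      }
  }
  out <- do.call(rbind, rows)
  out$start <- pmax(1L, out$start)
  out$name <- sprintf("%s_%gh_rep%d_pk%05d", out$factor, out$time,
                      out$replicate, seq_len(nrow(out)))
  out$strand <- "."
  out[, c("chrom", "start", "end", "name", "score", "strand",
          "factor", "time", "replicate", "planted_gene")]
}

#' Subset a simulated peak table to one replicate peak set
#'
#' @param peaks data.frame from [simulate_peaks()] or [read_peaks_bed()].
#' @param factor,time,replicate selectors.
#' @return peak data.frame for a single factor/time/replicate.
#' @export
peak_subset <- function(peaks, factor, time, replicate) {
  out <- peaks[peaks$factor == factor & peaks$time == time &
                 peaks$replicate == replicate, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Simulate Pol II PET interaction clusters
#'
#' Category III genes receive one intra-gene cluster whose promoter-side
#' anchor overlaps the gene promoter and whose distal anchor sits at the
#' transcription end; category IV genes are paired within chromosomes into
#' promoter-promoter clusters touching two distinct genes.  Categories I-II
#' receive none.  PET counts are `2 + Poisson(pet_count_lambda)`; decoy
#' clusters (count 1, or high FDR) are appended unless `decoys = FALSE`.
#'
#' @param gene_models a [kb_genes] object.
#' @param truth output of [simulate_truth()].
#' @param config a [sim_config()] object.
#' @return data.frame with columns `chromA`, `startA`, `endA`, `chromB`,
#'   `startB`, `endB`, `name`, `pet_count`, `strandA`, `strandB`, `p`,
#'   `fdr` (1-based closed coordinates).
#' @export
simulate_interactions <- function(gene_models, truth, config) {
  set.seed(config$seed + 4L)
  g <- gene_models$genes
  truth <- truth[match(g$gene_id, truth$gene_id), ]
  rows <- list()
  add <- function(chrA, sA, eA, chrB, sB, eB, count, p, fdr) {
    # store anchors with A <= B by coordinate
    if (chrA > chrB || (chrA == chrB && sA > sB)) {
      tmp <- c(chrA, sA, eA); chrA <- chrB; sA <- sB; eA <- eB
      chrB <- tmp[1]; sB <- as.integer(tmp[2]); eB <- as.integer(tmp[3])
    }
    rows[[length(rows) + 1L]] <<- data.frame(
      chromA = chrA, startA = as.integer(sA), endA = as.integer(eA),
      chromB = chrB, startB = as.integer(sB), endB = as.integer(eB),
      pet_count = as.integer(count), p = p, fdr = fdr,
      stringsAsFactors = FALSE)
  }
  prom_anchor <- function(i)
    c(g$tss[i] - 200L, g$tss[i] + 199L)
  for (i in which(truth$true_loop_category == "III")) {
    # promoter-side anchor inside the gene span, distal anchor at the TTS
    if (g$strand[i] == "+") {
      a <- c(g$tss[i], g$tss[i] + 399L); b <- c(g$tts[i] - 399L, g$tts[i])
    } else {
      a <- c(g$tss[i] - 399L, g$tss[i]); b <- c(g$tts[i], g$tts[i] + 399L)
    }
    add(g$chrom[i], a[1], a[2], g$chrom[i], b[1], b[2],
        2L + rpois(1, config$pet_count_lambda), 1e-6, 1e-4)
  }
  for (chr in unique(g$chrom)) {
    iv <- which(truth$true_loop_category == "IV" & g$chrom == chr)
    if (length(iv) == 0) next
    stopifnot(length(iv) %% 2 == 0)
    for (k in seq(1, length(iv), by = 2)) {
      i <- iv[k]; j <- iv[k + 1]
      a <- prom_anchor(i); b <- prom_anchor(j)
      add(chr, a[1], a[2], chr, b[1], b[2],
          2L + rpois(1, config$pet_count_lambda), 1e-6, 1e-4)
    }
  }
  if (config$decoys && config$n_loop_decoys > 0) {
    for (d in seq_len(config$n_loop_decoys)) {
      chr <- sample(names(gene_models$chrom_sizes), 1)
      pos <- .intergenic_positions(gene_models, chr, 2L)
      low_count <- runif(1) < 0.5
      add(chr, pos[1] - 200L, pos[1] + 199L, chr, pos[2] - 200L,
          pos[2] + 199L,
          if (low_count) 1L else 2L + rpois(1, config$pet_count_lambda),
          0.5, if (low_count) 0.5 else 0.6)
    }
  }
  out <- do.call(rbind, rows)
  out$startA <- pmax(1L, out$startA); out$startB <- pmax(1L, out$startB)
  out$name <- sprintf("pet%05d", seq_len(nrow(out)))
  out$strandA <- "."; out$strandB <- "."
  out[, c("chromA", "startA", "endA", "chromB", "startB", "endB",
          "name", "pet_count", "strandA", "strandB", "p", "fdr")]
}

#' Simulate promoter sequences for human and ortholog species
#'
#' Generates, per gene, the coding-strand sequence of the window
#' TSS-1000 .. TSS+100 (so both the 1-kb upstream conservation window and
#' the -400..+100 scan window are substrings).  Direct-target (Ad/Rd)
#' promoters carry 1-3 planted kB sites: the PWM consensus, at recorded
#' 0-based offsets within the upstream 1-kb window, on a random strand.
#' Ortholog sequences apply i.i.d. substitutions at the per-species
#' divergence rate; planted sites evolve neutrally, are spared, or are
#' scrambled according to `site_fate`.
#'
#' @param gene_models a [kb_genes] object.
#' @param truth output of [simulate_truth()].
#' @param pwm a `kb_pwm` object whose consensus is planted (default: the
#'   RELA-like member of [kb_motif_library()]).
#' @param config a [sim_config()] object.
#' @return object of class `kb_promoters`: list with `seqs` (per-species
#'   named character vectors of 1100-bp sequences), `sites` (data.frame
#'   `gene_id`, `offset` (0-based in the upstream 1-kb window), `strand`,
#'   `width`) and `species`.
#' @export
simulate_promoters <- function(gene_models, truth,
                               pwm = kb_motif_library()[["RELA"]],
                               config) {
  set.seed(config$seed + 5L)
  g <- gene_models$genes
  truth <- truth[match(g$gene_id, truth$gene_id), ]
  n <- nrow(g)
  up <- 1000L; down <- 100L; len <- up + down
  lim <- gene_models$chrom_sizes[g$chrom]
  plus <- g$strand == "+"
  too_low <- ifelse(plus, g$tss - up < 1, g$tss + up > lim)
  too_high <- ifelse(plus, g$tss + down > lim, g$tss - down < 1)
  if (any(too_low | too_high))
    stop("promoter window escapes chromosome bounds for gene(s): ",
         paste(g$gene_id[too_low | too_high], collapse = ", "))

  bases <- c("A", "C", "G", "T")
  consensus <- pwm_consensus(pwm)
  w <- nchar(consensus)
  seq_mat <- matrix(sample(bases, n * len, replace = TRUE), nrow = n)

  site_rows <- list()
  target <- which(truth$true_class %in% c("Ad", "Rd"))
  for (i in target) {
    k <- sample(seq(config$sites_per_target_range[1],
                    config$sites_per_target_range[2]), 1)
    offs <- integer(0)
    for (s in seq_len(k)) {
      repeat {
        o <- sample(0:(up - w), 1)  # 0-based offset in the 1-kb window
        if (all(abs(o - offs) >= w + 5L)) break
      }
      offs <- c(offs, o)
      strand <- sample(c("+", "-"), 1)
      site <- if (strand == "+") consensus else revcomp(consensus)
      seq_mat[i, (o + 1):(o + w)] <- strsplit(site, "")[[1]]
      site_rows[[length(site_rows) + 1L]] <- data.frame(
        gene_id = g$gene_id[i], offset = o, strand = strand, width = w,
        stringsAsFactors = FALSE)
    }
  }
  sites <- if (length(site_rows)) do.call(rbind, site_rows) else
    data.frame(gene_id = character(), offset = integer(),
               strand = character(), width = integer())

  human <- apply(seq_mat, 1, paste, collapse = "")
  names(human) <- g$gene_id
  seqs <- list(human = human)
  for (sp in names(config$divergence)) {
    r <- config$divergence[[sp]]
    sp_mat <- seq_mat
    for (i in seq_len(n)) {
      u <- runif(len)
      pick <- runif(len)  # drawn unconditionally: common random numbers
      mut <- which(u < r)
      if (config$site_fate == "spare" && nrow(sites)) {
        s_i <- sites[sites$gene_id == g$gene_id[i], ]
        if (nrow(s_i)) {
          protected <- unlist(lapply(seq_len(nrow(s_i)), function(j)
            (s_i$offset[j] + 1):(s_i$offset[j] + s_i$width[j])))
          mut <- setdiff(mut, protected)
        }
      }
      if (length(mut)) {
        for (p in mut) {
          alt <- bases[bases != sp_mat[i, p]]
          sp_mat[i, p] <- alt[ceiling(pick[p] * 3)]
        }
      }
      if (config$site_fate == "destroy" && nrow(sites)) {
        s_i <- sites[sites$gene_id == g$gene_id[i], ]
        if (nrow(s_i)) for (j in seq_len(nrow(s_i))) {
          idx <- (s_i$offset[j] + 1):(s_i$offset[j] + s_i$width[j])
          sp_mat[i, idx] <- sample(bases, length(idx), replace = TRUE)
        }
      }
    }
    sp_seq <- apply(sp_mat, 1, paste, collapse = "")
    names(sp_seq) <- g$gene_id
    seqs[[sp]] <- sp_seq
  }
  obj <- list(seqs = seqs, sites = sites,
              species = names(config$divergence),
              upstream = up, downstream = down)
  class(obj) <- "kb_promoters"
  obj
}

#' @export
print.kb_promoters <- function(x, ...) {
  cat("kb_promoters:", length(x$seqs$human), "genes,",
      length(x$seqs) - 1L, "ortholog species,",
      nrow(x$sites), "planted sites\n")
  invisible(x)
}

#' Extract promoter sequences for a window
#'
#' @param promoters a `kb_promoters` object.
#' @param species species name (`"human"` or an ortholog).
#' @param window `"conservation"` (upstream 1 kb, TSS-1000..TSS-1),
#'   `"scan"` (TSS-400..TSS+100) or `"full"` (TSS-1000..TSS+100).
#' @return named character vector of sequences.
#' @export
promoter_seqs <- function(promoters, species = "human",
                          window = c("conservation", "scan", "full")) {
  window <- match.arg(window)
  s <- promoters$seqs[[species]]
  if (is.null(s)) stop("unknown species: ", species)
  up <- promoters$upstream
  switch(window,
         conservation = substr(s, 1L, up),
         scan = substr(s, up - 400L + 1L, up + promoters$downstream),
         full = s)
}

#' Simulate a complete dataset
#'
#' Runs every generator with sub-seeds derived from `config$seed` and bundles
#' the results with the ground truth.
#'
#' @param config a [sim_config()] object.
#' @return object of class `kb_sim`: list with `config`, `gene_models`,
#'   `truth`, `expression`, `peaks`, `interactions`, `promoters`,
#'   `pwm_library`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  gene_models <- generate_gene_models(config)
  truth <- simulate_truth(gene_models, config)
  expression <- simulate_expression(gene_models, truth, config)
  peaks <- simulate_peaks(gene_models, truth, config)
  interactions <- simulate_interactions(gene_models, truth, config)
  pwms <- kb_motif_library()
  promoters <- simulate_promoters(gene_models, truth, pwms[["RELA"]],
                                  config)
  obj <- list(config = config, gene_models = gene_models, truth = truth,
              expression = expression, peaks = peaks,
              interactions = interactions, promoters = promoters,
              pwm_library = pwms)
  class(obj) <- "kb_sim"
  obj
}

#' @export
print.kb_sim <- function(x, ...) {
  cat("kb_sim dataset:", nrow(x$truth), "genes; class counts:\n")
  print(table(x$truth$true_class))
  invisible(x)
}
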