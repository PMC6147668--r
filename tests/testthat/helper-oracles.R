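# Independent oracles, deliberately written in a different style from the
# package implementations (gene-by-gene loops, no shared code paths).

# Brute-force Benjamini-Hochberg: q_i = min_{j: p_j >= p_i ranked} p_(j)*n/j
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- numeric(n)
  for (i in seq_len(n)) {
    rank_i <- which(o == i)
    cand <- numeric(0)
    for (j in rank_i:n) cand <- c(cand, p[o[j]] * n / j)
    q[i] <- min(1, min(cand))
  }
  q
}

# Set-algebra re-implementation of the taxonomy rules, one gene at a time.
# panel: kb_contrast_panel; rela: character vector of bound genes.
oracle_classify <- function(panel, rela, fdr = 0.05) {
  con <- panel$contrasts
  ids <- con$parental[[1]]$gene_id
  out <- character(length(ids))
  for (g in seq_along(ids)) {
    id <- ids[g]
    row <- function(tab) tab[tab$gene_id == id, ]
    reduced <- FALSE; increased <- FALSE; any_sig <- FALSE
    for (t in as.character(panel$times)) {
      r1 <- row(con$clone1[[t]]); r2 <- row(con$clone2[[t]])
      s1 <- r1$fdr <= fdr; s2 <- r2$fdr <= fdr
      if (s1) any_sig <- TRUE
      if (s2) any_sig <- TRUE
      if (s1 && s2 && r1$log2FC < 0 && r2$log2FC < 0) reduced <- TRUE
      if (s1 && s2 && r1$log2FC > 0 && r2$log2FC > 0) increased <- TRUE
    }
    for (t in as.character(panel$times))
      if (row(con$parental[[t]])$fdr <= fdr) any_sig <- TRUE
    bound <- id %in% rela
    out[g] <-
      if (reduced && !increased) { if (bound) "Ad" else "Ai" }
      else if (increased && !reduced) { if (bound) "Rd" else "Ri" }
      else if (!any_sig) { if (bound) "nonfunctional_bound" else "unaffected" }
      else "other"
  }
  data.frame(gene_id = ids, class = out, stringsAsFactors = FALSE)
}

# robust flag, re-derived independently
oracle_robust <- function(classes, panel, threshold = 2) {
  con <- panel$contrasts$parental
  vapply(seq_len(nrow(classes)), function(g) {
    id <- classes$gene_id[g]
    if (!classes$class[g] %in% c("Ad", "Ai", "Rd", "Ri")) return(FALSE)
    big <- FALSE
    for (t in as.character(panel$times)) {
      tab <- con[[t]]
      if (abs(tab$log2FC[tab$gene_id == id]) >= log2(threshold))
        big <- TRUE
    }
    big
  }, logical(1))
}

# putative targets by literal set intersection
oracle_putative <- function(panel, rela, fc_threshold = 2) {
  con <- panel$contrasts$parental
  ids <- con[[1]]$gene_id
  up <- character(0); down <- character(0)
  for (id in ids) {
    for (t in as.character(panel$times)) {
      lfc <- con[[t]]$log2FC[con[[t]]$gene_id == id]
      if (lfc >= log2(fc_threshold)) up <- union(up, id)
      if (lfc <= -log2(fc_threshold)) down <- union(down, id)
    }
  }
  list(bound_up = intersect(up, rela), bound_down = intersect(down, rela))
}

# exhaustive global alignment score by recursion (tiny inputs only)
oracle_nw_score <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  rec <- function(i, j) {
    if (i == 0 && j == 0) return(0)
    best <- -Inf
    if (i > 0 && j > 0)
      best <- max(best, rec(i - 1, j - 1) +
                    if (av[i] == bv[j]) match else mismatch)
    if (i > 0) best <- max(best, rec(i - 1, j) + gap)
    if (j > 0) best <- max(best, rec(i, j - 1) + gap)
    best
  }
  rec(length(av), length(bv))
}

# best label agreement over all permutations of cluster ids (k <= 7)
best_label_agreement <- function(labels, truth_labels) {
  ks <- sort(unique(truth_labels))
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  best <- 0
  for (p in perms(ks)) {
    mapped <- p[match(labels, ks)]
    best <- max(best, mean(mapped == truth_labels))
  }
  best
}

# textbook Kruskal-Wallis H (no tie correction needed for distinct values)
oracle_kruskal_h <- function(groups) {
  x <- unlist(groups)
  n <- length(x)
  r <- rank(x)
  idx <- rep(seq_along(groups), vapply(groups, length, 1L))
  h <- 0
  for (g in seq_along(groups)) {
    rg <- sum(r[idx == g])
    ng <- sum(idx == g)
    h <- h + rg^2 / ng
  }
  12 / (n * (n + 1)) * h - 3 * (n + 1)
}
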