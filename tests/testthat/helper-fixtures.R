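# Small fixture builders shared across the test files.

peak_df <- function(start, end, score, chrom = "chr1", factor = "RELA",
                    time = 1, replicate = 1) {
  n <- length(start)
  data.frame(chrom = rep(chrom, n), start = start, end = end,
             name = sprintf("pk%03d", seq_len(n)), score = score,
             strand = ".", factor = factor, time = time,
             replicate = replicate, stringsAsFactors = FALSE)
}

# two hand-built genes (one per strand) with known exon/UTR structure
tiny_gene_models <- function() {
  genes <- data.frame(
    gene_id = c("GA", "GB"),
    chrom = "chr1",
    start = c(10000L, 100000L),
    end = c(19999L, 109999L),
    strand = c("+", "-"),
    tss = c(10000L, 109999L),
    tts = c(19999L, 100000L),
    utr5_len = c(200L, 200L),
    utr3_len = c(300L, 300L),
    stringsAsFactors = FALSE)
  exons <- data.frame(
    gene_id = c("GA", "GA", "GB", "GB"),
    rank = c(1L, 2L, 1L, 2L),
    start = c(10000L, 16000L, 106000L, 100000L),
    end = c(13999L, 19999L, 109999L, 103999L))
  kb_genes(genes, exons, c(chr1 = 200000L))
}

# build a contrast panel directly from per-contrast (log2FC, fdr) vectors;
# each of lfc/fdr is a list with elements parental/clone1/clone2, each a
# list keyed by time ("1", "4") of per-gene vectors
make_panel <- function(gene_ids, lfc, fdr, times = c(1, 4)) {
  tab <- function(l, f)
    data.frame(gene_id = gene_ids, log2FC = l, p = f, fdr = f,
               stringsAsFactors = FALSE)
  contrasts <- list()
  for (arm in c("parental", "clone1", "clone2")) {
    contrasts[[arm]] <- list()
    for (t in as.character(times))
      contrasts[[arm]][[t]] <- tab(lfc[[arm]][[t]], fdr[[arm]][[t]])
  }
  structure(list(contrasts = contrasts, times = times, fdr = 0.05),
            class = "kb_contrast_panel")
}

# a panel where every contrast is null except as overridden;
# overrides: list of list(arm=, time=, gene=, lfc=, fdr=)
null_panel <- function(gene_ids, overrides = list(), times = c(1, 4)) {
  base_l <- base_f <- list()
  for (arm in c("parental", "clone1", "clone2")) {
    base_l[[arm]] <- base_f[[arm]] <- list()
    for (t in as.character(times)) {
      base_l[[arm]][[t]] <- rep(0, length(gene_ids))
      base_f[[arm]][[t]] <- rep(1, length(gene_ids))
    }
  }
  for (ov in overrides) {
    i <- match(ov$gene, gene_ids)
    base_l[[ov$arm]][[as.character(ov$time)]][i] <- ov$lfc
    base_f[[ov$arm]][[as.character(ov$time)]][i] <- ov$fdr
  }
  make_panel(gene_ids, base_l, base_f, times)
}

# random contrast panel for oracle-equivalence fuzzing
random_panel <- function(n_genes, seed) {
  set.seed(seed)
  ids <- sprintf("G%04d", seq_len(n_genes))
  l <- f <- list()
  for (arm in c("parental", "clone1", "clone2")) {
    l[[arm]] <- f[[arm]] <- list()
    for (t in c("1", "4")) {
      l[[arm]][[t]] <- round(rnorm(n_genes, 0, 1.5), 2)
      f[[arm]][[t]] <- round(runif(n_genes)^2, 3)
    }
  }
  make_panel(ids, l, f)
}

# trajectories from the 6 canonical shapes with multiplicative noise
shape_trajectories <- function(per_shape = 100, fold = 8, sdlog = 0.05,
                               seed = 1) {
  set.seed(seed)
  shapes <- kinetic_shapes(fold)
  traj <- do.call(rbind, lapply(1:6, function(p)
    matrix(rep(shapes[p, ], each = per_shape), nrow = per_shape) *
      matrix(rlnorm(per_shape * 3, 0, sdlog), nrow = per_shape)))
  rownames(traj) <- sprintf("g%03d", seq_len(nrow(traj)))
  list(traj = traj, truth = rep(1:6, each = per_shape))
}
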