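# Synthetic-data generator: determinism, gene packing, planted expression
# effects, peak reproducibility and promoter divergence.

test_that("fixing the seed fixes every generated output", {
  cfg <- sim_config(n_genes = 40, seed = 11)
  s1 <- simulate_dataset(cfg)
  s2 <- simulate_dataset(cfg)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$expression$counts, s2$expression$counts)
  expect_identical(s1$peaks, s2$peaks)
  expect_identical(s1$interactions, s2$interactions)
  expect_identical(s1$promoters$seqs, s2$promoters$seqs)
  g1 <- tempfile(fileext = ".gtf"); g2 <- tempfile(fileext = ".gtf")
  write_gtf(s1$gene_models, g1); write_gtf(s2$gene_models, g2)
  expect_identical(readLines(g1), readLines(g2))
})

test_that("gene models are packed without overlap, strand-consistently", {
  gm <- generate_gene_models(sim_config(n_genes = 1, seed = 1))
  expect_equal(nrow(gm$genes), 1)
  expect_true(nrow(promoter_windows(gm, "annotation")) == 1)

  gm <- generate_gene_models(sim_config(n_genes = 200, seed = 2))
  g <- gm$genes
  for (chr in unique(g$chrom)) {
    gc <- g[g$chrom == chr, ]
    gc <- gc[order(gc$start), ]
    expect_true(all(gc$start[-1] > gc$end[-nrow(gc)]))
  }
  plus <- g$strand == "+"
  expect_true(all(g$tss[plus] < g$tts[plus]))
  expect_true(all(g$tss[!plus] > g$tts[!plus]))
  # promoter windows sit upstream in stranded orientation
  prom <- promoter_windows(gm, "conservation")
  expect_true(all(prom$end[plus] == g$tss[plus] - 1))
  expect_true(all(prom$start[!plus] == g$tss[!plus] + 1))
})

test_that("infeasible packing raises an explicit error", {
  expect_error(
    generate_gene_models(sim_config(n_genes = 100, chrom_length = 2e5)),
    "infeasible packing")
})

test_that("promoter windows of minus-strand genes mirror the plus rule", {
  gm <- generate_gene_models(sim_config(n_genes = 5, seed = 3))
  g <- gm$genes
  prom <- promoter_windows(gm, "annotation")
  for (i in seq_len(5)) {
    if (g$strand[i] == "+") {
      expect_equal(prom$start[i], g$tss[i] - 1000)
      expect_equal(prom$end[i], g$tss[i] + 100)
    } else {
      expect_equal(prom$start[i], g$tss[i] - 100)
      expect_equal(prom$end[i], g$tss[i] + 1000)
    }
  }
})

test_that("unaffected genes share one mean across all conditions", {
  cfg <- sim_config(n_genes = 4, seed = 5, nb_dispersion = 0,
                    libsize_sdlog = 0,
                    base_mean_log_range = c(log(100), log(100)),
                    class_probs = c(Ad = 0, Ai = 0, Rd = 0, Ri = 0,
                                    nonfunctional_bound = 0,
                                    unaffected = 1),
                    n_replicates = 40)
  gm <- generate_gene_models(cfg)
  truth <- simulate_truth(gm, cfg)
  ex <- simulate_expression(gm, truth, cfg)
  # 600 Poisson draws per gene around the planted mean of 100
  n <- ncol(ex$counts)
  se <- sqrt(100 / n)
  expect_true(all(abs(rowMeans(ex$counts) - 100) < 3 * se))
  # per-condition means agree within Poisson noise
  s <- ex$samples
  for (t in c(0, 1, 4)) {
    cols <- s$sample[s$time == t]
    m <- rowMeans(ex$counts[, cols, drop = FALSE])
    expect_true(all(abs(m - 100) < 4 * sqrt(100 / length(cols))))
  }
})

test_that("a transient direct target is induced at 1 h and attenuated by Tet", {
  cfg <- sim_config(n_genes = 2, seed = 6, nb_dispersion = 0.05,
                    libsize_sdlog = 0, n_replicates = 40,
                    base_mean_log_range = c(log(200), log(200)))
  gm <- generate_gene_models(cfg)
  truth <- data.frame(gene_id = gm$genes$gene_id,
                      true_class = c("Ad", "unaffected"),
                      true_pattern = c(3L, NA),
                      true_loop_category = "I",
                      induction_fold = c(8, 1),
                      stringsAsFactors = FALSE)
  ex <- simulate_expression(gm, truth, cfg)
  s <- ex$samples
  m <- function(cell, tet, t)
    mean(ex$counts[1, s$sample[s$cell_line == cell & s$tet == tet &
                                 s$time == t]])
  expect_equal(m("parental", "minus", 1) / m("parental", "minus", 0), 8,
               tolerance = 0.15)
  expect_lt(m("parental", "minus", 4), m("parental", "minus", 1) / 2)
  # complete knockdown: no induction under Tet, in both clones
  for (cl in c("clone1", "clone2"))
    expect_equal(m(cl, "plus", 1) / m(cl, "plus", 0), 1, tolerance = 0.15)
})

test_that("missing design cells are reported by name", {
  cfg <- sim_config(n_genes = 3, seed = 1)
  gm <- generate_gene_models(cfg)
  truth <- simulate_truth(gm, cfg)
  des <- sim_design(cfg)
  broken <- des[!(des$cell_line == "clone1" & des$tet == "plus" &
                    des$time == 4 & des$replicate == 2), ]
  expect_error(simulate_expression(gm, truth, cfg, design = broken),
               "clone1/plus/4")
})

test_that("repressed targets are de-repressed by the perturbation", {
  cfg <- sim_config(n_genes = 2, seed = 8, nb_dispersion = 0,
                    libsize_sdlog = 0, n_replicates = 20,
                    base_mean_log_range = c(log(400), log(400)))
  gm <- generate_gene_models(cfg)
  truth <- data.frame(gene_id = gm$genes$gene_id,
                      true_class = c("Rd", "unaffected"),
                      true_pattern = c(2L, NA),
                      true_loop_category = "I",
                      induction_fold = c(4, 1), stringsAsFactors = FALSE)
  ex <- simulate_expression(gm, truth, cfg)
  s <- ex$samples
  m <- function(tet, t)
    mean(ex$counts[1, s$sample[s$cell_line == "clone1" & s$tet == tet &
                                 s$time == t]])
  expect_lt(m("minus", 4), m("plus", 4) / 2)   # repression relieved by Tet
  expect_equal(m("plus", 0), m("minus", 0), tolerance = 0.1)  # basal spared
})

test_that("replicate reproducibility controls the retained peak fraction", {
  mk <- function(repro, n = 1000, seed = 21) {
    cfg <- sim_config(n_genes = n, seed = seed, decoys = FALSE,
                      replicate_reproducibility = repro,
                      class_probs = c(Ad = 1, Ai = 0, Rd = 0, Ri = 0,
                                      nonfunctional_bound = 0,
                                      unaffected = 0))
    gm <- generate_gene_models(cfg)
    truth <- simulate_truth(gm, cfg)
    pk <- simulate_peaks(gm, truth, cfg)
    rep1 <- peak_subset(pk, "RELA", 1, 1)
    kept <- filter_reproducible(rep1, peak_subset(pk, "RELA", 1, 2))
    c(planted = nrow(rep1), kept = nrow(kept))
  }
  r1 <- mk(1, n = 200)
  expect_equal(unname(r1["kept"]), unname(r1["planted"]))
  r0 <- mk(0, n = 200)
  expect_equal(unname(r0["kept"]), 0)
  r5 <- mk(0.5, n = 1000)
  frac <- r5["kept"] / r5["planted"]
  ci_half <- qnorm(0.995) * sqrt(0.25 / r5["planted"])
  expect_lt(abs(frac - 0.5), ci_half)
})

test_that("interaction records encode the planted loop architecture", {
  cfg <- sim_config(n_genes = 1, seed = 2, decoys = FALSE)
  gm <- generate_gene_models(cfg)
  truth <- data.frame(gene_id = gm$genes$gene_id, true_class = "unaffected",
                      true_pattern = NA_integer_,
                      true_loop_category = "III", induction_fold = 1,
                      stringsAsFactors = FALSE)
  ints <- simulate_interactions(gm, truth, cfg)
  expect_equal(nrow(ints), 1)
  g <- gm$genes
  expect_true(ints$startA >= min(g$start, g$end) - 400 &&
                ints$endB <= max(g$start, g$end) + 400)

  cfg2 <- sim_config(n_genes = 2, seed = 2, decoys = FALSE,
                     chrom_names = "chr1")
  gm2 <- generate_gene_models(cfg2)
  truth2 <- data.frame(gene_id = gm2$genes$gene_id,
                       true_class = "unaffected",
                       true_pattern = NA_integer_,
                       true_loop_category = "IV", induction_fold = 1,
                       stringsAsFactors = FALSE)
  ints2 <- simulate_interactions(gm2, truth2, cfg2)
  expect_equal(nrow(ints2), 1)
  prom <- promoter_windows(gm2, "annotation")
  overlaps <- function(s, e, row)
    s <= prom$end[row] & e >= prom$start[row]
  expect_true(overlaps(ints2$startA, ints2$endA, 1) ||
                overlaps(ints2$startB, ints2$endB, 1))
  expect_true(overlaps(ints2$startA, ints2$endA, 2) ||
                overlaps(ints2$startB, ints2$endB, 2))
})

test_that("ortholog divergence behaves as a substitution probability", {
  cfg0 <- sim_config(n_genes = 10, seed = 9,
                     divergence = c(mouse = 0))
  gm <- generate_gene_models(cfg0)
  truth <- simulate_truth(gm, cfg0)
  pr0 <- simulate_promoters(gm, truth, config = cfg0)
  expect_identical(pr0$seqs$human, pr0$seqs$mouse)

  # substitutions go to one of the three other bases, so identity ~ 1 - r
  cfg1 <- sim_config(n_genes = 10, seed = 9, divergence = c(mouse = 1))
  pr1 <- simulate_promoters(gm, truth, config = cfg1)
  ident <- mapply(function(a, b) {
    va <- strsplit(a, "")[[1]]; vb <- strsplit(b, "")[[1]]
    mean(va == vb)
  }, pr1$seqs$human, pr1$seqs$mouse)
  expect_true(all(ident == 0))

  cfg5 <- sim_config(n_genes = 10, seed = 9, divergence = c(mouse = 0.5))
  pr5 <- simulate_promoters(gm, truth, config = cfg5)
  ident5 <- mean(mapply(function(a, b)
    mean(strsplit(a, "")[[1]] == strsplit(b, "")[[1]]),
    pr5$seqs$human, pr5$seqs$mouse))
  n_bases <- 10 * 1100
  expect_lt(abs(ident5 - 0.5), qnorm(0.995) * sqrt(0.25 / n_bases))
})

test_that("planted consensus sites are recovered by the scanner", {
  cfg <- sim_config(n_genes = 20, seed = 13)
  gm <- generate_gene_models(cfg)
  truth <- simulate_truth(gm, cfg)
  pwm <- kb_motif_library()[["RELA"]]
  pr <- simulate_promoters(gm, truth, pwm, cfg)
  expect_gt(nrow(pr$sites), 0)
  human <- promoter_seqs(pr, "human", "conservation")
  for (k in seq_len(nrow(pr$sites))) {
    hits <- scan_motif(human[[pr$sites$gene_id[k]]], pwm,
                       rel_threshold = 0.99)
    expect_true(pr$sites$offset[k] %in% hits$offset)
  }
})

test_that("class proportions follow the configured multinomial", {
  cfg <- sim_config(n_genes = 2000, seed = 17)
  gm <- generate_gene_models(cfg)
  truth <- simulate_truth(gm, cfg)
  tab <- table(truth$true_class)
  for (cls in names(cfg$class_probs)) {
    p <- cfg$class_probs[[cls]]
    se <- sqrt(p * (1 - p) / 2000)
    expect_lt(abs(tab[[cls]] / 2000 - p), 4 * se + 1e-9)
  }
  expect_equal(sum(tab), 2000)
  expect_false(anyDuplicated(truth$gene_id) > 0)
})
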