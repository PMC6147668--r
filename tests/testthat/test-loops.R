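# PET filtering, replicate overlap, Pol II status, loop categories,
# baseline-by-category statistics and the metagene profile.

interaction_df <- function(startA, endA, startB, endB, pet_count,
                           p = NULL, fdr = NULL, chrom = "chr1") {
  n <- length(startA)
  out <- data.frame(chromA = chrom, startA = startA, endA = endA,
                    chromB = chrom, startB = startB, endB = endB,
                    name = sprintf("pet%03d", seq_len(n)),
                    pet_count = pet_count, strandA = ".", strandB = ".",
                    stringsAsFactors = FALSE)
  if (!is.null(p)) { out$p <- p; out$fdr <- fdr }
  out
}

test_that("PET filter enforces count and FDR thresholds", {
  x <- interaction_df(c(100, 300, 500), c(200, 400, 600),
                      c(1000, 1300, 1500), c(1100, 1400, 1600),
                      pet_count = c(1, 5, 4),
                      p = c(0.001, 0.001, 0.2), fdr = c(0.01, 0.01, 0.3))
  out <- filter_pet_clusters(x)
  expect_equal(out$name, "pet002")   # count 1 and FDR 0.3 removed
})

test_that("a 50-cluster toy file filters exactly like the hand-coded rule", {
  set.seed(51)
  n <- 50
  x <- interaction_df(startA = seq(1000, by = 2000, length.out = n),
                      endA = seq(1400, by = 2000, length.out = n),
                      startB = seq(501000, by = 2000, length.out = n),
                      endB = seq(501400, by = 2000, length.out = n),
                      pet_count = sample(1:8, n, TRUE),
                      p = runif(n), fdr = runif(n))
  out <- filter_pet_clusters(x, min_count = 2, max_fdr = 0.05)
  keep <- character(0)                     # independent hand filter
  for (i in seq_len(n))
    if (x$pet_count[i] >= 2 && x$fdr[i] <= 0.05)
      keep <- c(keep, x$name[i])
  expect_identical(out$name, keep)
})

test_that("missing FDR triggers the random-ligation binomial model", {
  # two anchors ligated 40 times out of 50 total: far above expectation
  x <- interaction_df(startA = c(1000, 9000, 17000, 25000),
                      endA = c(1400, 9400, 17400, 25400),
                      startB = c(101000, 109000, 117000, 125000),
                      endB = c(101400, 109400, 117400, 125400),
                      pet_count = c(40, 2, 2, 2))
  out <- filter_pet_clusters(x)
  expect_true(all(c("p", "fdr") %in% names(out)))
  expect_true("pet001" %in% out$name)
  # a cluster as frequent as chance expects is not significant:
  # one anchor pair carrying almost all tags has expectation ~ n
  y <- interaction_df(startA = c(1000, 1000), endA = c(1400, 1400),
                      startB = c(101000, 109000),
                      endB = c(101400, 109400),
                      pet_count = c(90, 2))
  outy <- filter_pet_clusters(y)
  expect_false("pet001" %in% outy$name)
})

test_that("malformed BEDPE rows are reported with their line number", {
  f <- tempfile(fileext = ".bedpe")
  writeLines(c("chr1\t0\t100\tchr1\t500\t600\tpet1\t3\t.\t.",
               "chr1\t0\t100\tchr1\t500\tBAD\tpet2\t3\t.\t.",
               "chr1\t0\t100\tchr1\t500\t600\tpet3\t2\t.\t."), f)
  expect_error(read_bedpe(f), "line 2")
  writeLines(c("chr1\t0\t100\tchr1\t500\t600\tpet1\t3"), f)
  expect_equal(nrow(read_bedpe(f)), 1)
  writeLines(c("chr1\t0\t100\tchr1"), f)
  expect_error(read_bedpe(f), "line 1")
})

test_that("replicate overlap matches its definition", {
  a <- interaction_df(c(100, 5000), c(400, 5400),
                      c(100000, 105000), c(100400, 105400), c(3, 3))
  expect_equal(replicate_overlap(a, a), 1)
  b <- a; b$chromA <- b$chromB <- "chr2"
  expect_equal(replicate_overlap(a, b), 0)
  # half-shared: second A-cluster has no B partner
  b2 <- a[1, , drop = FALSE]
  expect_equal(replicate_overlap(a, b2), 0.5)
})

test_that("Pol II promoter status requires promoter-window overlap", {
  gm <- tiny_gene_models()
  spanning <- peak_df(9900, 10100, 300, factor = "POLII", time = 0)
  st <- promoter_polII_status(spanning, gm)
  expect_true(st[["GA"]])
  expect_false(st[["GB"]])
  upstream <- peak_df(4900, 5100, 300, factor = "POLII", time = 0)
  st2 <- promoter_polII_status(upstream, gm)
  expect_false(st2[["GA"]])   # 5 kb upstream is outside -1 kb .. +100 bp
})

test_that("loop categories recover the planted truth without decoys", {
  cfg <- sim_config(n_genes = 150, seed = 61, decoys = FALSE)
  sim <- simulate_dataset(cfg)
  repro <- reproducible_peak_sets(sim$peaks)
  polii <- promoter_polII_status(repro[["POLII_0h"]], sim$gene_models)
  filt <- filter_pet_clusters(sim$interactions)
  ls <- categorize_loops(sim$gene_models, filt, polii)
  truth <- sim$truth[match(ls$gene_id, sim$truth$gene_id), ]
  expect_identical(ls$category, truth$true_loop_category)
  # Pol II status is true exactly for categories II-IV
  expect_identical(unname(polii[truth$gene_id]),
                   truth$true_loop_category %in% c("II", "III", "IV"))
  # order invariance
  perm <- filt[rev(seq_len(nrow(filt))), ]
  ls2 <- categorize_loops(sim$gene_models, perm, polii)
  expect_identical(ls2$category, ls$category)
  # categories partition the genes; I and II carry no loops
  expect_true(all(ls$category %in% c("I", "II", "III", "IV")))
})

test_that("single- and multi-gene loop calls follow the anchor rules", {
  gm <- tiny_gene_models()
  polii <- setNames(c(TRUE, TRUE), c("GA", "GB"))
  # intra-gene loop on GA only
  intra <- interaction_df(10000, 10400, 19000, 19400, 3,
                          p = 1e-5, fdr = 1e-4)
  ls <- categorize_loops(gm, intra, polii)
  expect_equal(ls$category, c("III", "II"))
  # promoter-promoter loop joining both genes: both IV
  multi <- interaction_df(9800, 10200, 109800, 110200, 3,
                          p = 1e-5, fdr = 1e-4)
  ls2 <- categorize_loops(gm, multi, polii)
  expect_equal(ls2$category, c("IV", "IV"))
  # a gene with both loop types is IV (multi dominates)
  ls3 <- categorize_loops(gm, rbind(intra, multi), polii)
  expect_equal(ls3$category, c("IV", "IV"))
  # no loops, no Pol II -> I
  ls4 <- categorize_loops(gm, intra[0, ],
                          setNames(c(FALSE, TRUE), c("GA", "GB")))
  expect_equal(ls4$category, c("I", "II"))
})

test_that("loop-kinetics tables conserve class sizes", {
  loop_status <- data.frame(gene_id = sprintf("g%d", 1:6),
                            polII_at_promoter = TRUE,
                            category = c("III", "III", "I", "II", "IV",
                                         "I"),
                            stringsAsFactors = FALSE)
  records <- data.frame(gene_id = sprintf("g%d", 1:6),
                        class = c("Ad", "Ad", "Ad", "Ai", "Ai",
                                  "unaffected"),
                        robust = TRUE,
                        pattern_label = c("3Ad", "3Ad", "2Ad", "1Ai",
                                          "1Ai", NA),
                        stringsAsFactors = FALSE)
  class(records) <- c("kb_taxonomy", "data.frame")
  tab <- category_kinetics(loop_status, records)
  expect_equal(sum(tab$total), 5)   # unaffected gene excluded
  row3Ad <- tab[tab$pattern_label == "3Ad", ]
  expect_equal(row3Ad$looped, 2)
  expect_equal(row3Ad$non_looped, 0)
  expect_equal(sum(tab$looped + tab$non_looped), sum(tab$total))
})

test_that("Kruskal-Wallis on baseline RPM matches the textbook formula", {
  # printed 3-group toy table with distinct values
  groups <- list(I = c(1.2, 3.4, 2.2, 5.0),
                 II = c(6.1, 7.3, 8.0),
                 III = c(10.5, 12.0, 9.9, 11.1, 13.2))
  ls <- data.frame(gene_id = sprintf("g%d", 1:12),
                   polII_at_promoter = TRUE,
                   category = rep(c("I", "II", "III"), c(4, 3, 5)),
                   stringsAsFactors = FALSE)
  baseline <- setNames(unlist(groups), ls$gene_id)
  res <- baseline_expression_by_category(ls, baseline)
  expect_equal(res$H, oracle_kruskal_h(groups), tolerance = 1e-10)
  expect_equal(res$H, unname(kruskal.test(groups)$statistic))

  # identical distributions: H small, p not extreme
  set.seed(71)
  ls2 <- data.frame(gene_id = sprintf("h%d", 1:300),
                    polII_at_promoter = TRUE,
                    category = rep(c("I", "II", "III"), each = 100),
                    stringsAsFactors = FALSE)
  base2 <- setNames(rlnorm(300, 3, 1), ls2$gene_id)
  res2 <- baseline_expression_by_category(ls2, base2)
  expect_gt(res2$p, 0.001)

  # planted shift IV >> I at n = 200 per category
  ls3 <- data.frame(gene_id = sprintf("k%d", 1:400),
                    polII_at_promoter = TRUE,
                    category = rep(c("I", "IV"), each = 200),
                    stringsAsFactors = FALSE)
  base3 <- setNames(c(rlnorm(200, 2, 1), rlnorm(200, 4, 1)), ls3$gene_id)
  res3 <- baseline_expression_by_category(ls3, base3)
  expect_lt(res3$p, 0.001)
})

test_that("metagene profiles are flat for constant coverage", {
  gm <- tiny_gene_models()
  cov <- data.frame(chrom = "chr1", start = 0, end = 200000, value = 7)
  mp <- metagene_profile(cov, gm, n_bins = 50)
  expect_equal(unname(mp$profile), rep(7, 50))
})

test_that("metagene resamples a linear ramp analytically", {
  gm <- tiny_gene_models()
  gm$genes <- gm$genes[1, ]; gm$exons <- gm$exons[1:2, ]
  # coverage increases by 1 every bp over the gene body (0-based steps)
  steps <- data.frame(chrom = "chr1",
                      start = seq(9999, 19999, by = 1),
                      end = seq(10000, 20000, by = 1),
                      value = 0:10000)
  mp <- metagene_profile(steps, gm, n_bins = 10)
  # bin means of the unit ramp starting at 0: mean(0..999) = 499.5, etc.
  expected <- seq(499.5, 9499.5, by = 1000)
  expect_equal(unname(mp$profile), expected, tolerance = 1e-6)
})

test_that("minus-strand genes are profiled 5' to 3'", {
  gm <- tiny_gene_models()
  gm$genes <- gm$genes[2, ]; gm$exons <- gm$exons[3:4, ]
  # skewed coverage: high near the TSS (right end of a minus-strand gene)
  cov <- data.frame(chrom = "chr1", start = c(99999, 105000),
                    end = c(105000, 110000), value = c(1, 9))
  mp <- metagene_profile(cov, gm, n_bins = 10)
  expect_gt(mp$profile[1], mp$profile[10])   # bin 1 is the 5' end
  expect_equal(unname(mp$profile[1]), 9)
  expect_equal(unname(mp$profile[10]), 1)
})

test_that("metagene validates gene length against the bin count", {
  gm <- tiny_gene_models()
  gm$genes$end[1] <- gm$genes$start[1] + 30L
  cov <- data.frame(chrom = "chr1", start = 0, end = 2e5, value = 1)
  expect_error(metagene_profile(cov, gm, n_bins = 100), "shorter")
})
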