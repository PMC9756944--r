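# NB dispersion estimation, the per-window GLM, Simes/merging, AT scoring,
# and the edgeR oracle cross-check of the from-scratch inference.

test_that("dispersion estimation separates Poisson from NB counts", {
  set.seed(51)
  grp <- rep(c("A", "B"), each = 3)
  lib <- rep(1e6, 6)
  y_pois <- matrix(rpois(3000 * 6, 50), 3000, 6)
  expect_lt(estimate_dispersion(y_pois, grp, lib)$phi, 0.05)
  y_nb <- matrix(rnbinom(5000 * 6, mu = 50, size = 10), 5000, 6)
  phi <- estimate_dispersion(y_nb, grp, lib)$phi
  expect_gte(phi, 0.08)
  expect_lte(phi, 0.12)
})

test_that("degenerate dispersion inputs are flagged or rejected", {
  expect_warning(
    est <- estimate_dispersion(matrix(c(5L, 7L, 6L, 9L), 1, 4),
                               rep(c("A", "B"), each = 2), rep(100, 4)),
    "wide")
  expect_true(est$wide_flag)
  expect_error(estimate_dispersion(matrix(0L, 10, 4)), "zero")
  expect_error(estimate_dispersion(matrix(1L, 10, 1)), "2 samples")
})

test_that("identical groups give log2FC 0 and p near 1; enrichment is recovered", {
  y_eq <- matrix(rep(c(10L, 20L, 30L, 10L, 20L, 30L), 5), 5, 6,
                 byrow = TRUE)
  grp <- rep(c("A", "B"), each = 3)
  r <- nb_test(y_eq, grp, phi = 0.1, lib_sizes = rep(100, 6))
  expect_equal(r$log2fc, rep(0, 5), tolerance = 1e-6)
  expect_true(all(r$p > 0.99))

  set.seed(52)
  yA <- matrix(rnbinom(500 * 3, mu = 400, size = 10), 500, 3)
  yB <- matrix(rnbinom(500 * 3, mu = 50, size = 10), 500, 3)
  r8 <- nb_test(cbind(yA, yB), grp, phi = 0.1, lib_sizes = rep(1e5, 6))
  expect_gte(median(r8$log2fc), 2.5)
  expect_lte(median(r8$log2fc), 3.5)
  expect_gt(mean(r8$p < 0.01), 0.9)
  # all-zero windows are reported as non-findings, not errors
  rz <- nb_test(matrix(0L, 2, 6), grp, phi = 0.1, lib_sizes = rep(100, 6))
  expect_equal(rz$p, c(1, 1))
})

test_that("the NB GLM matches the edgeR oracle at a shared dispersion", {
  skip_if_not_installed("edgeR")
  set.seed(53)
  grp <- factor(rep(c("A", "B"), each = 3))
  y <- matrix(rnbinom(2000 * 6, mu = 60, size = 10), 2000, 6)
  y[1:60, 1:3] <- rnbinom(60 * 3, mu = 300, size = 10)
  lib <- rep(60 * 2000, 6)
  mine_phi <- estimate_dispersion(y, grp, lib)$phi
  d <- edgeR::DGEList(counts = y, group = grp, lib.size = lib)
  ed <- edgeR::estimateGLMCommonDisp(d, design = stats::model.matrix(~grp))
  expect_lt(abs(mine_phi - ed$common.dispersion) /
              ed$common.dispersion, 0.05)
  mine <- nb_test(y, grp, mine_phi, lib)
  fit <- edgeR::glmFit(d, stats::model.matrix(~grp), dispersion = mine_phi)
  lrt <- edgeR::glmLRT(fit, coef = 2)
  expect_lt(max(abs(mine$p - lrt$table$PValue)), 1e-6)
  # edgeR's logFC uses prior counts; agreement is near-exact but not bitwise
  expect_gt(cor(mine$log2fc, -lrt$table$logFC), 0.999)
})

test_that("the quasi-likelihood variant stays calibrated and ranks like the LRT", {
  set.seed(54)
  grp <- rep(c("A", "B"), each = 3)
  y <- matrix(rnbinom(1500 * 6, mu = 50, size = 10), 1500, 6)
  lrt <- nb_test(y, grp, 0.1, rep(1e5, 6), test = "lrt")
  qlf <- nb_test(y, grp, 0.1, rep(1e5, 6), test = "qlf")
  expect_true(all(qlf$p >= 0 & qlf$p <= 1))
  expect_gt(cor(rank(lrt$p), rank(qlf$p)), 0.99)
  expect_lt(abs(mean(qlf$p < 0.05) - 0.05), 0.025)
})

test_that("region merging is boundary-exact at the <100 bp rule", {
  # windows [0,69) and [168,237): 99 bp apart -> merged
  w99 <- c(gr0(0, 69), gr0(168, 237))
  r99 <- merge_and_combine(w99, c(0.01, 0.02), c(3, 3))
  expect_equal(length(r99), 1L)
  expect_equal(r99$n_windows, 2L)
  # 100 bp apart -> kept separate
  w100 <- c(gr0(0, 69), gr0(169, 238))
  r100 <- merge_and_combine(w100, c(0.01, 0.02), c(3, 3))
  expect_equal(length(r100), 2L)
})

test_that("Simes combination, idempotence and order invariance hold", {
  w <- c(gr0(0, 69), gr0(23, 92), gr0(46, 115))
  p <- c(0.01, 0.03, 0.04)
  r <- merge_and_combine(w, p, c(2, 2, 2))
  expect_equal(r$p_combined, 0.03)
  expect_gte(r$p_combined, min(p))
  single <- merge_and_combine(gr0(0, 69), 0.02, 1.5)
  expect_equal(single$p_combined, 0.02)

  set.seed(55)
  starts <- sort(sample(seq(0, 5000, by = 23), 40))
  wr <- gr0(starts, starts + 69)
  pr <- runif(40); fc <- rnorm(40, 2)
  a <- merge_and_combine(wr, pr, fc)
  perm <- sample(40)
  b <- merge_and_combine(wr[perm], pr[perm], fc[perm])
  expect_equal(as.data.frame(a), as.data.frame(b))
  # merging the merged regions changes nothing
  c2 <- merge_and_combine(a, a$p_combined, a$log2fc)
  expect_equal(GenomicRanges::granges(c2), GenomicRanges::granges(a))
})

test_that("AT fraction is case-insensitive and excludes ambiguous bases", {
  g <- Biostrings::DNAStringSet(c(chr = "ATATGCGCATGCNNNN"))
  expect_equal(at_fraction(gr0(0, 4, "chr"), g), 1.0)
  expect_equal(at_fraction(gr0(4, 8, "chr"), g), 0.0)
  expect_equal(at_fraction(gr0(8, 13, "chr"), g), 0.5)  # "ATGCN"
  expect_error(at_fraction(gr0(10, 20, "chr"), g), "outside")
  expect_error(at_fraction(GenomicRanges::GRanges("chr",
                                                  IRanges::IRanges(5, 4)), g),
               "empty")
})

test_that("differentially bound regions carry elevated AT content from AT-boosted sites", {
  cs <- simulate_chip(chip_sim_config(seed = 56))
  res <- chip_differential(cs$fragments, cs$samples$condition,
                           genome = cs$genome)
  expect_gt(length(res$significant), 5)
  bg_at <- at_fraction(gr0(3e5, 3.5e5, "chr"), cs$genome)
  expect_gt(median(res$significant$at_frac), bg_at)
})
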