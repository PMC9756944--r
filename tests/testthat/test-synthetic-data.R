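# Generators: determinism, closed-form moments, and construction contracts.

test_that("all generators are deterministic under a fixed seed", {
  a <- simulate_spt(spt_sim_config(n_molecules = 50, n_frames = 15, seed = 9))
  b <- simulate_spt(spt_sim_config(n_molecules = 50, n_frames = 15, seed = 9))
  expect_identical(a, b)

  ha <- simulate_hyphae(hypha_sim_config(n_hyphae = 4, seed = 9,
                                         branch_prob = 0.05))
  hb <- simulate_hyphae(hypha_sim_config(n_hyphae = 4, seed = 9,
                                         branch_prob = 0.05))
  expect_identical(ha, hb)

  ca <- simulate_chip(chip_sim_config(genome_length = 5e4, n_sites = 3,
                                      library_sizes = 5000, seed = 9))
  cb <- simulate_chip(chip_sim_config(genome_length = 5e4, n_sites = 3,
                                      library_sizes = 5000, seed = 9))
  expect_identical(ca, cb)

  ga <- simulate_growth(growth_sim_config(seed = 9))
  gb <- simulate_growth(growth_sim_config(seed = 9))
  expect_identical(ga, gb)
})

test_that("PALM simulator emits exactly n_molecules x n_frames localizations without loss processes", {
  sim <- simulate_spt(spt_sim_config(n_molecules = 5, n_frames = 10,
                                     p_bleach = 0, p_blink = 0, seed = 2))
  expect_equal(nrow(sim$localizations), 50L)
  expect_equal(nrow(sim$truth), 50L)
  # ground truth joins 1:1 by loc_id
  expect_setequal(sim$localizations$loc_id, sim$truth$loc_id)
  # all localizations inside the field of view
  expect_true(all(sim$localizations$x_um >= 0 &
                    sim$localizations$x_um <= sim$config$fov[1]))
  expect_true(all(sim$localizations$y_um >= 0 &
                    sim$localizations$y_um <= sim$config$fov[2]))
})

test_that("mean squared 2D step matches 4 D dt + 4 sigma^2 within 3 SE", {
  D <- 0.1; dt <- 0.03; sig <- 0.05
  sim <- simulate_spt(spt_sim_config(n_molecules = 1200, n_frames = 11,
                                     D_slow = D, D_fast = D, f_slow = 0.5,
                                     dt = dt, loc_sigma = sig, p_bleach = 0,
                                     p_blink = 0, fov = c(50, 50), seed = 3))
  tr <- truth_tracks(sim)
  steps <- do.call(rbind, lapply(split(tr, tr$track_id), step_displacements))
  expect_gte(nrow(steps), 1e4)
  expected <- 4 * D * dt + 4 * sig^2
  # r2 is exponential with mean `expected`; SE of the mean = mean / sqrt(n)
  se <- expected / sqrt(nrow(steps))
  expect_lt(abs(mean(steps$r2) - expected), 3 * se)
})

test_that("stationary slow-state occupancy equals f_slow within 3 SE", {
  f <- 0.6
  sim <- simulate_spt(spt_sim_config(n_molecules = 4000, n_frames = 40,
                                     f_slow = f, switch_prob = 0.3,
                                     p_bleach = 0, p_blink = 0, seed = 4))
  # final-frame states across molecules are independent draws from the chain
  last <- sim$truth[sim$truth$frame == 40, ]
  phat <- mean(last$state == "slow")
  se <- sqrt(f * (1 - f) / nrow(last))
  expect_lt(abs(phat - f), 3 * se)
})

test_that("tip-to-proximal-focus truth distance is constant without drift and has slope tip_drift with it", {
  still <- simulate_hyphae(hypha_sim_config(n_hyphae = 3, tip_drift = 0,
                                            stall_prob = 0, branch_prob = 0,
                                            duplication_interval = 50,
                                            noise_sigma = 0, seed = 5))
  for (hid in unique(still$foci$hypha_id)) {
    d <- tapply(still$foci$dist_um[still$foci$hypha_id == hid],
                still$foci$frame[still$foci$hypha_id == hid], min)
    expect_equal(diff(range(d)), 0)
  }
  drift <- simulate_hyphae(hypha_sim_config(n_hyphae = 3, tip_drift = 0.1,
                                            stall_prob = 0, branch_prob = 0,
                                            duplication_interval = 50,
                                            noise_sigma = 0, seed = 5))
  for (hid in unique(drift$foci$hypha_id)) {
    d <- tapply(drift$foci$dist_um[drift$foci$hypha_id == hid],
                drift$foci$frame[drift$foci$hypha_id == hid], min)
    expect_equal(as.numeric(diff(d)), rep(0.1, length(d) - 1),
                 tolerance = 1e-10)
  }
})

test_that("noise-free profile peaks at the ground-truth focus position within half a pixel", {
  sim <- simulate_hyphae(hypha_sim_config(n_hyphae = 1, noise_sigma = 0,
                                          branch_prob = 0, stall_prob = 0,
                                          duplication_interval = 50,
                                          seed = 6))
  p1 <- sim$profiles[sim$profiles$frame == 1, ]
  truth1 <- sim$foci$dist_um[sim$foci$frame == 1]
  expect_length(truth1, 1)
  # remove the baseline gradient before taking the arg-max
  base <- 15 + 0.8 * p1$position_um
  expect_lt(abs(p1$position_um[which.max(p1$intensity - base)] - truth1),
            sim$config$pixel_size / 2 + 1e-9)
})

test_that("site AT fraction is boosted to the configured binomial mean", {
  cfg <- chip_sim_config(genome_length = 1e5, gc_background = 0.5,
                         site_at_boost = 0.2, n_sites = 10, site_width = 200,
                         library_sizes = 1000, seed = 7)
  cs <- simulate_chip(cfg)
  gr <- GenomicRanges::GRanges("chr", IRanges::IRanges(cs$sites$start + 1,
                                                       cs$sites$end))
  at <- at_fraction(gr, cs$genome)
  n_bases <- sum(GenomicRanges::width(gr))
  se <- sqrt(0.7 * 0.3 / n_bases)
  expect_lt(abs(mean(at) - 0.7), 3 * se)
  # background AT stays near 1 - gc
  bg <- GenomicRanges::GRanges("chr", IRanges::IRanges(50001, 60000))
  expect_lt(abs(at_fraction(bg, cs$genome) - 0.5), 0.05)
})

test_that("emitted fragment totals match library sizes and window counts have the configured dispersion", {
  lib <- 60000
  cfg <- chip_sim_config(genome_length = 4e5, n_sites = 0,
                         enrichment_fold = c(1, 1), library_sizes = lib,
                         dispersion = 0.1, n_reps = 1, seed = 8)
  cs <- simulate_chip(cfg)
  tot <- vapply(cs$fragments, length, integer(1))
  # total CV^2 ~ 1/N + phi / n_blocks
  sd_tot <- lib * sqrt(1 / lib + 0.1 / (4e5 / 1000))
  expect_true(all(abs(tot - lib) < 5 * sd_tot))

  # near-Poisson limit: index of dispersion of disjoint window counts -> 1
  cfg0 <- chip_sim_config(genome_length = 4e5, n_sites = 0,
                          enrichment_fold = c(1, 1), library_sizes = lib,
                          dispersion = 1e-8, n_reps = 1, seed = 8)
  cs0 <- simulate_chip(cfg0)
  win <- GenomicRanges::GRanges("chr", IRanges::IRanges(
    start = seq(1, 4e5 - 400, by = 400), width = 69))
  GenomeInfoDb::seqlengths(win) <- c(chr = 4e5)
  y <- as.integer(count_fragments(win, cs0$fragments[[1]]))
  iod <- stats::var(y) / mean(y)
  se_iod <- sqrt(2 / (length(y) - 1))
  expect_lt(abs(iod - 1), 3 * se_iod)

  # at phi = 0.3 the same statistic reflects the NB variance inflation
  cfg3 <- chip_sim_config(genome_length = 4e5, n_sites = 0,
                          enrichment_fold = c(1, 1), library_sizes = lib,
                          dispersion = 0.3, n_reps = 1, block_size = 2000,
                          seed = 8)
  cs3 <- simulate_chip(cfg3)
  win3 <- GenomicRanges::GRanges("chr", IRanges::IRanges(
    start = seq(1, 4e5 - 2000, by = 2000) + 500, width = 69))
  GenomeInfoDb::seqlengths(win3) <- c(chr = 4e5)
  y3 <- as.integer(count_fragments(win3, cs3$fragments[[1]]))
  expect_gt(stats::var(y3) / mean(y3), 1 + 0.3 * mean(y3) / 2)
})

test_that("noise-free growth curves hit the ED50 definition and the plateau tail bound", {
  cfg <- growth_sim_config(b_true = -5, d_true = 1.2, e_true = 2,
                           noise_sigma = 0, n_replicates = 1,
                           t_grid = unique(sort(c(2, seq(0.5, 40, by = 0.5)))),
                           seed = 1)
  g <- simulate_growth(cfg)
  expect_equal(g$rep1[g$time_h == 2], 0.6)
  # monotone non-decreasing for negative b
  expect_true(all(diff(g$rep1) >= 0))
  # closed-form tail: within 1% of the plateau for t > e * exp(5/|b|)
  tail_t <- g$time_h > 2 * exp(5 / 5)
  expect_true(all(abs(g$rep1[tail_t] - 1.2) < 0.012))
})

test_that("generator configs validate their domains", {
  expect_error(spt_sim_config(f_slow = 1.2), "probability")
  expect_error(spt_sim_config(D_slow = 0.5, D_fast = 0.1), "D_slow")
  expect_error(growth_sim_config(t_grid = c(2, 1, 3)), "increasing")
  expect_error(growth_sim_config(t_grid = c(0, 1, 2)), "t_grid")
  expect_error(chip_sim_config(genome_length = 1000, n_sites = 20,
                               site_width = 100), "smaller")
  expect_error(chip_sim_config(enrichment_fold = c(0.5, 1)), ">= 1")
})
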