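# Diffusion-mixture fitting and mobility classification.

make_pure_tracks <- function(n_tracks, n_steps, step_sd, id0 = 0) {
  do.call(rbind, lapply(seq_len(n_tracks), function(i) {
    data.frame(track_id = id0 + i, frame = seq_len(n_steps + 1),
               x_um = cumsum(c(0, rnorm(n_steps, 0, step_sd))),
               y_um = cumsum(c(0, rnorm(n_steps, 0, step_sd))))
  }))
}

test_that("K = 1 reduces to the closed-form exponential MLE", {
  set.seed(1)
  tr <- make_pure_tracks(30, 10, sqrt(2 * 0.2 * 0.03))
  fit <- fit_diffusion_mixture(tr, K = 1, dt = 0.03, loc_sigma = 0)
  steps <- do.call(rbind, lapply(split(tr, tr$track_id), step_displacements))
  expect_equal(fit$D_app, mean(steps$r2) / (4 * 0.03), tolerance = 1e-10)
  expect_equal(fit$weights, 1)
})

test_that("EM log-likelihood is monotone non-decreasing over iterations", {
  set.seed(2)
  r2 <- c(rexp(3000, 1 / 0.002), rexp(1000, 1 / 0.05))
  res <- hyphachrom:::.exp_mix_em(r2, 2, c(0.5, 0.5), c(0.001, 0.1))
  expect_true(all(diff(res$trace) > -1e-8))
})

test_that("two-state parameters are recovered from simulated PALM steps", {
  sim <- simulate_spt(spt_sim_config(n_molecules = 3000, n_frames = 12,
                                     D_slow = 0.015, D_fast = 0.400,
                                     f_slow = 0.75, switch_prob = 0.02,
                                     dt = 0.03, loc_sigma = 0.02,
                                     p_bleach = 0, p_blink = 0, seed = 21))
  fit <- fit_diffusion_mixture(truth_tracks(sim), K = 2, dt = 0.03,
                               loc_sigma = 0.02)
  expect_lt(abs(fit$D_app[1] - 0.015) / 0.015, 0.10)
  expect_lt(abs(fit$D_app[2] - 0.400) / 0.400, 0.10)
  expect_lt(abs(fit$weights[1] - 0.75), 0.03)
  expect_equal(sum(fit$weights), 1, tolerance = 1e-9)
  expect_equal(fit$mean_D_app, sum(fit$weights * fit$D_app))
})

test_that("a K = 2 fit on single-state data collapses without corrupting the mean", {
  set.seed(3)
  tr <- make_pure_tracks(120, 12, sqrt(2 * 0.1 * 0.03))
  f1 <- fit_diffusion_mixture(tr, K = 1, dt = 0.03)
  f2 <- fit_diffusion_mixture(tr, K = 2, dt = 0.03)
  degenerate <- abs(diff(f2$means)) / mean(f2$means) < 0.2
  vanishing <- min(f2$weights) < 0.05
  expect_true(degenerate || vanishing)
  expect_lt(abs(f2$mean_D_app - f1$mean_D_app) / f1$mean_D_app, 0.05)
})

test_that("the MSD/GMM cross-check mode broadly agrees with the exponential fit", {
  skip_if_not_installed("mclust")
  sim <- simulate_spt(spt_sim_config(n_molecules = 800, n_frames = 15,
                                     D_slow = 0.015, D_fast = 0.400,
                                     f_slow = 0.75, switch_prob = 0,
                                     loc_sigma = 0, p_bleach = 0,
                                     p_blink = 0, seed = 22))
  tr <- truth_tracks(sim)
  fe <- fit_diffusion_mixture(tr, K = 2, dt = 0.03)
  fm <- fit_diffusion_mixture(tr, K = 2, dt = 0.03, method = "msd_gmm")
  expect_equal(sum(fm$weights), 1, tolerance = 1e-9)
  expect_lt(fm$D_app[1], fm$D_app[2])
  expect_lt(abs(fm$weights[1] - fe$weights[1]), 0.1)
  # per-track coefficients average to the same overall mobility
  expect_equal(fm$mean_D_track, fe$mean_D_track)
})

test_that("mobility classes follow the 3-step window rule", {
  set.seed(4)
  slow_sd <- sqrt(2 * 0.015 * 0.03)
  fast_sd <- sqrt(2 * 0.4 * 0.03)
  slow <- make_pure_tracks(40, 6, slow_sd, id0 = 0)
  fast <- make_pure_tracks(40, 6, fast_sd, id0 = 100)
  # deterministic tracks: all-slow, all-fast, and alternating-state
  alt_steps <- rep(c(0.001, 0.3), 4)
  alt <- data.frame(track_id = 999, frame = 1:9,
                    x_um = cumsum(c(0, alt_steps)), y_um = 0)
  pure_slow <- data.frame(track_id = 998, frame = 1:7,
                          x_um = cumsum(c(0, rep(0.001, 6))), y_um = 0)
  pure_fast <- data.frame(track_id = 997, frame = 1:7,
                          x_um = cumsum(c(0, rep(0.3, 6))), y_um = 0)
  tracks <- rbind(slow, fast, alt, pure_slow, pure_fast)
  fit <- fit_diffusion_mixture(tracks, K = 2, dt = 0.03)
  mob <- classify_mobility(tracks, fit)
  cls <- mob$classes
  expect_equal(cls$class[cls$track_id == "999"], "mixed")
  expect_equal(cls$class[cls$track_id == "998"], "confined")
  expect_equal(cls$class[cls$track_id == "997"], "free")
  # stochastic pure-state populations: the per-step max-posterior labels
  # misclassify a bounded fraction of steps, so most tracks keep their class
  expect_gt(mean(cls$class[cls$track_id %in% 1:40] == "confined"), 0.6)
  expect_gt(mean(cls$class[cls$track_id %in% 101:140] == "free"), 0.25)
  expect_equal(sum(mob$fractions), 1)
  # tracks shorter than the window are not classified
  short <- rbind(tracks, data.frame(track_id = 1000, frame = 1:3,
                                    x_um = c(0, 0.01, 0.02), y_um = 0))
  mob2 <- classify_mobility(short, fit_diffusion_mixture(short, K = 2,
                                                         dt = 0.03))
  expect_false("1000" %in% mob2$classes$track_id)
})

test_that("mixture fitting enforces its contracts", {
  tr <- make_pure_tracks(2, 3, 0.01)
  expect_error(fit_diffusion_mixture(tr, K = 2, min_steps = 50), "steps")
  expect_error(fit_diffusion_mixture(tr, K = 0), "K")
  still <- data.frame(track_id = 1, frame = 1:60, x_um = 0, y_um = 0)
  expect_error(fit_diffusion_mixture(still, K = 1, min_steps = 10), "zero")
  sim <- simulate_spt(spt_sim_config(n_molecules = 200, n_frames = 5,
                                     p_bleach = 0, p_blink = 0, seed = 5))
  fit1 <- fit_diffusion_mixture(truth_tracks(sim), K = 1)
  expect_error(classify_mobility(truth_tracks(sim), fit1), "K = 2")
})
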