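# 1D focus detection, distance metrics, duplication tracking and smoothing.

gauss_profile <- function(centres, length_um = 20, pixel = 0.07, amp = 80,
                          sigma = 0.15, noise = 0, baseline = 20) {
  pos <- seq(0, length_um, by = pixel)
  int <- rep(baseline, length(pos))
  for (c0 in centres) int <- int + amp * exp(-(pos - c0)^2 / (2 * sigma^2))
  if (noise > 0) int <- int + rnorm(length(pos), 0, noise)
  data.frame(position_um = pos, intensity = int)
}

test_that("a noise-free Gaussian peak is located to sub-pixel accuracy", {
  p <- gauss_profile(10.0)
  f <- detect_foci(p)
  expect_equal(nrow(f), 1L)
  expect_lt(abs(f$position_um - 10.0), 0.07 / 2)
})

test_that("flat noisy profiles yield no foci at a 5-sigma threshold in almost all trials", {
  set.seed(11)
  false_calls <- vapply(1:200, function(i) {
    p <- gauss_profile(numeric(0), noise = 8)
    nrow(detect_foci(p))
  }, numeric(1))
  expect_gte(mean(false_calls == 0), 0.99)
})

test_that("peaks closer than min_separation are merged into the higher one", {
  p <- gauss_profile(c(10.0, 10.25))
  f <- detect_foci(p)  # min_separation 0.5, peaks 0.25 apart
  expect_equal(nrow(f), 1L)
  p2 <- gauss_profile(c(8, 12))
  expect_equal(nrow(detect_foci(p2)), 2L)
})

test_that("detection input contracts are enforced", {
  p <- gauss_profile(10)
  p$intensity[3] <- NA
  expect_error(detect_foci(p), "non-finite")
  expect_error(detect_foci(gauss_profile(1)[1:3, ]), "5 pixels")
})

test_that("tip-distance series picks the tip-proximal focus and flags focus-free frames", {
  hypha <- data.frame(frame = 1:3, time_min = c(0, 10, 20))
  foci <- data.frame(frame = c(1, 1, 2), position_um = c(1.8, 4.0, 2.1))
  ts <- tip_distance_series(hypha, foci)
  expect_equal(ts$tip_distance_um, c(1.8, 2.1, NA))
  expect_equal(ts$focus_free, c(FALSE, FALSE, TRUE))
})

test_that("inter-focus distances cover adjacent and all-pairs modes", {
  expect_equal(interfocus_distances(c(1, 2.5, 4)), c(1.5, 1.5))
  expect_setequal(interfocus_distances(c(1, 2.5, 4), "all_pairs"),
                  c(1.5, 1.5, 3.0))
  expect_length(interfocus_distances(2.5), 0)
})

test_that("median inter-focus spacing is recovered from detected foci", {
  # 90-min duplication spacing lets each sister pair settle to the
  # steady-state spacing before the next split starts a new ramp
  sim <- simulate_hyphae(hypha_sim_config(
    n_hyphae = 30, n_frames = 28, branch_prob = 0, stall_prob = 0,
    duplication_interval = 9, split_rate = 1.55 / 60, seed = 12))
  det <- detect_foci_all(sim$profiles)
  d <- unlist(lapply(split(det, list(det$hypha_id, det$frame), drop = TRUE),
                     function(x) interfocus_distances(x$position_um)))
  expect_gt(length(d), 200)
  expect_lt(abs(median(d) - 1.55), 0.1)
})

test_that("tip-drift slope is recovered from detected foci", {
  sim <- simulate_hyphae(hypha_sim_config(
    n_hyphae = 15, n_frames = 15, tip_drift = 0.1, branch_prob = 0,
    stall_prob = 0, duplication_interval = 50, seed = 13))
  det <- detect_foci_all(sim$profiles)
  slopes <- vapply(split(det, det$hypha_id), function(dh) {
    ts <- tip_distance_series(data.frame(frame = sort(unique(dh$frame)),
                                         time_min = 10 * (sort(unique(dh$frame)) - 1)),
                              dh)
    unname(coef(lm(tip_distance_um ~ frame, ts))[2])
  }, numeric(1))
  expect_lt(abs(mean(slopes) - 0.1), 0.02)
})

test_that("focus tracking reports persistent splits and ignores transient ones", {
  # one focus becoming two, both persisting 5 frames
  pos <- list(2, 2, c(2, 2.3), c(2, 2.6), c(2, 2.9), c(2, 3.2), c(2, 3.5))
  foci <- do.call(rbind, lapply(seq_along(pos), function(f) {
    data.frame(hypha_id = "h", frame = f, position_um = pos[[f]])
  }))
  tf <- track_foci(foci, max_move = 0.5)
  expect_equal(nrow(tf$events), 1L)
  expect_equal(tf$events$frame, 3L)
  expect_equal(unname(tf$separation[1, 1:4]), c(0.3, 0.6, 0.9, 1.2))
  # every detected focus belongs to exactly one trajectory
  expect_equal(nrow(tf$trajectories), nrow(foci))

  transient <- do.call(rbind, lapply(1:5, function(f) {
    data.frame(hypha_id = "h", frame = f,
               position_um = if (f == 3) c(2, 2.3) else 2)
  }))
  expect_equal(nrow(track_foci(transient, max_move = 0.5)$events), 0L)
})

test_that("sister-separation schedule is recovered from ground-truth foci", {
  sim <- simulate_hyphae(hypha_sim_config(
    n_hyphae = 15, n_frames = 15, branch_prob = 0, stall_prob = 0,
    duplication_interval = 6, noise_sigma = 0, seed = 14))
  truth_foci <- data.frame(hypha_id = sim$foci$hypha_id,
                           frame = sim$foci$frame,
                           position_um = sim$foci$dist_um)
  tf <- track_foci(truth_foci, max_move = 0.6, frame_interval = 10)
  expect_gt(nrow(tf$events), 5)
  # separation at 60 min after the split: split_rate * 60 = 1.75 um
  sep60 <- tf$separation[, "t60"]
  expect_true(all(abs(sep60[!is.na(sep60)] - 1.75) < 0.1))
  # and the full 0-60 min ramp matches the linear schedule
  for (k in 1:7) {
    sk <- tf$separation[, k]
    expect_true(all(abs(sk[!is.na(sk)] - (k - 1) * 10 * 1.75 / 60) < 0.1))
  }
})

test_that("loess trend reproduces lines, preserves constants and smooths noise", {
  t <- seq(0, 10, length.out = 40)
  y_lin <- 2 * t + 1
  expect_equal(loess_trend(t, y_lin, 0.5), y_lin, tolerance = 1e-8)
  expect_equal(loess_trend(t, rep(3, 40), 0.5), rep(3, 40), tolerance = 1e-8)
  set.seed(15)
  truth <- sin(t)
  noisy <- truth + rnorm(40, 0, 0.3)
  sm <- loess_trend(t, noisy, 0.3)
  expect_lt(sqrt(mean((sm - truth)^2)), sqrt(mean((noisy - truth)^2)))
  expect_error(loess_trend(t[1:3], y_lin[1:3]), "5 points")
  expect_error(loess_trend(t, y_lin, 1.5), "span")
})
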