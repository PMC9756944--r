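# Focus detection and distance metrics along 1D hyphal intensity profiles.
# All positions are um from the current hyphal tip (tip-anchored frame).

#' Peak-detection configuration
#'
#' @param smooth_sigma Gaussian smoothing SD (um), kept below the optical
#'   peak width so peak height is not unduly attenuated.
#' @param background_window half-width (um) of the iterative-clipping (SNIP)
#'   background estimator.
#' @param snr_threshold detection threshold in multiples of the robust
#'   (MAD-based) noise SD.
#' @param min_separation minimum distance between reported foci (um); closer
#'   maxima are resolved by keeping the higher.
#' @param pixel_size profile sampling (um/pixel).
#' @return object of class `peak_detect_config`.
#' @export
peak_detect_config <- function(smooth_sigma = 0.08, background_window = 2,
                               snr_threshold = 5, min_separation = 0.5,
                               pixel_size = 0.07) {
  stop_if_not_pos(c(smooth_sigma, background_window, snr_threshold,
                    min_separation, pixel_size), "peak_detect_config fields")
  structure(list(smooth_sigma = smooth_sigma,
                 background_window = background_window,
                 snr_threshold = snr_threshold,
                 min_separation = min_separation, pixel_size = pixel_size),
            class = "peak_detect_config")
}

# SNIP-style background: iterative clipping with growing window, robust to
# peaks narrower than the final half-width (in pixels).
.snip_background <- function(v, half_width_px) {
  n <- length(v)
  m_max <- max(1L, min(half_width_px, n - 1L))
  b <- v
  for (m in seq_len(m_max)) {
    if (m + 1 > n - m) break
    i <- (m + 1):(n - m)
    b[i] <- pmin(b[i], (b[i - m] + b[i + m]) / 2)
  }
  b
}

.gauss_smooth <- function(v, sigma_px) {
  if (sigma_px <= 0) return(v)
  hw <- max(1L, ceiling(4 * sigma_px))
  k <- stats::dnorm(-hw:hw, sd = sigma_px)
  k <- k / sum(k)
  n <- length(v)
  pad <- c(rev(v[seq_len(min(hw, n))]), v, rev(v[seq.int(n, by = -1,
                                                         length.out = min(hw, n))]))
  sm <- stats::filter(pad, k, sides = 2)
  as.numeric(sm[(hw + 1):(hw + n)])
}

#' Detect fluorescent foci in a 1D intensity profile
#'
#' Background is removed by iterative clipping (SNIP-style) over
#' `background_window`; the residual is Gaussian-smoothed; local maxima
#' exceeding `snr_threshold` times the robust noise SD (1.4826 x MAD of
#' first differences / sqrt(2)) are retained; maxima closer than
#' `min_separation` are resolved by keeping the higher; positions are
#' refined to sub-pixel accuracy by 3-point parabolic interpolation.
#'
#' @param profile data.frame with `position_um` (regular grid) and
#'   `intensity`.
#' @param config a [peak_detect_config()].
#' @return data.frame with `position_um`, `intensity` (background-subtracted
#'   peak height) and `snr`; zero rows when nothing exceeds the threshold.
#' @export
detect_foci <- function(profile, config = peak_detect_config()) {
  stopifnot(inherits(config, "peak_detect_config"))
  pos <- profile$position_um
  v <- profile$intensity
  if (length(v) < 5) stop("profile must have at least 5 pixels", call. = FALSE)
  if (any(!is.finite(v))) stop("non-finite intensities", call. = FALSE)
  px <- config$pixel_size
  bg <- .snip_background(v, round(config$background_window / px))
  sig <- v - bg
  noise <- 1.4826 * stats::median(abs(diff(sig))) / sqrt(2)
  sm <- .gauss_smooth(sig, config$smooth_sigma / px)
  n <- length(sm)
  if (n < 3) return(data.frame(position_um = numeric(0),
                               intensity = numeric(0), snr = numeric(0)))
  i <- 2:(n - 1)
  is_max <- sm[i] >= sm[i - 1] & sm[i] > sm[i + 1] &
    sm[i] > config$snr_threshold * max(noise, 1e-12)
  cand <- i[is_max]
  if (length(cand) == 0) {
    return(data.frame(position_um = numeric(0), intensity = numeric(0),
                      snr = numeric(0)))
  }
  # non-maximum suppression within min_separation, keeping higher peaks
  cand <- cand[order(sm[cand], decreasing = TRUE)]
  kept <- integer(0)
  for (cc in cand) {
    if (all(abs(pos[cc] - pos[kept]) >= config$min_separation)) {
      kept <- c(kept, cc)
    }
  }
  kept <- sort(kept)
  # sub-pixel refinement
  delta <- 0.5 * (sm[kept - 1] - sm[kept + 1]) /
    (sm[kept - 1] - 2 * sm[kept] + sm[kept + 1])
  delta[!is.finite(delta)] <- 0
  delta <- pmax(pmin(delta, 0.5), -0.5)
  data.frame(position_um = pos[kept] + delta * px, intensity = sig[kept],
             snr = sm[kept] / max(noise, 1e-12))
}

#' Detect foci in every frame of every hypha
#'
#' @param profiles profile data.frame (`hypha_id`, `frame`, `position_um`,
#'   `intensity`), e.g. from [simulate_hyphae()].
#' @param config a [peak_detect_config()].
#' @return data.frame `hypha_id`, `frame`, `position_um`, `intensity`, `snr`.
#' @export
detect_foci_all <- function(profiles, config = peak_detect_config()) {
  parts <- lapply(split(profiles, list(profiles$hypha_id, profiles$frame),
                        drop = TRUE), function(p) {
    if (nrow(p) < 5) return(NULL)
    f <- detect_foci(p[order(p$position_um), ], config)
    if (nrow(f) == 0) return(NULL)
    cbind(data.frame(hypha_id = p$hypha_id[1], frame = p$frame[1]), f)
  })
  out <- do.call(rbind, Filter(Negate(is.null), parts))
  if (is.null(out)) {
    out <- data.frame(hypha_id = character(0), frame = integer(0),
                      position_um = numeric(0), intensity = numeric(0),
                      snr = numeric(0))
  }
  rownames(out) <- NULL
  out[order(out$hypha_id, out$frame, out$position_um), ]
}

#' Tip-to-proximal-focus distance series
#'
#' For each frame the distance from the hyphal tip to the nearest
#' (tip-proximal) focus; frames without any focus yield `NA` and flag the
#' hypha record as focus-free for that frame.
#'
#' @param hypha per-frame record of one hypha (`frame`, `time_min`).
#' @param foci focus table for the same hypha (`frame`, `position_um`,
#'   distances from the tip).
#' @return data.frame `frame`, `time_min`, `tip_distance_um`, `focus_free`.
#' @export
tip_distance_series <- function(hypha, foci) {
  d <- vapply(hypha$frame, function(f) {
    p <- foci$position_um[foci$frame == f]
    if (length(p) == 0) NA_real_ else min(p)
  }, numeric(1))
  data.frame(frame = hypha$frame, time_min = hypha$time_min,
             tip_distance_um = d, focus_free = is.na(d))
}

#' Distances between foci in one frame
#'
#' @param positions focus positions along the axis (um), any order.
#' @param mode `"adjacent"` (consecutive along-axis differences, default --
#'   nearest-neighbour spacing) or `"all_pairs"`.
#' @return numeric vector of distances (empty for fewer than 2 foci).
#' @export
interfocus_distances <- function(positions, mode = c("adjacent", "all_pairs")) {
  mode <- match.arg(mode)
  p <- sort(positions)
  if (length(p) < 2) return(numeric(0))
  if (mode == "adjacent") diff(p) else as.numeric(stats::dist(p))
}

#' Smooth a series with local linear (loess) regression
#'
#' Tricube-weighted local linear regression over a `span` fraction of
#' nearest neighbours, evaluated at the input abscissae (exact fit surface).
#'
#' @param t abscissae; @param y values; @param span fraction in (0, 1].
#' @return fitted values at `t`.
#' @export
loess_trend <- function(t, y, span = 0.5) {
  if (length(t) < 5) stop("need at least 5 points", call. = FALSE)
  if (span <= 0 || span > 1) stop("`span` must be in (0, 1]", call. = FALSE)
  if (length(unique(t)) < 2) stop("degenerate abscissae", call. = FALSE)
  fit <- stats::loess(y ~ t, span = span, degree = 1, family = "gaussian",
                      surface = "direct")
  as.numeric(stats::predict(fit, data.frame(t = t)))
}

#' Link foci across frames and detect duplication events
#'
#' Foci are linked frame-to-frame by along-axis nearest neighbour within
#' `max_move` (ties broken towards the tip-proximal candidate). A new focus
#' appearing within `max_move` of an existing trajectory starts a sister
#' trajectory; when both sisters persist for at least 2 frames the split is
#' recorded as a duplication event. For each event the sister-separation
#' series and the tip distances of both sisters are reported at the
#' acquisition interval for 90 minutes after the split (10 columns at 10-min
#' framing), together with column means (the average-position trend line).
#'
#' @param foci focus table (`hypha_id`, `frame`, `position_um`), consecutive
#'   frames per hypha.
#' @param max_move maximum per-frame along-axis movement (um).
#' @param frame_interval minutes between frames.
#' @param horizon_min reporting horizon after a split (default 90 min).
#' @return list with `trajectories` (`traj_id`, `hypha_id`, `frame`,
#'   `position_um`), `events` (`event_id`, `hypha_id`, `frame`, `traj_a`,
#'   `traj_b`), `separation` (events x timepoints matrix, um),
#'   `tip_distance` (2 rows per event: sisters a/b), and `col_means`.
#' @export
track_foci <- function(foci, max_move = 0.5, frame_interval = 10,
                       horizon_min = 90) {
  n_tp <- floor(horizon_min / frame_interval) + 1L
  traj_rows <- list(); events <- list()
  next_traj <- 1L
  for (hid in unique(foci$hypha_id)) {
    fh <- foci[foci$hypha_id == hid, , drop = FALSE]
    frames <- sort(unique(fh$frame))
    active_id <- integer(0); active_pos <- numeric(0); active_frame <- integer(0)
    parent_of <- integer(0); born <- integer(0); seen <- integer(0)
    pending <- list()  # candidate splits awaiting persistence
    store <- function(ids, frame, pos) {
      traj_rows[[length(traj_rows) + 1L]] <<- data.frame(
        traj_id = ids, hypha_id = hid, frame = frame, position_um = pos)
    }
    for (f in frames) {
      pos <- sort(fh$position_um[fh$frame == f])
      assigned <- rep(NA_integer_, length(pos))
      cand <- which(active_frame == f - 1L)
      if (length(cand) && length(pos)) {
        d <- abs(outer(active_pos[cand], pos, "-"))
        ok <- which(d <= max_move)
        # ascending distance, ties towards the tip-proximal (smaller) position
        ti <- (ok - 1L) %% length(cand) + 1L
        si <- (ok - 1L) %/% length(cand) + 1L
        ordp <- order(d[ok], pos[si])
        used_t <- logical(length(cand)); used_s <- logical(length(pos))
        for (k in ordp) {
          if (!used_t[ti[k]] && !used_s[si[k]]) {
            used_t[ti[k]] <- TRUE; used_s[si[k]] <- TRUE
            tr <- cand[ti[k]]
            assigned[si[k]] <- tr
            active_pos[tr] <- pos[si[k]]
            active_frame[tr] <- f
            seen[tr] <- seen[tr] + 1L
          }
        }
      }
      new_idx <- which(is.na(assigned))
      for (k in new_idx) {
        id <- next_traj; next_traj <- next_traj + 1L
        # sister birth: close to a surviving trajectory's current position
        near <- which(active_frame == f & abs(active_pos - pos[k]) <= max_move)
        par <- if (length(near)) {
          near[which.min(abs(active_pos[near] - pos[k]))]
        } else NA_integer_
        active_id[id] <- id; active_pos[id] <- pos[k]
        active_frame[id] <- f; seen[id] <- 1L
        parent_of[id] <- if (is.na(par)) NA_integer_ else active_id[par]
        born[id] <- f
        assigned[k] <- id
      }
      store(assigned, f, pos)
      # confirm pending splits: both sisters observed >= 2 frames
      for (id in which(!is.na(parent_of) & born == f - 1L)) {
        if (seen[id] >= 2L && seen[parent_of[id]] >= 2L &&
            active_frame[parent_of[id]] >= f) {
          events[[length(events) + 1L]] <- data.frame(
            hypha_id = hid, frame = born[id], traj_a = parent_of[id],
            traj_b = id)
        }
      }
    }
  }
  trajectories <- if (length(traj_rows)) do.call(rbind, traj_rows) else {
    data.frame(traj_id = integer(0), hypha_id = character(0),
               frame = integer(0), position_um = numeric(0))
  }
  ev <- if (length(events)) do.call(rbind, events) else {
    data.frame(hypha_id = character(0), frame = integer(0),
               traj_a = integer(0), traj_b = integer(0))
  }
  ev$event_id <- seq_len(nrow(ev))
  sep <- matrix(NA_real_, nrow(ev), n_tp)
  tipd <- matrix(NA_real_, 2 * nrow(ev), n_tp)
  tp_min <- (seq_len(n_tp) - 1L) * frame_interval
  colnames(sep) <- colnames(tipd) <- paste0("t", tp_min)
  for (e in seq_len(nrow(ev))) {
    for (k in seq_len(n_tp)) {
      f <- ev$frame[e] + (k - 1L)
      pa <- trajectories$position_um[trajectories$traj_id == ev$traj_a[e] &
                                       trajectories$frame == f]
      pb <- trajectories$position_um[trajectories$traj_id == ev$traj_b[e] &
                                       trajectories$frame == f]
      if (length(pa) == 1) tipd[2 * e - 1L, k] <- pa
      if (length(pb) == 1) tipd[2 * e, k] <- pb
      if (length(pa) == 1 && length(pb) == 1) sep[e, k] <- abs(pa - pb)
    }
  }
  list(trajectories = trajectories, events = ev, separation = sep,
       tip_distance = tipd,
       col_means = colMeans(tipd, na.rm = TRUE))
}
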