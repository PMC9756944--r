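# Time-lapse hyphal simulator. Hyphae are 1D axes (position along the hypha,
# um); all focus coordinates are distances from the current tip, matching the
# tip-anchored frame in which the real measurements are taken.

# Sister-separation schedule after a duplication: linear growth at `rate`
# um/min for the first 60 min, then relaxation to the steady-state chain
# spacing by 90 min (the empirical separation curve saturates around 60 min).
.sister_sep <- function(tau_min, rate, steady) {
  peak <- rate * 60
  ifelse(tau_min <= 60, rate * tau_min,
         ifelse(tau_min >= 90, steady,
                peak + (steady - peak) * (tau_min - 60) / 30))
}

#' Simulate time-lapse hyphae with chromosomal foci
#'
#' Each hypha extends by `extension_rate` um per frame (until an optional
#' permanent stall), carries a tip-anchored proximal focus whose tip distance
#' grows by `tip_drift` um per frame (anchorage loss), and a trailing chain of
#' foci created by periodic duplication of the tip-proximal focus. Branches
#' appear stochastically, initially focus-free, and acquire their first focus
#' after a configurable arrival delay. Per frame a 1D fluorescence intensity
#' profile is emitted: Gaussian peaks of width `peak_sigma` on a gently
#' sloped baseline plus additive Gaussian noise.
#'
#' @param config a [hypha_sim_config()].
#' @return list with data.frames `hyphae` (`hypha_id`, `parent_id`, `frame`,
#'   `time_min`, `tip_um`, `length_um`), `profiles` (`hypha_id`, `frame`,
#'   `position_um` measured from the tip, `intensity`), ground-truth `foci`
#'   (`hypha_id`, `frame`, `time_min`, `focus_id`, `dist_um`), an `events`
#'   log (germination/branch/duplication/focus_arrival/stall), and `config`.
#' @export
simulate_hyphae <- function(config) {
  stopifnot(inherits(config, "hypha_sim_config"))
  with_seed(config$seed, {
    fi <- config$frame_interval
    nf <- config$n_frames
    hy <- list(); pr <- list(); fo <- list(); ev <- list()
    next_focus <- 1L

    simulate_one <- function(id, parent, appear, len0, has_focus_from) {
      frames <- appear:nf
      n <- length(frames)
      stalled_at <- NA_integer_
      if (config$stall_prob > 0) {
        g <- stats::rgeom(1, config$stall_prob)  # frames grown before stall
        if (g < n - 1) stalled_at <- frames[g + 2L]
      }
      grow <- rep(config$extension_rate, n)
      grow[1] <- 0
      if (!is.na(stalled_at)) grow[frames >= stalled_at] <- 0
      len <- len0 + cumsum(grow)

      events <- list(data.frame(hypha_id = id, frame = appear,
                                time_min = (appear - 1) * fi,
                                event = if (is.na(parent)) "germination" else "branch",
                                value = parent %||% NA_character_))
      if (!is.na(stalled_at)) {
        events <- c(events, list(data.frame(
          hypha_id = id, frame = stalled_at, time_min = (stalled_at - 1) * fi,
          event = "stall", value = NA_character_)))
      }

      # focus chain state: first element is tip distance of the proximal
      # focus; later elements are separations governed by .sister_sep()
      ids <- integer(0); split_frame <- integer(0); steady <- numeric(0)
      chain_start <- NA_integer_
      focus_rows <- list()
      for (k in seq_len(n)) {
        f <- frames[k]
        if (is.na(chain_start) && f >= has_focus_from) {
          chain_start <- f
          ids <- next_focus; next_focus <<- next_focus + 1L
          split_frame <- f; steady <- NA_real_
          if (!is.na(parent)) {
            events <- c(events, list(data.frame(
              hypha_id = id, frame = f, time_min = (f - 1) * fi,
              event = "focus_arrival", value = as.character(ids[1]))))
          }
        }
        if (!is.na(chain_start)) {
          since <- f - chain_start
          if (since > 0 && since %% config$duplication_interval == 0L) {
            new_id <- next_focus; next_focus <<- next_focus + 1L
            ids <- c(ids[1], new_id, ids[-1])
            split_frame <- c(split_frame[1], f, split_frame[-1])
            steady <- c(steady[1],
                        config$focus_spacing * (1 + stats::rnorm(1, 0, 0.05)),
                        steady[-1])
            events <- c(events, list(data.frame(
              hypha_id = id, frame = f, time_min = (f - 1) * fi,
              event = "duplication",
              value = paste(ids[1], new_id, sep = ":"))))
          }
          d1 <- config$tip_focus_distance +
            config$tip_drift * (f - chain_start)
          seps <- if (length(ids) > 1) {
            .sister_sep((f - split_frame[-1]) * fi, config$split_rate,
                        steady[-1])
          } else numeric(0)
          pos <- cumsum(c(d1, seps))
          inside <- pos <= len[k] - 0.1
          if (any(inside)) {
            focus_rows <- c(focus_rows, list(data.frame(
              hypha_id = id, frame = f, time_min = (f - 1) * fi,
              focus_id = ids[inside], dist_um = pos[inside])))
          }
        }
      }
      foci <- if (length(focus_rows)) do.call(rbind, focus_rows) else NULL

      # intensity profiles (position measured from the tip)
      prof_rows <- vector("list", n)
      for (k in seq_len(n)) {
        f <- frames[k]
        grid <- seq(0, len[k], by = config$pixel_size)
        base <- 15 + 0.8 * grid
        sig <- base
        if (!is.null(foci)) {
          p <- foci$dist_um[foci$frame == f]
          for (pp in p) {
            sig <- sig + config$peak_amplitude *
              exp(-(grid - pp)^2 / (2 * config$peak_sigma^2))
          }
        }
        if (config$noise_sigma > 0) {
          sig <- sig + stats::rnorm(length(grid), 0, config$noise_sigma)
        }
        prof_rows[[k]] <- data.frame(hypha_id = id, frame = f,
                                     position_um = grid, intensity = sig)
      }

      list(hypha = data.frame(hypha_id = id,
                              parent_id = parent %||% NA_character_,
                              frame = frames, time_min = (frames - 1) * fi,
                              tip_um = len, length_um = len),
           profiles = do.call(rbind, prof_rows), foci = foci,
           events = do.call(rbind, events))
    }

    for (i in seq_len(config$n_hyphae)) {
      id <- sprintf("h%03d", i)
      res <- simulate_one(id, NA_character_, 1L, 3, 1L)
      hy <- c(hy, list(res$hypha)); pr <- c(pr, list(res$profiles))
      fo <- c(fo, list(res$foci)); ev <- c(ev, list(res$events))
      # branching off the main hypha
      if (config$branch_prob > 0 && nf > 3) {
        bframes <- which(stats::runif(nf) < config$branch_prob)
        bframes <- bframes[bframes > 1 & bframes < nf - 1]
        for (j in seq_along(bframes)) {
          bid <- sprintf("%s_b%d", id, j)
          delay <- max(0, config$branch_focus_delay + stats::rnorm(1, 0, 5))
          focus_from <- bframes[j] + ceiling(delay / fi)
          resb <- simulate_one(bid, id, bframes[j], 1.2, focus_from)
          hy <- c(hy, list(resb$hypha)); pr <- c(pr, list(resb$profiles))
          fo <- c(fo, list(resb$foci)); ev <- c(ev, list(resb$events))
        }
      }
    }
    list(hyphae = do.call(rbind, hy), profiles = do.call(rbind, pr),
         foci = do.call(rbind, Filter(Negate(is.null), fo)),
         events = do.call(rbind, ev), config = config)
  })
}
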