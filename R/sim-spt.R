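#' Simulate two-state PALM localization data
#'
#' Simulates `n_molecules` molecules switching between a slow (DNA-bound) and
#' fast (free) Brownian state, imaged at `dt` seconds per frame with
#' localization error, blinking (single-frame dropouts) and photobleaching
#' (geometric track termination). Displacements over a frame interval use the
#' state occupied at the source frame, so squared lag-1 step lengths are
#' exponential with mean `4 * D_state * dt + 4 * loc_sigma^2` per state.
#' Trajectories reflect at the field-of-view boundary.
#'
#' @param config a [spt_sim_config()].
#' @return list with `localizations` (data.frame: `loc_id`, `frame`, `x_um`,
#'   `y_um`, `intensity` -- what a detector would emit), `truth` (data.frame
#'   joining 1:1 on `loc_id` with `molecule`, `state` ("slow"/"fast") and
#'   noise-free coordinates), and the `config`.
#' @examples
#' sim <- simulate_spt(spt_sim_config(n_molecules = 20, n_frames = 10,
#'                                    p_bleach = 0, p_blink = 0, seed = 1))
#' nrow(sim$localizations)  # 20 * 10
#' @export
simulate_spt <- function(config) {
  stopifnot(inherits(config, "spt_sim_config"))
  with_seed(config$seed, {
    n <- config$n_molecules
    nf <- config$n_frames
    # activation frame and bleaching lifetime (frames observed)
    start <- if (config$stagger) sample.int(nf, n, replace = TRUE) else rep(1L, n)
    life <- if (config$p_bleach > 0) 1L + stats::rgeom(n, config$p_bleach) else rep(nf, n)
    end <- pmin(start + life - 1L, nf)
    len <- end - start + 1L

    # state chains: 1 = slow, 2 = fast; stationary occupancy = f_slow
    p_sf <- config$switch_prob * (1 - config$f_slow)
    p_fs <- config$switch_prob * config$f_slow
    states <- matrix(NA_integer_, n, nf)
    states[, 1] <- ifelse(stats::runif(n) < config$f_slow, 1L, 2L)
    if (nf > 1) {
      for (k in 2:nf) {
        u <- stats::runif(n)
        prev <- states[, k - 1L]
        flip <- (prev == 1L & u < p_sf) | (prev == 2L & u < p_fs)
        states[, k] <- ifelse(flip, 3L - prev, prev)
      }
    }

    sd_state <- sqrt(2 * c(config$D_slow, config$D_fast) * config$dt)
    x <- matrix(NA_real_, n, nf)
    y <- matrix(NA_real_, n, nf)
    x[, 1] <- stats::runif(n, 0, config$fov[1])
    y[, 1] <- stats::runif(n, 0, config$fov[2])
    if (nf > 1) {
      for (k in 2:nf) {
        s <- sd_state[states[, k - 1L]]
        x[, k] <- reflect_into(x[, k - 1L] + stats::rnorm(n, 0, s), config$fov[1])
        y[, k] <- reflect_into(y[, k - 1L] + stats::rnorm(n, 0, s), config$fov[2])
      }
    }

    # expand to (molecule, frame) records within each molecule's lifetime
    mol <- rep.int(seq_len(n), len)
    frame <- unlist(lapply(seq_len(n), function(i) seq.int(start[i], end[i])),
                    use.names = FALSE)
    idx <- cbind(mol, frame)
    xt <- x[idx]; yt <- y[idx]; st <- states[idx]
    xo <- reflect_into(xt + stats::rnorm(length(xt), 0, config$loc_sigma),
                       config$fov[1])
    yo <- reflect_into(yt + stats::rnorm(length(yt), 0, config$loc_sigma),
                       config$fov[2])
    keep <- if (config$p_blink > 0) {
      stats::runif(length(xt)) >= config$p_blink
    } else rep(TRUE, length(xt))
    intensity <- stats::rlnorm(length(xt), meanlog = log(1000), sdlog = 0.3)

    ord <- order(frame, mol)
    keep_o <- keep[ord]
    loc_id <- seq_len(sum(keep_o))
    sel <- ord[keep_o]
    localizations <- data.frame(
      loc_id = loc_id, frame = frame[sel], x_um = xo[sel], y_um = yo[sel],
      intensity = intensity[sel])
    truth <- data.frame(
      loc_id = loc_id, molecule = mol[sel], frame = frame[sel],
      state = c("slow", "fast")[st[sel]], x_true_um = xt[sel],
      y_true_um = yt[sel])
    list(localizations = localizations, truth = truth, config = config)
  })
}

#' Ground-truth tracks from a PALM simulation
#'
#' Convenience accessor turning the simulator truth table into the track
#' data.frame layout produced by [link_tracks()] (one track per molecule),
#' bypassing the linking step when only the downstream fit is under study.
#'
#' @param sim result of [simulate_spt()].
#' @return data.frame with `track_id`, `frame`, `x_um`, `y_um`, `loc_id`.
#' @export
truth_tracks <- function(sim) {
  tr <- merge(sim$truth[, c("loc_id", "molecule", "frame")],
              sim$localizations[, c("loc_id", "x_um", "y_um")], by = "loc_id")
  tr <- tr[order(tr$molecule, tr$frame), ]
  data.frame(track_id = tr$molecule, frame = tr$frame, x_um = tr$x_um,
             y_um = tr$y_um, loc_id = tr$loc_id, row.names = NULL)
}
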