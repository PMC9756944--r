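#' Tracking configuration
#'
#' Defaults follow the published acquisition rule: localizations are linked
#' if they appear in consecutive frames within a 0.6 um radius, with one
#' missing frame allowed (gap closing at the same radius).
#'
#' @param link_radius maximum linking distance (um).
#' @param max_gap number of missing frames tolerated.
#' @param dt frame interval in seconds.
#' @return object of class `tracking_config`.
#' @export
tracking_config <- function(link_radius = 0.6, max_gap = 1L, dt = 0.03) {
  stop_if_not_pos(link_radius, "link_radius")
  if (!is.numeric(max_gap) || max_gap < 0 || max_gap != round(max_gap)) {
    stop("`max_gap` must be an integer >= 0", call. = FALSE)
  }
  stop_if_not_pos(dt, "dt")
  structure(list(link_radius = link_radius, max_gap = as.integer(max_gap),
                 dt = dt), class = "tracking_config")
}

# Greedy distance-ascending partial matching between two point sets.
# Returns integer index into (xs, ys) for each (xt, yt), NA if unmatched.
.greedy_match <- function(xt, yt, xs, ys, radius) {
  nt <- length(xt); ns <- length(xs)
  out <- rep(NA_integer_, nt)
  if (nt == 0L || ns == 0L) return(out)
  d2 <- outer(xt, xs, "-")^2 + outer(yt, ys, "-")^2
  ok <- which(d2 <= radius^2)
  if (length(ok) == 0L) return(out)
  ord <- ok[order(d2[ok])]
  used_t <- logical(nt); used_s <- logical(ns)
  ti <- (ord - 1L) %% nt + 1L
  si <- (ord - 1L) %/% nt + 1L
  for (k in seq_along(ord)) {
    if (!used_t[ti[k]] && !used_s[si[k]]) {
      out[ti[k]] <- si[k]
      used_t[ti[k]] <- TRUE
      used_s[si[k]] <- TRUE
    }
  }
  out
}

#' Link localizations into tracks
#'
#' Frame-to-frame assignment is a greedy partial matching in order of
#' ascending distance, restricted to pairs closer than `link_radius`. Track
#' ends left unmatched are retried against localizations `g + 1` frames ahead
#' for gaps `g = 1, ..., max_gap` (same radius). Every localization is
#' assigned to exactly one track; localizations matching nothing become
#' singleton tracks.
#'
#' @param localizations data.frame with integer `frame` and finite `x_um`,
#'   `y_um` (a `loc_id` column is carried through if present).
#' @param config a [tracking_config()].
#' @return data.frame `track_id`, `frame`, `x_um`, `y_um`, `loc_id`, ordered
#'   by track then frame, with the config attached as attribute `"config"`.
#' @export
link_tracks <- function(localizations, config = tracking_config()) {
  stopifnot(inherits(config, "tracking_config"))
  loc <- as.data.frame(localizations)
  need <- c("frame", "x_um", "y_um")
  if (!all(need %in% names(loc))) {
    stop("localizations need columns frame, x_um, y_um", call. = FALSE)
  }
  if (anyNA(loc$x_um) || anyNA(loc$y_um) || anyNA(loc$frame)) {
    stop("NaN/NA coordinates or frames are not allowed", call. = FALSE)
  }
  if (any(loc$frame != round(loc$frame))) {
    stop("frames must be integers", call. = FALSE)
  }
  if (is.null(loc$loc_id)) loc$loc_id <- seq_len(nrow(loc))
  n <- nrow(loc)
  if (n == 0L) {
    return(structure(data.frame(track_id = integer(0), frame = integer(0),
                                x_um = numeric(0), y_um = numeric(0),
                                loc_id = integer(0)), config = config))
  }

  ord <- order(loc$frame, loc$loc_id)
  loc <- loc[ord, , drop = FALSE]
  frames <- sort(unique(loc$frame))
  by_frame <- split(seq_len(n), factor(loc$frame, levels = frames))

  track_of <- rep(NA_integer_, n)
  # per-track tail bookkeeping: row index of last localization
  tail_row <- integer(0)
  tail_frame <- integer(0)
  next_track <- 1L

  for (f in frames) {
    rows <- by_frame[[as.character(f)]]
    unassigned <- rows
    for (g in 0:config$max_gap) {
      if (length(unassigned) == 0L) break
      cand <- which(tail_frame == f - 1L - g)
      if (length(cand) == 0L) next
      m <- .greedy_match(loc$x_um[tail_row[cand]], loc$y_um[tail_row[cand]],
                         loc$x_um[unassigned], loc$y_um[unassigned],
                         config$link_radius)
      hit <- which(!is.na(m))
      for (k in hit) {
        tr <- cand[k]
        row <- unassigned[m[k]]
        track_of[row] <- tr
        tail_row[tr] <- row
        tail_frame[tr] <- f
      }
      if (length(hit)) unassigned <- unassigned[-m[hit]]
    }
    if (length(unassigned)) {
      ids <- next_track:(next_track + length(unassigned) - 1L)
      track_of[unassigned] <- ids
      tail_row[ids] <- unassigned
      tail_frame[ids] <- f
      next_track <- next_track + length(unassigned)
    }
  }
  out <- data.frame(track_id = track_of, frame = loc$frame, x_um = loc$x_um,
                    y_um = loc$y_um, loc_id = loc$loc_id)
  out <- out[order(out$track_id, out$frame), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, config = config)
}

#' Squared step displacements of one track
#'
#' Returns `r^2` for all localization pairs separated by exactly `lag`
#' positions along the observed track. Pairs spanning a closed gap are
#' flagged via `frame_lag` (their true time separation in frames), which
#' lets the mixture fit exclude or rescale them.
#'
#' @param track data.frame for a single track (`frame`, `x_um`, `y_um`).
#' @param lag positive integer lag in observed positions.
#' @return data.frame with `r2` (um^2), `frame_lag` and `gap` (logical:
#'   `frame_lag > lag`); zero rows if the track is too short.
#' @export
step_displacements <- function(track, lag = 1L) {
  if (lag < 1 || lag != round(lag)) stop("`lag` must be an integer >= 1",
                                         call. = FALSE)
  tr <- track[order(track$frame), , drop = FALSE]
  m <- nrow(tr)
  if (m <= lag) {
    return(data.frame(r2 = numeric(0), frame_lag = integer(0),
                      gap = logical(0)))
  }
  i <- seq_len(m - lag)
  dx <- tr$x_um[i + lag] - tr$x_um[i]
  dy <- tr$y_um[i + lag] - tr$y_um[i]
  fl <- tr$frame[i + lag] - tr$frame[i]
  data.frame(r2 = dx^2 + dy^2, frame_lag = as.integer(fl), gap = fl > lag)
}

# All lag-1 squared displacements of a track table, with track ids.
# Used by the mixture fit and the mobility classifier.
.all_steps <- function(tracks, include_gap_steps = FALSE) {
  parts <- lapply(split(tracks, tracks$track_id), function(tr) {
    s <- step_displacements(tr, 1L)
    if (nrow(s) == 0) return(NULL)
    s$track_id <- tr$track_id[1]
    s
  })
  out <- do.call(rbind, Filter(Negate(is.null), parts))
  if (is.null(out)) {
    out <- data.frame(r2 = numeric(0), frame_lag = integer(0),
                      gap = logical(0), track_id = integer(0))
  }
  if (!include_gap_steps) out <- out[!out$gap, , drop = FALSE]
  rownames(out) <- NULL
  out
}
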