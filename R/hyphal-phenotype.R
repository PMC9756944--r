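# Germination and growth-arrest phenotype rules from the time-lapse
# protocol: spores with no hypha over the whole 16-h observation are
# nongerminating; germlings whose extension pauses for more than 1 h are
# inhibited; branches with no extension for at least 2 h and no
# re-initiation before the end of the experiment are stalled.

#' Phenotype classification rules
#'
#' @param total_observation observation span in minutes (16 h).
#' @param germ_inhibit_window pause (min) beyond which a germling counts as
#'   growth-inhibited (strictly greater than).
#' @param branch_stall_window pause (min) from which a branch counts as
#'   stalled when growth never re-initiates (greater than or equal).
#' @param extension_epsilon minimum per-frame tip movement (um) counted as
#'   extension (sub-pixel jitter is not growth).
#' @return object of class `phenotype_rules`.
#' @export
phenotype_rules <- function(total_observation = 960, germ_inhibit_window = 60,
                            branch_stall_window = 120,
                            extension_epsilon = 0.2) {
  stop_if_not_pos(c(total_observation, germ_inhibit_window,
                    branch_stall_window), "windows")
  stop_if_not_pos(extension_epsilon, "extension_epsilon", strict = FALSE)
  if (germ_inhibit_window > total_observation ||
      branch_stall_window > total_observation) {
    stop("rule windows must not exceed `total_observation`", call. = FALSE)
  }
  structure(list(total_observation = total_observation,
                 germ_inhibit_window = germ_inhibit_window,
                 branch_stall_window = branch_stall_window,
                 extension_epsilon = extension_epsilon),
            class = "phenotype_rules")
}

#' Classify the growth phenotype of one hypha or spore
#'
#' The record is scanned for extension events (tip movement greater than
#' `extension_epsilon` between consecutive frames). Decision order:
#' \itemize{
#'   \item series covering less than `total_observation` minutes:
#'     `"unclassifiable"`;
#'   \item no emergence (length stays 0) across the whole observation:
#'     `"nongerminating"`;
#'   \item a branch whose final extension pause lasts at least
#'     `branch_stall_window` and reaches the end of the record (no
#'     re-initiation): `"stalled_branch"`, otherwise `"growing"`;
#'   \item a spore-derived hypha with a pause strictly longer than
#'     `germ_inhibit_window` after initial extension: `"inhibited"`,
#'     otherwise `"germinated"`.
#' }
#' Pause durations are boundary-exact: a pause of exactly 60 min does not
#' make a germling inhibited, a final pause of exactly 120 min does make a
#' branch stalled.
#'
#' @param hypha per-frame record (`time_min`, `length_um`), one hypha;
#'   `parent_id` (column or argument) marks branches.
#' @param rules a [phenotype_rules()].
#' @param is_branch override for branch status; default taken from a
#'   non-`NA` `parent_id` column.
#' @return character scalar phenotype.
#' @export
classify_phenotype <- function(hypha, rules = phenotype_rules(),
                               is_branch = NULL) {
  stopifnot(inherits(rules, "phenotype_rules"))
  h <- hypha[order(hypha$time_min), , drop = FALSE]
  if (is.null(is_branch)) {
    is_branch <- !is.null(h$parent_id) && any(!is.na(h$parent_id))
  }
  # times are minutes from the start of the experiment; the record must
  # reach the end of the observation window to be classifiable
  if (max(h$time_min) < rules$total_observation) return("unclassifiable")
  if (all(h$length_um <= 0)) return("nongerminating")

  len <- h$length_um
  t <- h$time_min
  ext <- diff(len) > rules$extension_epsilon
  emerged <- len > 0
  # pauses: maximal runs of non-extending steps after emergence
  first_ext <- which(ext)[1]
  if (is.na(first_ext)) {
    # emerged but never extended: one pause covering the record
    pause_start <- t[1]; pause_end <- t[length(t)]
    pauses <- data.frame(start = pause_start, end = pause_end,
                         to_end = TRUE)
  } else {
    r <- rle(ext)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    idx <- which(!r$values)
    pauses <- data.frame(start = t[starts[idx]], end = t[ends[idx] + 1L],
                         to_end = ends[idx] == length(ext))
  }
  if (!is.na(first_ext)) {
    # only pauses after the initial extension count
    pauses <- pauses[pauses$start >= t[first_ext], , drop = FALSE]
  }
  if (nrow(pauses)) {
    dur <- pauses$end - pauses$start
    if (is_branch) {
      if (any(pauses$to_end & dur >= rules$branch_stall_window)) {
        return("stalled_branch")
      }
    } else if (any(dur > rules$germ_inhibit_window)) {
      return("inhibited")
    }
  }
  if (is_branch) "growing" else "germinated"
}

#' Time from branch appearance to first chromosomal focus
#'
#' @param branch per-frame record of one branch (`frame`, `time_min`).
#' @param foci focus table for that branch (`frame` at minimum).
#' @return one-row data.frame: `appearance_min`, `first_focus_min`,
#'   `delay_min` (NA when no focus ever appears) and `focus_free`.
#' @export
branch_first_focus_time <- function(branch, foci) {
  t0 <- min(branch$time_min)
  ff <- foci[foci$frame %in% branch$frame, , drop = FALSE]
  if (nrow(ff) == 0) {
    return(data.frame(appearance_min = t0, first_focus_min = NA_real_,
                      delay_min = NA_real_, focus_free = TRUE))
  }
  fmin <- min(ff$frame)
  t1 <- branch$time_min[match(fmin, branch$frame)]
  data.frame(appearance_min = t0, first_focus_min = t1,
             delay_min = t1 - t0, focus_free = FALSE)
}

#' Paired stalled-vs-growing sampling of tip distance and focus count
#'
#' Reproduces the comparison protocol behind the stalled/growing contrasts:
#' stalled hyphae are measured 10 minutes (one frame) before growth arrest,
#' and each is paired with a normally growing hypha measured at the frame
#' where its length is closest to the stalled hypha's length at measurement.
#'
#' @param hyphae per-frame records (`hypha_id`, `frame`, `time_min`,
#'   `length_um`).
#' @param foci detected focus table (`hypha_id`, `frame`, `position_um`).
#' @param events event log containing `stall` rows (from
#'   [simulate_hyphae()]) or a data.frame (`hypha_id`, `frame`) of arrest
#'   frames.
#' @return data.frame with one row per measured hypha: `group`
#'   ("stalled"/"growing"), `hypha_id`, `frame`, `length_um`,
#'   `tip_distance_um`, `n_foci`.
#' @export
stall_growth_comparison <- function(hyphae, foci, events) {
  st <- if (!is.null(events$event)) {
    events[events$event == "stall", c("hypha_id", "frame")]
  } else events[, c("hypha_id", "frame")]
  measure <- function(hid, f) {
    p <- foci$position_um[foci$hypha_id == hid & foci$frame == f]
    len <- hyphae$length_um[hyphae$hypha_id == hid & hyphae$frame == f]
    data.frame(hypha_id = hid, frame = f, length_um = len[1],
               tip_distance_um = if (length(p)) min(p) else NA_real_,
               n_foci = length(p))
  }
  rows <- list()
  growing_ids <- setdiff(unique(hyphae$hypha_id), st$hypha_id)
  for (i in seq_len(nrow(st))) {
    f <- st$frame[i] - 1L
    hid <- st$hypha_id[i]
    if (!any(hyphae$hypha_id == hid & hyphae$frame == f)) next
    ms <- cbind(group = "stalled", measure(hid, f))
    rows <- c(rows, list(ms))
    if (length(growing_ids)) {
      # pick the growing hypha/frame with the closest length
      gg <- hyphae[hyphae$hypha_id %in% growing_ids, , drop = FALSE]
      j <- which.min(abs(gg$length_um - ms$length_um))
      rows <- c(rows, list(cbind(group = "growing",
                                 measure(gg$hypha_id[j], gg$frame[j]))))
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(group = character(0), hypha_id = character(0),
                      frame = integer(0), length_um = numeric(0),
                      tip_distance_um = numeric(0), n_foci = integer(0))
  }
  rownames(out) <- NULL
  out
}
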