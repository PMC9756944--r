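# Independent oracles used by the tests. Deliberately naive/brute-force:
# they never share code with the implementation they check.

# Minimum-total-distance perfect matching between equal-sized point sets,
# by exhaustive permutation (n <= 7). Returns the assignment and whether
# the optimum is unique (up to 1e-12).
brute_force_matching <- function(x1, y1, x2, y2) {
  n <- length(x1)
  stopifnot(n == length(x2), n <= 7)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    }
    out
  }
  best <- NULL; best_cost <- Inf; unique_opt <- TRUE
  for (p in perms(seq_len(n))) {
    cost <- sum(sqrt((x1 - x2[p])^2 + (y1 - y2[p])^2))
    if (cost < best_cost - 1e-12) {
      best <- p; best_cost <- cost; unique_opt <- TRUE
    } else if (abs(cost - best_cost) <= 1e-12 && !identical(p, best)) {
      unique_opt <- FALSE
    }
  }
  list(assignment = best, cost = best_cost, unique = unique_opt)
}

# Naive FASTA parser (oracle for read_fasta).
naive_fasta <- function(path) {
  lines <- readLines(path)
  headers <- grep("^>", lines)
  stopifnot(length(headers) > 0)
  out <- list()
  bounds <- c(headers, length(lines) + 1L)
  for (i in seq_along(headers)) {
    nm <- sub("^>\\s*(\\S+).*$", "\\1", lines[headers[i]])
    body <- lines[seq.int(headers[i] + 1L, bounds[i + 1L] - 1L)]
    out[[nm]] <- paste(body, collapse = "")
  }
  out
}

# Brute-force interval-overlap counter on 0-based half-open intervals.
brute_force_overlap_counts <- function(win_start0, win_end0, frag_start0,
                                       frag_end0) {
  vapply(seq_along(win_start0), function(i) {
    sum(frag_start0 < win_end0[i] & frag_end0 > win_start0[i])
  }, numeric(1))
}

# Truth-vs-detected focus matching: recall and false-positive rate with a
# positional tolerance (um), computed per hypha and frame.
focus_detection_scores <- function(truth, detected, tol = 0.25) {
  tp <- 0L; fn <- 0L
  for (i in seq_len(nrow(truth))) {
    d <- detected[detected$hypha_id == truth$hypha_id[i] &
                    detected$frame == truth$frame[i], ]
    hit <- nrow(d) > 0 && min(abs(d$position_um - truth$dist_um[i])) <= tol
    if (hit) tp <- tp + 1L else fn <- fn + 1L
  }
  fp <- 0L
  for (i in seq_len(nrow(detected))) {
    tr <- truth[truth$hypha_id == detected$hypha_id[i] &
                  truth$frame == detected$frame[i], ]
    miss <- nrow(tr) == 0 ||
      min(abs(tr$dist_um - detected$position_um[i])) > tol
    if (miss) fp <- fp + 1L
  }
  list(recall = tp / max(tp + fn, 1L), fpr = fp / max(nrow(detected), 1L))
}

# GRanges from 0-based half-open coordinates (BED convention).
gr0 <- function(start0, end0, ctg = "chr") {
  GenomicRanges::GRanges(ctg, IRanges::IRanges(start0 + 1, end0))
}

# Build a per-frame hypha record on a 10-min grid from a tip-length vector.
hypha_series <- function(lengths_um, frame_interval = 10, parent = NA) {
  data.frame(hypha_id = "h", parent_id = parent,
             frame = seq_along(lengths_um),
             time_min = (seq_along(lengths_um) - 1) * frame_interval,
             tip_um = lengths_um, length_um = lengths_um)
}
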