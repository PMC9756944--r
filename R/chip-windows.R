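# Sliding-window differential binding scaffolding: tiling, fragment
# counting, the local background filter and binned coverage. Windows use
# 1-based closed GRanges internally; constructors and writers translate
# from/to 0-based half-open BED coordinates.

#' Sliding-window analysis configuration
#'
#' Defaults are the published analysis settings: 69-bp windows with a 23-bp
#' slide, a 2000-bp local background, a log2 fold-change filter of 2, <100 bp
#' region merging and a 0.05 FDR.
#'
#' @param width window width (bp).
#' @param slide window slide (bp); must not exceed `width`.
#' @param bg_window local background width (bp), centred on the window.
#' @param min_log2fc local-enrichment filter threshold (strictly greater
#'   than).
#' @param merge_gap regions strictly closer than this many bp are merged.
#' @param fdr Benjamini-Hochberg threshold across merged regions.
#' @param count_prior pseudocount stabilising the filter log-ratio.
#' @return object of class `window_config`.
#' @export
window_config <- function(width = 69, slide = 23, bg_window = 2000,
                          min_log2fc = 2, merge_gap = 100, fdr = 0.05,
                          count_prior = 0.5) {
  stop_if_not_count(width, "width")
  stop_if_not_count(slide, "slide")
  stop_if_not_count(bg_window, "bg_window")
  if (slide > width) stop("`slide` must be <= `width`", call. = FALSE)
  if (bg_window <= width) stop("`bg_window` must exceed `width`", call. = FALSE)
  if (merge_gap < 0) stop("`merge_gap` must be >= 0", call. = FALSE)
  stop_if_not_prob(fdr, "fdr")
  stop_if_not_pos(count_prior, "count_prior", strict = FALSE)
  structure(list(width = as.integer(width), slide = as.integer(slide),
                 bg_window = as.integer(bg_window), min_log2fc = min_log2fc,
                 merge_gap = as.integer(merge_gap), fdr = fdr,
                 count_prior = count_prior), class = "window_config")
}

#' Tile a genome with sliding windows
#'
#' Windows start at 0, `slide`, `2 * slide`, ... (0-based); the last window
#' of each contig is truncated at the contig end. With the default 69/23
#' geometry every internal base is covered by exactly 3 windows.
#'
#' @param seqlengths named integer vector of contig lengths.
#' @param config a [window_config()].
#' @return [GenomicRanges::GRanges] of windows.
#' @export
tile_windows <- function(seqlengths, config = window_config()) {
  stopifnot(inherits(config, "window_config"))
  if (is.null(names(seqlengths)) || any(seqlengths <= 0)) {
    stop("`seqlengths` must be a named vector of positive lengths",
         call. = FALSE)
  }
  parts <- lapply(names(seqlengths), function(ctg) {
    len <- seqlengths[[ctg]]
    # contigs shorter than one window yield a single truncated window
    starts0 <- if (len <= config$width) 0L else {
      seq.int(0L, len - 1L, by = config$slide)
    }
    ends0 <- pmin(starts0 + config$width, len)
    GenomicRanges::GRanges(ctg, IRanges::IRanges(start = starts0 + 1L,
                                                 end = ends0))
  })
  gr <- do.call(c, parts)
  GenomeInfoDb::seqlengths(gr) <- seqlengths
  gr
}

.as_fragment_list <- function(fragments) {
  if (methods::is(fragments, "GRanges")) fragments <- list(sample = fragments)
  if (is.null(names(fragments))) {
    names(fragments) <- paste0("sample", seq_along(fragments))
  }
  fragments
}

#' Count fragments overlapping each window
#'
#' A fragment contributes one count to every window it overlaps by at least
#' one base (strand is ignored).
#'
#' @param windows window [GenomicRanges::GRanges].
#' @param fragments one [GenomicRanges::GRanges], or a (named) list of them
#'   (one element per sample).
#' @return integer matrix windows x samples, with per-sample totals in
#'   attribute `"totals"`.
#' @export
count_fragments <- function(windows, fragments) {
  fragments <- .as_fragment_list(fragments)
  counts <- vapply(fragments, function(fr) {
    GenomicRanges::countOverlaps(windows, fr, minoverlap = 1L,
                                 ignore.strand = TRUE)
  }, integer(length(windows)))
  counts <- matrix(counts, nrow = length(windows),
                   dimnames = list(NULL, names(fragments)))
  attr(counts, "totals") <- vapply(fragments, length, integer(1))
  counts
}

#' Local background enrichment filter
#'
#' For each window the background is estimated from the surrounding
#' `bg_window` bp (centred, truncated at contig ends with proportional
#' rescaling, the window's own counts excluded):
#' `bg = (count_in_bg - count_in_window) * width / (bg_len - width)`.
#' Windows are retained when
#' `log2((count + prior) / (bg + prior)) > min_log2fc`, evaluated on the
#' mean across the ChIP samples.
#'
#' @param windows window [GenomicRanges::GRanges].
#' @param fragments per-sample fragment list (as in [count_fragments()]).
#' @param config a [window_config()].
#' @param counts optional precomputed window-count matrix.
#' @param chip_samples columns considered ChIP samples for the filter
#'   (default: all).
#' @return list: `keep` (logical), `log2fc_local`, `counts`, `bg_scaled`.
#' @export
local_filter <- function(windows, fragments, config = window_config(),
                         counts = NULL, chip_samples = NULL) {
  stopifnot(inherits(config, "window_config"))
  fragments <- .as_fragment_list(fragments)
  if (is.null(counts)) counts <- count_fragments(windows, fragments)
  chip_samples <- chip_samples %||% seq_len(ncol(counts))
  centre <- (GenomicRanges::start(windows) + GenomicRanges::end(windows)) / 2
  half <- config$bg_window / 2
  lens <- GenomeInfoDb::seqlengths(windows)[as.character(
    GenomeInfoDb::seqnames(windows))]
  lens <- ifelse(is.na(lens), Inf, as.numeric(lens))  # unknown: no truncation
  bstart <- pmax(1, ceiling(centre - half))
  bend <- pmin(lens, floor(centre + half))
  bg_ranges <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(windows),
                                      IRanges::IRanges(bstart, bend))
  bg_counts <- vapply(fragments, function(fr) {
    GenomicRanges::countOverlaps(bg_ranges, fr, minoverlap = 1L,
                                 ignore.strand = TRUE)
  }, integer(length(windows)))
  bg_counts <- matrix(bg_counts, nrow = length(windows))
  w <- GenomicRanges::width(windows)
  bg_len <- bend - bstart + 1
  win_mean <- rowMeans(counts[, chip_samples, drop = FALSE])
  bg_mean <- rowMeans(bg_counts[, chip_samples, drop = FALSE])
  bg_scaled <- unname(pmax(bg_mean - win_mean, 0) * w / pmax(bg_len - w, 1))
  lfc <- log2((win_mean + config$count_prior) /
                (bg_scaled + config$count_prior))
  list(keep = lfc > config$min_log2fc & win_mean > 0, log2fc_local = lfc,
       counts = counts, bg_scaled = bg_scaled)
}

#' Coverage configuration
#'
#' @param bin bin width in bp (200 bp in the published coverage tracks).
#' @param average average across samples after normalisation.
#' @return object of class `coverage_config`.
#' @export
coverage_config <- function(bin = 200, average = TRUE) {
  stop_if_not_count(bin, "bin")
  structure(list(bin = as.integer(bin), average = isTRUE(average)),
            class = "coverage_config")
}

#' Binned, total-read-normalised coverage
#'
#' Fragments are counted in `bin`-bp bins and divided by the sample's total
#' fragment count; replicate tracks are optionally averaged.
#'
#' @param fragments per-sample fragment list.
#' @param seqlengths named contig lengths.
#' @param config a [coverage_config()].
#' @return data.frame `contig`, `start` (0-based), `end`, then one column
#'   per sample, plus `mean` when `average` is set.
#' @export
binned_coverage <- function(fragments, seqlengths,
                            config = coverage_config()) {
  stopifnot(inherits(config, "coverage_config"))
  fragments <- .as_fragment_list(fragments)
  parts <- lapply(names(seqlengths), function(ctg) {
    len <- seqlengths[[ctg]]
    starts0 <- seq.int(0L, len - 1L, by = config$bin)
    ends0 <- pmin(starts0 + config$bin, len)
    GenomicRanges::GRanges(ctg, IRanges::IRanges(starts0 + 1L, ends0))
  })
  bins <- do.call(c, parts)
  out <- data.frame(contig = as.character(GenomeInfoDb::seqnames(bins)),
                    start = GenomicRanges::start(bins) - 1L,
                    end = GenomicRanges::end(bins))
  for (nm in names(fragments)) {
    total <- length(fragments[[nm]])
    if (total == 0) stop("sample with zero fragments: ", nm, call. = FALSE)
    out[[nm]] <- GenomicRanges::countOverlaps(bins, fragments[[nm]],
                                              ignore.strand = TRUE) / total
  }
  if (config$average) {
    out$mean <- rowMeans(out[, names(fragments), drop = FALSE])
  }
  out
}
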