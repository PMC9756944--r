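# Negative-binomial inference for windowed ChIP counts: a common dispersion
# estimated by Cox-Reid adjusted profile likelihood, a per-window NB GLM
# with log library-size offsets, Simes combination over merged regions and
# Benjamini-Hochberg FDR across regions. Vectorised across windows (the
# one-factor design admits a per-group Newton solve on the log mean).

# Solve, per window and group, the NB score equation for the log rate theta
# (mu_j = N_j * exp(theta)): sum_j (y_j - mu_j) / (1 + phi * mu_j) = 0.
# Y: windows x samples matrix; N: library sizes. Returns windows-vector.
.nb_theta <- function(Y, N, phi, iter = 30L) {
  tot <- rowSums(Y)
  theta <- log(pmax(tot, 0.5) / sum(N))
  for (it in seq_len(iter)) {
    mu <- exp(theta) %o% N                     # windows x samples
    denom <- 1 + phi * mu
    f <- rowSums((Y - mu) / denom)
    fp <- -rowSums(mu * (1 + phi * Y) / denom^2)
    step <- f / pmin(fp, -1e-10)
    step <- pmax(pmin(step, 2), -2)            # damp large Newton steps
    theta <- theta - step
    if (max(abs(step)) < 1e-10) break
  }
  theta
}

.nb_loglik_rows <- function(Y, mu, phi) {
  if (phi < 1e-8) {
    rowSums(stats::dpois(Y, pmax(mu, 1e-300), log = TRUE))
  } else {
    rowSums(stats::dnbinom(Y, size = 1 / phi, mu = pmax(mu, 1e-300),
                           log = TRUE))
  }
}

# Fisher information of theta per group (used for the Cox-Reid adjustment):
# I_g = sum_{j in g} mu_j / (1 + phi mu_j).
.cr_adjust_rows <- function(mu, phi, group_idx) {
  adj <- 0
  for (idx in group_idx) {
    w <- mu[, idx, drop = FALSE] / (1 + phi * mu[, idx, drop = FALSE])
    adj <- adj + log(pmax(rowSums(w), 1e-300))
  }
  adj / 2
}

#' Estimate a common NB dispersion by Cox-Reid adjusted profile likelihood
#'
#' Maximises, over the dispersion `phi`, the sum across windows of the NB
#' profile log-likelihood at the per-group fitted means minus half the log
#' determinant of the Fisher information of the mean parameters (the
#' Cox-Reid adjustment); the search is on log(phi).
#'
#' @param counts integer matrix, windows x samples.
#' @param groups factor/vector of condition labels per sample (a single
#'   group is allowed, e.g. for intercept-only dispersion estimation).
#' @param lib_sizes library sizes (default: column totals of `counts`).
#' @return list with `phi` and `wide_flag` (`TRUE` when fewer than 50
#'   windows informed the estimate; a warning is also raised).
#' @export
estimate_dispersion <- function(counts, groups = NULL, lib_sizes = NULL) {
  Y <- as.matrix(counts)
  if (ncol(Y) < 2) stop("need at least 2 samples", call. = FALSE)
  if (all(Y == 0)) stop("all counts are zero", call. = FALSE)
  groups <- factor(groups %||% rep("all", ncol(Y)))
  N <- lib_sizes %||% pmax(colSums(Y), 1)
  keep <- rowSums(Y) > 0
  Y <- Y[keep, , drop = FALSE]
  wide_flag <- nrow(Y) < 50
  if (wide_flag) {
    warning("dispersion estimated from ", nrow(Y),
            " windows; estimate is wide", call. = FALSE)
  }
  group_idx <- split(seq_len(ncol(Y)), groups)
  apl <- function(log_phi) {
    phi <- exp(log_phi)
    mu <- matrix(0, nrow(Y), ncol(Y))
    for (idx in group_idx) {
      th <- .nb_theta(Y[, idx, drop = FALSE], N[idx], phi)
      mu[, idx] <- exp(th) %o% N[idx]
    }
    sum(.nb_loglik_rows(Y, mu, phi)) - sum(.cr_adjust_rows(mu, phi, group_idx))
  }
  opt <- stats::optimize(apl, interval = log(c(1e-6, 5)), maximum = TRUE,
                         tol = 1e-3)
  list(phi = exp(opt$maximum), wide_flag = wide_flag)
}

#' Per-window NB GLM test for differential binding
#'
#' Fits, per window, a negative-binomial log-linear model with log
#' library-size offsets and a two-level group factor at a fixed dispersion
#' `phi`, and tests the group coefficient. The primary inference is the
#' likelihood-ratio test against chi-squared with 1 df; `test = "qlf"`
#' rescales the LR statistic by a global quasi-likelihood dispersion
#' (mean residual deviance per df across windows) and refers it to an F
#' distribution -- a simplified quasi-likelihood variant.
#'
#' @param counts integer matrix, windows x samples.
#' @param groups two-level factor/vector per sample; the log2 fold change is
#'   `first level - second level` on the log2 scale.
#' @param phi common NB dispersion (e.g. from [estimate_dispersion()]).
#' @param lib_sizes library sizes (default: column totals).
#' @param test `"lrt"` or `"qlf"`.
#' @return data.frame with `log2fc`, `stat`, `p`; all-zero windows get
#'   `log2fc = 0`, `p = 1`.
#' @export
nb_test <- function(counts, groups, phi, lib_sizes = NULL,
                    test = c("lrt", "qlf")) {
  test <- match.arg(test)
  Y <- as.matrix(counts)
  groups <- factor(groups)
  if (nlevels(groups) != 2) stop("`groups` must have exactly 2 levels",
                                 call. = FALSE)
  if (min(table(groups)) < 1) stop("each group needs >= 1 sample",
                                   call. = FALSE)
  N <- lib_sizes %||% pmax(colSums(Y), 1)
  ia <- which(groups == levels(groups)[1])
  ib <- which(groups == levels(groups)[2])

  th_a <- .nb_theta(Y[, ia, drop = FALSE], N[ia], phi)
  th_b <- .nb_theta(Y[, ib, drop = FALSE], N[ib], phi)
  th_0 <- .nb_theta(Y, N, phi)
  mu1 <- matrix(0, nrow(Y), ncol(Y))
  mu1[, ia] <- exp(th_a) %o% N[ia]
  mu1[, ib] <- exp(th_b) %o% N[ib]
  mu0 <- exp(th_0) %o% N
  lr <- pmax(2 * (.nb_loglik_rows(Y, mu1, phi) -
                    .nb_loglik_rows(Y, mu0, phi)), 0)
  zero <- rowSums(Y) == 0
  lr[zero] <- 0
  log2fc <- (th_a - th_b) / log(2)
  log2fc[zero] <- 0
  if (test == "lrt") {
    p <- stats::pchisq(lr, df = 1, lower.tail = FALSE)
  } else {
    # global QL dispersion: residual deviance of the full fit per df
    mu_sat <- Y
    dev <- 2 * (.nb_loglik_rows(Y, pmax(mu_sat, 1e-8), phi) -
                  .nb_loglik_rows(Y, mu1, phi))
    df_res <- ncol(Y) - 2L
    s2 <- max(mean(dev[!zero]) / df_res, 1e-8)
    p <- stats::pf(lr / s2, df1 = 1, df2 = df_res * max(sum(!zero), 1),
                   lower.tail = FALSE)
  }
  p[zero] <- 1
  data.frame(log2fc = log2fc, stat = lr, p = p)
}

# Simes combined p-value over a vector of member p-values.
.simes <- function(p) {
  p <- sort(p)
  min(pmin(p * length(p) / seq_along(p), 1))
}

#' Merge tested windows into differential regions
#'
#' Windows separated by a gap strictly smaller than `merge_gap` bp are
#' merged transitively (overlapping/adjacent windows always merge); each
#' region's combined p-value is the Simes combination over its member
#' windows; FDR is Benjamini-Hochberg across regions; `direction` is the
#' sign of the mean member log2 fold change.
#'
#' @param windows tested window [GenomicRanges::GRanges].
#' @param p per-window p-values.
#' @param log2fc per-window log2 fold changes.
#' @param config a [window_config()] (supplies `merge_gap` and `fdr`).
#' @return [GenomicRanges::GRanges] of merged regions with metadata columns
#'   `n_windows`, `p_combined`, `fdr`, `log2fc` (mean), `direction`
#'   ("up"/"down") and `significant` (`fdr < config$fdr`), sorted.
#' @export
merge_and_combine <- function(windows, p, log2fc, config = window_config()) {
  stopifnot(inherits(config, "window_config"),
            length(p) == length(windows), length(log2fc) == length(windows))
  if (length(windows) == 0) {
    out <- GenomicRanges::GRanges()
    S4Vectors::mcols(out) <- S4Vectors::DataFrame(
      n_windows = integer(0), p_combined = numeric(0), fdr = numeric(0),
      log2fc = numeric(0), direction = character(0), significant = logical(0))
    return(out)
  }
  ord <- GenomicRanges::order(windows)
  windows <- windows[ord]; p <- p[ord]; log2fc <- log2fc[ord]
  # gap of g bp between [.,e] and [s,.] (1-based closed) means s - e - 1 = g;
  # merge when g < merge_gap <=> min.gapwidth = merge_gap
  red <- GenomicRanges::reduce(windows,
                               min.gapwidth = max(config$merge_gap, 1L),
                               with.revmap = TRUE)
  revmap <- S4Vectors::mcols(red)$revmap
  p_comb <- vapply(revmap, function(ii) .simes(p[ii]), numeric(1))
  lfc <- vapply(revmap, function(ii) mean(log2fc[ii]), numeric(1))
  nw <- lengths(revmap)
  fdr <- stats::p.adjust(p_comb, method = "BH")
  out <- GenomicRanges::granges(red)
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(
    n_windows = as.integer(nw), p_combined = p_comb, fdr = fdr,
    log2fc = lfc, direction = ifelse(lfc >= 0, "up", "down"),
    significant = fdr < config$fdr)
  out
}

#' AT fraction of genomic regions
#'
#' `(A + T) / (A + C + G + T)` of each region, case-insensitive; ambiguous
#' bases are excluded from numerator and denominator.
#'
#' @param regions [GenomicRanges::GRanges] within the genome.
#' @param genome a [Biostrings::DNAStringSet] (names matching contigs).
#' @return numeric vector of AT fractions (NaN for regions with no
#'   unambiguous base).
#' @export
at_fraction <- function(regions, genome) {
  if (any(GenomicRanges::width(regions) == 0)) {
    stop("empty region", call. = FALSE)
  }
  ctg <- as.character(GenomeInfoDb::seqnames(regions))
  if (!all(ctg %in% names(genome))) {
    stop("regions reference contigs absent from the genome", call. = FALSE)
  }
  ends_ok <- GenomicRanges::end(regions) <=
    Biostrings::width(genome)[match(ctg, names(genome))]
  if (!all(ends_ok)) stop("region outside genome", call. = FALSE)
  seqs <- Biostrings::DNAStringSet(lapply(seq_along(regions), function(i) {
    Biostrings::subseq(genome[[ctg[i]]],
                       start = GenomicRanges::start(regions)[i],
                       end = GenomicRanges::end(regions)[i])
  }))
  freq <- Biostrings::letterFrequency(seqs, letters = c("A", "C", "G", "T"))
  at <- freq[, "A"] + freq[, "T"]
  acgt <- rowSums(freq)
  as.numeric(at / acgt)
}

#' Compare two region sets by overlap
#'
#' Overlap is any intersection of at least one base.
#'
#' @param a,b sorted [GenomicRanges::GRanges].
#' @return list with `unique_a`, `unique_b`, `shared` (GRanges subsets of
#'   `a`/`b`) and counts `n_unique_a`, `n_unique_b`, `n_shared` (`n_shared`
#'   counts regions of `a` overlapping `b`).
#' @export
compare_region_sets <- function(a, b) {
  hit_a <- GenomicRanges::countOverlaps(a, b, minoverlap = 1L,
                                        ignore.strand = TRUE) > 0
  hit_b <- GenomicRanges::countOverlaps(b, a, minoverlap = 1L,
                                        ignore.strand = TRUE) > 0
  list(unique_a = a[!hit_a], unique_b = b[!hit_b], shared = a[hit_a],
       n_unique_a = sum(!hit_a), n_unique_b = sum(!hit_b),
       n_shared = sum(hit_a))
}

#' End-to-end sliding-window differential binding analysis
#'
#' Tiles the genome, counts fragments, applies the local background filter,
#' estimates a common dispersion on the retained windows, tests each
#' retained window with the NB GLM, merges windows into regions with
#' Simes-combined p-values and BH FDR, and (when a genome sequence is
#' supplied) annotates regions with their AT fraction.
#'
#' @param fragments named list of per-sample fragment `GRanges`.
#' @param conditions condition label per sample (two levels).
#' @param seqlengths named contig lengths (defaults to the seqlengths of the
#'   first fragment set).
#' @param config a [window_config()].
#' @param genome optional [Biostrings::DNAStringSet] for AT annotation.
#' @param test `"lrt"` or `"qlf"`, passed to [nb_test()].
#' @return list: `windows` (all), `retained` (tested windows with `log2fc`,
#'   `p`), `phi`, `regions` (all merged), `significant` (FDR < threshold),
#'   `lib_sizes`.
#' @export
chip_differential <- function(fragments, conditions, seqlengths = NULL,
                              config = window_config(), genome = NULL,
                              test = "lrt") {
  fragments <- .as_fragment_list(fragments)
  seqlengths <- seqlengths %||% GenomeInfoDb::seqlengths(fragments[[1]])
  if (any(is.na(seqlengths))) {
    stop("supply `seqlengths` (fragments carry none)", call. = FALSE)
  }
  windows <- tile_windows(seqlengths, config)
  counts <- count_fragments(windows, fragments)
  lib <- attr(counts, "totals")
  filt <- local_filter(windows, fragments, config, counts = counts)
  retained <- windows[filt$keep]
  if (length(retained) == 0) {
    regions <- merge_and_combine(retained, numeric(0), numeric(0), config)
    return(list(windows = windows, retained = retained, phi = NA_real_,
                regions = regions, significant = regions, lib_sizes = lib))
  }
  yk <- counts[filt$keep, , drop = FALSE]
  disp <- estimate_dispersion(yk, groups = conditions, lib_sizes = lib)
  tests <- nb_test(yk, conditions, disp$phi, lib_sizes = lib, test = test)
  S4Vectors::mcols(retained)$log2fc <- tests$log2fc
  S4Vectors::mcols(retained)$p <- tests$p
  regions <- merge_and_combine(retained, tests$p, tests$log2fc, config)
  if (!is.null(genome) && length(regions) > 0) {
    S4Vectors::mcols(regions)$at_frac <- at_fraction(regions, genome)
  }
  list(windows = windows, retained = retained, phi = disp$phi,
       regions = regions, significant = regions[regions$significant],
       lib_sizes = lib)
}
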