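# Growth-curve statistics: three-parameter log-logistic fits (ED50,
# relative slope, plateau), the unpaired Wilcoxon rank-sum test used for
# the between-strain comparisons, and comparative ddCt quantification.

#' Fit a three-parameter log-logistic growth curve
#'
#' Least-squares fit of `od(t) = d / (1 + exp(b * (log t - log e)))` by
#' Levenberg-Marquardt with multi-start initialisation (`d0` = max OD,
#' `e0` = time nearest half-max, `b0` in {-1, -5, -10}; the mirrored
#' positive slopes are also tried for decreasing data). The negative-`b`
#' convention means an increasing curve; `e` is the ED50, the time at which
#' the curve reaches half its plateau. Standard errors come from the
#' Jacobian (Gauss-Newton covariance). Replicate columns may be stacked by
#' the caller; points are fitted jointly.
#'
#' @param t times (h), all > 0.
#' @param od optical densities, same length as `t`.
#' @param subtract_blank subtract the minimum of the first time point
#'   (simple background-OD preprocessing) before fitting.
#' @return object of class `growth_fit`: `b`, `d`, `e`, `se` (named),
#'   `sigma` (residual SD), `fitted`, `converged`, `n`, `monotone_warning`
#'   (`TRUE` when the data trend downwards while the best fit is an
#'   increasing curve, or vice versa).
#' @export
fit_log_logistic <- function(t, od, subtract_blank = FALSE) {
  stopifnot(length(t) == length(od))
  keep <- is.finite(t) & is.finite(od)
  t <- t[keep]; od <- od[keep]
  if (any(t <= 0)) stop("`t` must be positive", call. = FALSE)
  if (length(t) < 6) stop("need at least 6 points", call. = FALSE)
  if (subtract_blank) od <- od - min(od[t == min(t)])
  d0 <- max(od)
  if (d0 <= 0) stop("OD must have positive values", call. = FALSE)
  e0 <- t[which.min(abs(od - d0 / 2))]
  dat <- data.frame(t = t, od = od)
  best <- NULL
  for (b0 in c(-1, -5, -10, 1, 5, 10)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        od ~ d / (1 + exp(b * (log(t) - log(e)))), data = dat,
        start = list(b = b0, d = d0, e = e0),
        lower = c(b = -Inf, d = 1e-9, e = 1e-9),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::residuals(fit)^2)
      if (is.null(best) || rss < best$rss - 1e-12) {
        best <- list(fit = fit, rss = rss)
      }
    }
  }
  if (is.null(best)) {
    return(structure(list(b = NA_real_, d = NA_real_, e = NA_real_,
                          se = c(b = NA_real_, d = NA_real_, e = NA_real_),
                          sigma = NA_real_, fitted = rep(NA_real_, length(t)),
                          converged = FALSE, n = length(t),
                          monotone_warning = FALSE), class = "growth_fit"))
  }
  cf <- stats::coef(best$fit)
  sm <- summary(best$fit)
  se <- sm$coefficients[, "Std. Error"]
  # growth data are expected to trend upwards; flag decreasing series and
  # fits whose direction contradicts the data trend
  trend_up <- stats::cor(t, od) > 0
  structure(list(b = cf[["b"]], d = cf[["d"]], e = cf[["e"]],
                 se = c(b = se[["b"]], d = se[["d"]], e = se[["e"]]),
                 sigma = sm$sigma, fitted = as.numeric(stats::fitted(best$fit)),
                 converged = TRUE, n = length(t),
                 monotone_warning = !trend_up || (cf[["b"]] < 0) != trend_up),
            class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  if (!x$converged) {
    cat("log-logistic fit: did not converge\n")
    return(invisible(x))
  }
  cat(sprintf(paste0("log-logistic growth fit (n = %d)\n",
                     "  relative slope b = %.3f +/- %.3f\n",
                     "  plateau        d = %.4f +/- %.4f OD\n",
                     "  ED50           e = %.3f +/- %.3f h\n"),
              x$n, x$b, x$se[["b"]], x$d, x$se[["d"]], x$e, x$se[["e"]]))
  invisible(x)
}

#' Fit a log-logistic curve to a replicate OD table
#'
#' @param od_table data.frame with `time_h` and replicate columns (as from
#'   [simulate_growth()]).
#' @param ... passed to [fit_log_logistic()].
#' @return a `growth_fit` (replicate points stacked and fitted jointly).
#' @export
fit_growth_table <- function(od_table, ...) {
  reps <- setdiff(names(od_table), "time_h")
  t <- rep(od_table$time_h, times = length(reps))
  od <- unlist(od_table[reps], use.names = FALSE)
  fit_log_logistic(t, od, ...)
}

#' Two-sample Wilcoxon rank-sum test
#'
#' Unpaired two-sided Mann-Whitney/Wilcoxon test with mid-ranks for ties:
#' the exact null distribution is used for small samples without ties, and
#' the normal approximation with continuity correction otherwise (the
#' behaviour of [stats::wilcox.test()], which this wraps).
#'
#' @param x,y numeric samples.
#' @return object of class `rank_sum_result`: `statistic` (Mann-Whitney W),
#'   `p_value`, `n1`, `n2`, `exact`.
#' @export
rank_sum_test <- function(x, y) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) == 0 || length(y) == 0) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  ties <- any(duplicated(c(x, y)))
  wt <- suppressWarnings(stats::wilcox.test(x, y, alternative = "two.sided",
                                            correct = TRUE))
  structure(list(statistic = unname(wt$statistic), p_value = wt$p.value,
                 n1 = length(x), n2 = length(y),
                 exact = !ties && length(x) < 50 && length(y) < 50),
            class = "rank_sum_result")
}

#' @export
print.rank_sum_result <- function(x, ...) {
  cat(sprintf("Wilcoxon rank-sum: W = %g, n = %d/%d, two-sided p = %.4g%s\n",
              x$statistic, x$n1, x$n2, x$p_value,
              if (x$exact) " (exact)" else ""))
  invisible(x)
}

#' Comparative ddCt quantification
#'
#' `ddCt = (Ct_target,sample - Ct_ref,sample) -
#'         (Ct_target,calibrator - Ct_ref,calibrator)`;
#' the relative expression level is `2^(-ddCt)`.
#'
#' @param ct_target_sample,ct_ref_sample Ct of target and endogenous-control
#'   gene in the sample of interest.
#' @param ct_target_cal,ct_ref_cal same in the calibrator sample.
#' @return list: `dct_sample`, `dct_calibrator`, `ddct`, `relative_level`.
#' @export
ddct <- function(ct_target_sample, ct_ref_sample, ct_target_cal, ct_ref_cal) {
  vals <- c(ct_target_sample, ct_ref_sample, ct_target_cal, ct_ref_cal)
  if (any(!is.finite(vals))) stop("Ct values must be finite", call. = FALSE)
  d_s <- ct_target_sample - ct_ref_sample
  d_c <- ct_target_cal - ct_ref_cal
  dd <- d_s - d_c
  list(dct_sample = d_s, dct_calibrator = d_c, ddct = dd,
       relative_level = 2^(-dd))
}
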