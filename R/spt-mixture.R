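# Diffusion-state mixture model. For 2D Brownian motion observed at interval
# dt with localization error sigma, the squared lag-1 displacement in state k
# is exponential with mean 4 * D_k * dt + 4 * sigma^2; a K-state population
# therefore yields a K-component exponential mixture, fitted here by EM.

.exp_mix_loglik <- function(r2, w, m) {
  dens <- vapply(seq_along(w), function(k) w[k] / m[k] * exp(-r2 / m[k]),
                 numeric(length(r2)))
  sum(log(rowSums(dens) + 1e-300))
}

.exp_mix_em <- function(r2, K, w0, m0, max_iter = 500, tol = 1e-8) {
  w <- w0; m <- m0
  ll_old <- -Inf
  n <- length(r2)
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    dens <- vapply(seq_len(K), function(k) w[k] / m[k] * exp(-r2 / m[k]),
                   numeric(n))
    tot <- rowSums(dens) + 1e-300
    resp <- dens / tot
    ll <- sum(log(tot))
    trace <- c(trace, ll)
    w <- colMeans(resp)
    m <- pmax(colSums(resp * r2) / (colSums(resp) + 1e-300), 1e-12)
    if (is.finite(ll_old) && ll - ll_old < tol * abs(ll)) {
      ll_old <- ll
      break
    }
    ll_old <- ll
  }
  list(w = w, m = m, logL = ll_old, trace = trace)
}

#' Fit a K-component diffusion mixture to track displacements
#'
#' Pools lag-1 squared displacements over all tracks (steps spanning closed
#' gaps are excluded by default, their time base differs) and fits a
#' K-component exponential mixture by EM with multiple restarts, keeping the
#' best log-likelihood. Component means `m_k` are converted to apparent
#' diffusion coefficients `D_k = (m_k - 4 * loc_sigma^2) / (4 * dt)`,
#' clipped at zero, and components are reported in ascending-`D` order.
#'
#' `method = "msd_gmm"` is an independent cross-check mode: it computes one
#' apparent D per track from its mean squared displacement and fits a
#' K-component Gaussian mixture (via \pkg{mclust}) to those per-track values.
#'
#' @param tracks track data.frame from [link_tracks()] or [truth_tracks()].
#' @param K number of diffusion components.
#' @param dt frame interval (s).
#' @param loc_sigma localization error SD (um) used for correction; 0
#'   reports uncorrected apparent coefficients.
#' @param min_steps minimum number of usable lag-1 steps.
#' @param restarts EM restarts (first from quantile-based means, the rest
#'   randomised).
#' @param include_gap_steps include steps spanning closed gaps.
#' @param method `"exponential"` (likelihood-exact, default) or `"msd_gmm"`.
#' @return object of class `diffusion_mixture_fit`: `D_app`, `weights`,
#'   `means`, `logL`, `mean_D_app` (weight-averaged), `mean_D_track`
#'   (average over per-track MSD-based coefficients), per-step `posteriors`
#'   with the matching `steps` table, `n_steps`, `dt`, `loc_sigma`.
#' @export
fit_diffusion_mixture <- function(tracks, K = 2L, dt = 0.03, loc_sigma = 0,
                                  min_steps = 50L, restarts = 10L,
                                  include_gap_steps = FALSE,
                                  method = c("exponential", "msd_gmm")) {
  method <- match.arg(method)
  if (K < 1 || K != round(K)) stop("`K` must be an integer >= 1", call. = FALSE)
  steps <- .all_steps(tracks, include_gap_steps = include_gap_steps)
  r2 <- steps$r2
  if (length(r2) < min_steps) {
    stop(sprintf("need >= %d lag-1 steps, got %d", min_steps, length(r2)),
         call. = FALSE)
  }
  if (all(r2 == 0)) stop("all displacements are zero", call. = FALSE)

  # per-track MSD-based coefficients (cross-check mode and mean_D_track)
  msd <- vapply(split(steps$r2, steps$track_id), mean, numeric(1))
  d_track <- pmax((msd - 4 * loc_sigma^2) / (4 * dt), 0)

  if (method == "msd_gmm") {
    if (!requireNamespace("mclust", quietly = TRUE)) {
      stop("method 'msd_gmm' needs the mclust package", call. = FALSE)
    }
    mclustBIC <- mclust::mclustBIC  # Mclust resolves this in the caller
    gm <- mclust::Mclust(d_track, G = K, modelNames = "V", verbose = FALSE)
    ordk <- order(gm$parameters$mean)
    D <- pmax(as.numeric(gm$parameters$mean)[ordk], 0)
    w <- gm$parameters$pro[ordk]
    fit <- list(K = K, D_app = D, weights = w,
                means = 4 * D * dt + 4 * loc_sigma^2, logL = gm$loglik,
                mean_D_app = sum(w * D), mean_D_track = mean(d_track),
                posteriors = NULL, steps = steps, n_steps = length(r2),
                dt = dt, loc_sigma = loc_sigma, method = method)
    class(fit) <- "diffusion_mixture_fit"
    return(fit)
  }

  qs <- stats::quantile(r2[r2 > 0], probs = (seq_len(K)) / (K + 1))
  best <- NULL
  for (rs in seq_len(restarts)) {
    m0 <- if (rs == 1) as.numeric(qs) else {
      sort(stats::runif(K, min(qs) * 0.2, max(qs) * 3))
    }
    m0 <- pmax(m0, 1e-9)
    res <- .exp_mix_em(r2, K, rep(1 / K, K), m0)
    if (is.null(best) || res$logL > best$logL) best <- res
  }
  ordk <- order(best$m)
  w <- best$w[ordk]; m <- best$m[ordk]
  D <- pmax((m - 4 * loc_sigma^2) / (4 * dt), 0)
  dens <- vapply(seq_len(K), function(k) w[k] / m[k] * exp(-r2 / m[k]),
                 numeric(length(r2)))
  post <- dens / (rowSums(dens) + 1e-300)
  fit <- list(K = K, D_app = D, weights = w, means = m, logL = best$logL,
              mean_D_app = sum(w * D), mean_D_track = mean(d_track),
              posteriors = post, steps = steps, n_steps = length(r2),
              dt = dt, loc_sigma = loc_sigma, method = method)
  class(fit) <- "diffusion_mixture_fit"
  fit
}

#' @export
print.diffusion_mixture_fit <- function(x, ...) {
  cat(sprintf("%d-component diffusion mixture (%s), %d steps\n", x$K,
              x$method, x$n_steps))
  for (k in seq_len(x$K)) {
    cat(sprintf("  D_%d = %.4g um^2/s  (weight %.3f)\n", k, x$D_app[k],
                x$weights[k]))
  }
  cat(sprintf("  mean apparent D (weight-averaged) = %.4g um^2/s\n",
              x$mean_D_app))
  invisible(x)
}

#' Mobility-classification configuration
#'
#' @param window_steps number of consecutive steps a state must persist for
#'   (3 steps of 30 ms = the 90 ms confinement window).
#' @return object of class `mobility_config`.
#' @export
mobility_config <- function(window_steps = 3L) {
  stop_if_not_count(window_steps, "window_steps")
  structure(list(window_steps = as.integer(window_steps)),
            class = "mobility_config")
}

#' Classify tracks as confined, free or mixed
#'
#' Each lag-1 step is labelled by its maximum-posterior mixture state. A
#' track with at least `window_steps` steps is `confined` when every sliding
#' `window_steps`-step window is entirely slow-state, `free` when entirely
#' fast-state, and `mixed` otherwise. Shorter tracks are not classifiable.
#'
#' @param tracks track data.frame.
#' @param fit a two-component [fit_diffusion_mixture()] result (exponential
#'   method, slow state first).
#' @param config a [mobility_config()].
#' @return list with `classes` (data.frame `track_id`, `n_steps`, `class`)
#'   and `fractions` (named vector over confined/free/mixed, summing to 1
#'   over classifiable tracks).
#' @export
classify_mobility <- function(tracks, fit, config = mobility_config()) {
  stopifnot(inherits(fit, "diffusion_mixture_fit"),
            inherits(config, "mobility_config"))
  if (fit$K != 2L) stop("mobility classification requires a K = 2 fit",
                        call. = FALSE)
  if (is.null(fit$posteriors)) {
    stop("fit has no per-step posteriors (use method = 'exponential')",
         call. = FALSE)
  }
  steps <- fit$steps
  slow <- fit$posteriors[, 1] >= fit$posteriors[, 2]
  per_track <- split(slow, steps$track_id)
  n_steps <- lengths(per_track)
  keep <- n_steps >= config$window_steps
  cls <- vapply(per_track[keep], function(s) {
    if (all(s)) "confined" else if (!any(s)) "free" else "mixed"
  }, character(1))
  classes <- data.frame(track_id = names(per_track)[keep],
                        n_steps = as.integer(n_steps[keep]), class = cls,
                        row.names = NULL)
  fr <- c(confined = mean(cls == "confined"), free = mean(cls == "free"),
          mixed = mean(cls == "mixed"))
  list(classes = classes, fractions = fr)
}
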