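#' Log-logistic mean function
#'
#' `d / (1 + exp(b * (log t - log e)))`: with negative `b` the curve rises
#' from 0 to the plateau `d`, passing `d / 2` exactly at `t = e` (ED50).
#'
#' @param t time (h), must be > 0.
#' @param b relative slope; @param d plateau; @param e ED50 (h).
#' @return expected OD at `t`.
#' @export
log_logistic <- function(t, b, d, e) {
  stopifnot(all(t > 0))
  d / (1 + exp(b * (log(t) - log(e))))
}

#' Simulate replicated growth curves
#'
#' @param config a [growth_sim_config()].
#' @return data.frame with `time_h` and one `repN` column per replicate
#'   (OD units); the noise-free mean is available as attribute `"mu"`.
#' @export
simulate_growth <- function(config) {
  stopifnot(inherits(config, "growth_sim_config"))
  with_seed(config$seed, {
    mu <- log_logistic(config$t_grid, config$b_true, config$d_true,
                       config$e_true)
    out <- data.frame(time_h = config$t_grid)
    for (r in seq_len(config$n_replicates)) {
      out[[paste0("rep", r)]] <- mu +
        stats::rnorm(length(mu), 0, config$noise_sigma)
    }
    attr(out, "mu") <- mu
    out
  })
}
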