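# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards so simulations are reproducible
#' without clobbering the session stream. A `NULL` seed leaves the current
#' stream untouched.
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

stop_if_not_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0 || x > 1) {
    stop(sprintf("`%s` must be a single probability in [0, 1]", name), call. = FALSE)
  }
  invisible(x)
}

stop_if_not_pos <- function(x, name, strict = TRUE) {
  ok <- is.numeric(x) && all(is.finite(x)) && if (strict) all(x > 0) else all(x >= 0)
  if (!ok) {
    stop(sprintf("`%s` must be %s", name,
                 if (strict) "finite and > 0" else "finite and >= 0"), call. = FALSE)
  }
  invisible(x)
}

stop_if_not_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min ||
      x != round(x)) {
    stop(sprintf("`%s` must be an integer >= %d", name, min), call. = FALSE)
  }
  invisible(as.integer(x))
}

# Reflect coordinates into [0, w] (billiard reflection, handles any excursion).
reflect_into <- function(x, w) {
  y <- x %% (2 * w)
  ifelse(y > w, 2 * w - y, y)
}
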