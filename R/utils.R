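# Internal helpers: argument checking and scoped random-number state.

#' @keywords internal
stop_config <- function(...) {
  stop(structure(
    class = c("pauseflow_config_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

#' @keywords internal
stop_validation <- function(...) {
  stop(structure(
    class = c("pauseflow_validation_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

#' @keywords internal
assert_scalar_num <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop_validation("`", name, "` must be a single non-missing number")
  if (x < lower || x > upper)
    stop_validation("`", name, "` must be in [", lower, ", ", upper, "], got ", x)
  invisible(x)
}

# Evaluate `code` with the global RNG seeded to `seed`, restoring any
# pre-existing RNG state afterwards so callers see no global side effects.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
      stop_validation("`seed` must be a single integer")
    had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had_seed) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed), kind = "Mersenne-Twister", normal.kind = "Inversion")
  }
  force(code)
}

# lognormal jitter with mean `mean` and coefficient of variation `cv`
#' @keywords internal
rlnorm_mean_cv <- function(n, mean, cv) {
  if (mean <= 0 || cv <= 0) return(rep(mean, n))
  sdlog <- sqrt(log(1 + cv^2))
  meanlog <- log(mean) - sdlog^2 / 2
  stats::rlnorm(n, meanlog, sdlog)
}
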