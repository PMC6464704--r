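#' Run code with a temporary RNG state
#'
#' All generators route their randomness through this helper so that a call
#' with a given seed is bit-reproducible and never disturbs the caller's RNG
#' stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Trapezoidal integral over an arbitrary axis
#' @param x positions (strictly increasing).
#' @param y values at `x`.
#' @return scalar integral.
#' @keywords internal
trapz <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 2L) return(0)
  sum(diff(x) * (head(y, -1L) + tail(y, -1L)) / 2)
}

# Parameter check that names the offending field, per the generators' error
# contract.
check_that <- function(ok, field, msg) {
  if (!isTRUE(ok)) {
    stop(sprintf("invalid parameter `%s`: %s", field, msg), call. = FALSE)
  }
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
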