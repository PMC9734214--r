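# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG state
#'
#' Saves the caller's `.Random.seed`, seeds the RNG with `seed`, evaluates
#' `code`, and restores the previous state on exit. All stochastic operations
#' in the package route their seeding through this helper so that generators
#' are reproducible without clobbering the user's RNG stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single non-missing number")
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Derive a child seed from a master seed and a counter, kept inside the
# 32-bit signed integer range.
derive_seed <- function(seed, counter) {
  as.integer((as.double(seed) * 7919 + as.double(counter) * 104729) %% 2147483647)
}

stopifnot_scalar <- function(x, name, lower = -Inf, upper = Inf,
                             strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("`%s` must be a single non-missing number", name))
  }
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok) {
    stop(sprintf(
      "`%s` = %s out of range %s%s, %s%s", name, format(x),
      if (strict_lower) "(" else "[", format(lower),
      format(upper), if (strict_upper) ")" else "]"
    ))
  }
  invisible(x)
}

# Euclidean projection of each row of Q onto the probability simplex.
project_rows_simplex <- function(Q) {
  k <- ncol(Q)
  if (k == 1L) return(matrix(1, nrow(Q), 1L))
  t(apply(Q, 1L, function(v) {
    u <- sort(v, decreasing = TRUE)
    css <- cumsum(u)
    rho <- max(which(u + (1 - css) / seq_len(k) > 0))
    theta <- (1 - css[rho]) / rho
    pmax(v + theta, 0)
  }))
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)
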