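# Internal helpers shared across modules.

#' Derive a reproducible sub-seed from a master seed
#'
#' Streams of randomness for subjects, acquisitions and channels are derived
#' deterministically from one master seed so that whole-cohort simulations are
#' reproducible while individual records remain independently regenerable.
#' The result always lies in [1, 2^31 - 2].
#'
#' @param seed master seed (single integer-like number).
#' @param ... integer identifiers (e.g. subject index, acquisition index).
#' @return a single integer usable with [set.seed()].
#' @export
derive_seed <- function(seed, ...) {
  ids <- c(...)
  m <- 2147483647 # 2^31 - 1, prime
  h <- as.numeric(seed) %% m
  mults <- c(48271, 16807, 69621, 40692, 10007)
  for (i in seq_along(ids)) {
    mult <- mults[((i - 1L) %% length(mults)) + 1L]
    h <- (h * mult + as.numeric(ids[i]) + 1) %% m
  }
  as.integer(h %% (m - 2)) + 1L
}

# Run code with a locally seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_zero = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stopf("`%s` must be a single finite number", name)
  }
  if (x < lower || x > upper || (!allow_zero && x == 0)) {
    stopf("`%s` = %g is outside the allowed range [%g, %g]",
          name, x, lower, upper)
  }
  invisible(x)
}

check_positive <- function(x, name) {
  check_number(x, name)
  if (x <= 0) stopf("`%s` must be > 0 (got %g)", name, x)
  invisible(x)
}
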