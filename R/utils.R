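# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG seed
#'
#' Sets the RNG seed for the duration of `code` and restores the caller's
#' RNG state afterwards, so seeded generators are pure functions of their
#' arguments and never perturb the session's random stream.
#'
#' @param seed Integer seed, or `NULL` to leave the RNG untouched.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv(), inherits = FALSE)
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

# Deterministic 32-bit seed derivation: mixes integer offsets into a parent
# seed with a Lehmer-style step (all intermediates stay below 2^53, so the
# arithmetic is exact in doubles).
derive_seed <- function(seed, ...) {
  s <- as.double(seed) %% 2147483647
  for (o in c(...)) {
    s <- (s * 69069 + as.double(o) + 1) %% 2147483647
  }
  as.integer(s)
}

cf_stop <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
cf_warn <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 1 && x == round(x)
}

# Population-style standardization: mean 0, mean-square 1 (divide-by-n SD).
# With this convention the mean of an edge timeseries equals the Pearson
# correlation of the two columns exactly.
standardize_cols <- function(x) {
  mu <- colMeans(x)
  xc <- sweep(x, 2L, mu, `-`)
  sd_pop <- sqrt(colMeans(xc^2))
  list(values = sweep(xc, 2L, sd_pop, `/`), sd = sd_pop)
}
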