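#' @keywords internal
"_PACKAGE"

#' Evaluate an expression under a local, reproducible RNG state
#'
#' Saves and restores `.Random.seed` so that seeded internals never disturb
#' the caller's random number stream. All stochastic operations in the
#' package route through this helper, which is what makes the full pipeline
#' byte-reproducible for a fixed seed.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_local_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("seed must be a single finite number", call. = FALSE)
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Derive a sub-seed from (seed, tag) so independent pipeline stages use
# independent but reproducible streams. Kept below 2^31 - 1.
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(as.character(tag)) * seq_along(utf8ToInt(as.character(tag))))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483629 + 1)
}

stop_f <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_that <- function(ok, fmt, ...) {
  if (!isTRUE(ok)) stop_f(fmt, ...)
  invisible(TRUE)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
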