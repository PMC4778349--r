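`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Wraps [withr::with_seed()] but treats `seed = NULL` as "use the session
#' RNG stream as-is". All stochastic operations in the package funnel their
#' `seed` argument through here, so a `NULL` seed never clobbers the caller's
#' RNG state and an integer seed gives byte-identical results.
#'
#' @param seed Integer seed or `NULL`.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(as.integer(seed), code)
}

#' Derive a deterministic sub-seed for a named pipeline stage
#'
#' Multi-stage operations (e.g. the full pipeline, or read emission which
#' first draws counts and then corrupts reads) need independent but
#' reproducible RNG streams per stage. The derived seed stays below 2^31.
#'
#' @param seed Integer master seed or `NULL` (returns `NULL`).
#' @param tag Character stage label.
#' @return Integer seed, or `NULL`.
#' @keywords internal
derive_seed <- function(seed, tag) {
  if (is.null(seed)) return(NULL)
  v <- utf8ToInt(tag)
  h <- sum(v * seq_along(v))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

# stop() with a prefix naming the failing check; keeps call noise down
abort <- function(...) stop(..., call. = FALSE)

assert_that <- function(ok, ...) if (!isTRUE(ok)) abort(...)
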