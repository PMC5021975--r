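# Internal helpers shared across the package.

MONTHS <- 1:12

`%||%` <- function(x, y) if (is.null(x)) y else x

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 0 && x == trunc(x)
}

is_prob <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 0 && x <= 1
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the seed, runs the code, and restores the caller's random-number
#' state afterwards, so library functions never disturb user-level
#' reproducibility.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Derive a deterministic sub-seed from a master seed and a string key
#'
#' Polynomial rolling hash modulo 2^31 - 1. Intermediate products stay below
#' 2^53, so the arithmetic is exact in doubles. Used to give every condition
#' (or institution) its own reproducible random stream independent of
#' iteration order.
#'
#' @param master Integer master seed.
#' @param key Character scalar.
#' @return A positive integer seed below 2^31.
#' @export
derive_seed <- function(master, key) {
  stopifnot(length(master) == 1L, is.numeric(master), length(key) == 1L,
            is.character(key))
  h <- abs(as.double(master)) %% 2147483647
  for (b in utf8ToInt(paste0("|", key))) {
    h <- (h * 31 + b) %% 2147483647
  }
  as.integer(h) + 1L
}
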