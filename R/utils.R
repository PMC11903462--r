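#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded helpers never perturb the
#' caller's RNG stream. All randomness in the package flows through this.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a per-cell seed from a master seed and grid coordinates
#'
#' Deterministic integer mixing so every sweep cell gets an independent,
#' individually reproducible seed. Result is always in [1, 2^31 - 2].
#'
#' @param master_seed Integer master seed.
#' @param ... Integer coordinates (e.g. N index, offset index, sigma index).
#' @return A single integer seed.
#' @export
derive_seed <- function(master_seed, ...) {
  parts <- c(as.numeric(master_seed), as.numeric(unlist(list(...))))
  s <- 104729
  for (p in parts) {
    # stays below 2^53 so double arithmetic is exact
    s <- ((s %% 2147483647) * 48271 + (p %% 2147483647) * 16807 + 12345) %% 2147483647
  }
  as.integer(s %% 2147483646 + 1)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
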