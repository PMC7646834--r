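# Internal helpers shared across modules.

#' Derive a reproducible child seed from a master seed
#'
#' Stages and per-unit random streams (pixels, proteins, folds) draw their
#' own seeds from a master seed so that subsetting one stream does not
#' perturb another. The derivation is a fixed integer hash kept below 2^31.
#'
#' @param seed master seed (single integer).
#' @param ... one or more integers or strings identifying the consumer.
#' @return a single integer seed in [0, 2^31).
#' @export
derive_seed <- function(seed, ...) {
  parts <- list(...)
  h <- as.double(seed) %% 2147483647
  for (p in parts) {
    if (is.character(p)) p <- sum(utf8ToInt(p))
    for (v in as.double(p)) {
      h <- (h * 48271 + v + 1) %% 2147483647
    }
  }
  as.integer(h)
}

#' Evaluate an expression under a local RNG state
#'
#' Runs `expr` with the RNG seeded to `seed`; the caller's RNG state is
#' saved and restored, so seeded stages never perturb one another.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
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
  set.seed(seed)
  expr
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x, min = 0) {
  length(x) == 1 && is.numeric(x) && !is.na(x) && x >= min && x == floor(x)
}

is_number <- function(x) length(x) == 1 && is.numeric(x) && is.finite(x)

#' The three renal tumor classes used throughout the workflow
#'
#' Fixed class order: clear cell renal cell carcinoma, renal oncocytoma,
#' chromophobe renal cell carcinoma. All score matrices and calls use this
#' order for columns and tie-breaking.
#'
#' @return character vector `c("ccRCC", "RO", "ChRCC")`.
#' @export
tumor_classes <- function() c("ccRCC", "RO", "ChRCC")
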