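#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Fixed-digit rounding with ties going up (half-up), matching how
#' percentages are conventionally reported in habitat-area tables, rather
#' than base R's round-half-to-even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded to `digits` decimal places, ties away from zero.
#' @export
#' @examples
#' round_half_up(12.625, 2) # 12.63
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

## run expr under a local RNG state seeded with `seed` (master state untouched)
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

#' Derive a stage seed from a master seed
#'
#' Deterministically combines a master seed with a stage label so that every
#' randomized pipeline stage gets its own reproducible stream. The derivation
#' is a pure function of the two arguments and always stays below 2^31.
#'
#' @param master integer master seed.
#' @param stage character stage label, e.g. `"background"`.
#' @return an integer seed.
#' @export
stage_seed <- function(master, stage) {
  stopifnot(length(stage) == 1L, is.character(stage))
  h <- 0
  for (cc in utf8ToInt(stage)) h <- (h * 131 + cc) %% 1000003
  as.integer((as.numeric(master) %% 1000003 + h * 7919) %% 2147483629 + 1)
}
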