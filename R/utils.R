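#' Round half away from zero
#'
#' Decimal rounding with ties going away from zero (so 0.25 -> 0.3 and
#' -0.25 -> -0.3 at one decimal), the convention used when reporting risk
#' differences in percentage points. Base `round()` rounds half to even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded to `digits` decimals.
#' @export
#' @examples
#' round_half_away(c(0.25, -0.25, 1.571), 1)
round_half_away <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## condition helpers: errors carry a class so callers/tests can distinguish
## schema problems from integrity problems from plain bad arguments
vs_stop <- function(class, fmt, ...) {
  msg <- sprintf(fmt, ...)
  stop(structure(
    class = c(class, "virosnap_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

week_to_day <- function(week) as.integer(7L * week)

## run `expr` with a local RNG state seeded by `seed`, restoring the caller's
## state afterwards
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x >= 0 && x == floor(x)
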