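# Internal helpers shared across modules.

# Nucleotide channel order used throughout: the order in which the one-hot
# channels and label codes are assigned. Deliberately (A, T, G, C), not
# alphabetical: label codes are A=0, T=1, G=2, C=3.
NUC_ORDER <- c("A", "T", "G", "C")

# Missing-call sentinel used internally and in matrix-format files.
MISSING_CALL <- "N"

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves the caller's RNG state, seeds the generator, evaluates `expr`, and
#' restores the previous state, so library functions never perturb a user's
#' random stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  expr
}

# Stage-aware condition helpers: every user-facing error carries the name of
# the operation that raised it so pipeline failures are attributable.
stop2 <- function(..., call. = FALSE) stop(..., call. = call.)

`%||%` <- function(a, b) if (is.null(a)) b else a

# round-half-up to `digits` decimal places (R's round() is banker's rounding)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

is_count <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x) &&
  x == as.integer(x) && x > 0
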