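`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a local RNG seed
#'
#' Sets the RNG seed, evaluates `expr`, and restores the previous RNG state so
#' that seeded package internals never disturb the caller's random stream.
#'
#' @param seed integer seed, or NULL to leave the stream untouched.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic child seeds (kept < 2^31) for independent stage streams.
split_seed <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# sample() that never falls into the 1:n expansion trap for length-1 input
resample <- function(x, size = length(x)) x[sample.int(length(x), size)]

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == round(x)

# IUPAC codes accepted on input; everything outside A/C/G/T is treated as
# missing by the callers.
IUPAC_CHARS <- c("A", "C", "G", "T", "N", "-", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V")

PURINES <- c("A", "G")
PYRIMIDINES <- c("C", "T")

is_transition <- function(a, b) {
  (a %in% PURINES & b %in% PURINES) | (a %in% PYRIMIDINES & b %in% PYRIMIDINES)
}
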