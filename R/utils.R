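# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
# The caller's .Random.seed is restored afterwards, so seeded generator
# calls never perturb an ongoing simulation stream (one stream per call).
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

#' Round a probability to its printed precision
#'
#' Rounds the way tail probabilities are conventionally printed in
#' sister-clade diversification tables: two significant figures below 0.1,
#' two decimal places otherwise. Rounding is IEEE round-half-even, matching
#' the behaviour of \code{signif()} and \code{round()}.
#'
#' @param p numeric vector of probabilities in \code{[0, 1]}.
#' @return numeric vector rounded to printed precision.
#' @examples
#' printedRound(c(3 / 152, 25 / 424, 874 / 875))
#' @export
printedRound <- function(p) {
  stopifnot(is.numeric(p), all(is.finite(p)), all(p >= 0), all(p <= 1))
  ifelse(p < 0.0995, signif(p, 2), round(p, 2))
}

# Is x integer-valued (within floating tolerance)?
.isCount <- function(x, min = 1) {
  is.numeric(x) & is.finite(x) & abs(x - round(x)) < 1e-8 & x >= min
}

# Consistent "row i, field f" validation error.
.fieldError <- function(row, field, what) {
  stop(sprintf("sister-pair table validation: row %d, field '%s': %s",
               row, field, what), call. = FALSE)
}
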