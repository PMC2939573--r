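#' @include core_io.R
NULL

#' Equal Rates Markov tail probability of a diversity bipartition
#'
#' Under the Equal Rates Markov null, every split of \eqn{n} extant species
#' into two non-empty sister clades \eqn{(j, n-j)}, \eqn{j = 1, \dots, n-1},
#' is equiprobable. The probability that a focal clade holds at least its
#' observed \eqn{k} species is therefore
#' \deqn{P(K \ge k) = (n - k) / (n - 1).}
#' The value is exact: a single division of two integers. It is strictly
#' decreasing in \eqn{k} for fixed \eqn{n} and equals 1 iff \eqn{k = 1}.
#'
#' @param k focal-clade richness, \eqn{1 \le k \le n - 1} (the sister must
#'   be non-empty).
#' @param n combined richness of the two sisters, \eqn{n \ge 2}.
#' @return the tail probability; vectorized over \code{k} and \code{n}.
#' @examples
#' ermProbability(150, 153)   # 3/152
#' ermProbability(400, 425)   # 25/424
#' @export
ermProbability <- function(k, n) {
  if (!all(.isCount(k, min = 0)) || !all(.isCount(n, min = 0))) {
    stop("k and n must be integers", call. = FALSE)
  }
  if (any(n < 2)) stop("n must be at least 2", call. = FALSE)
  if (any(k < 1 | k > n - 1)) {
    stop("k must satisfy 1 <= k <= n - 1 (both sister clades are non-empty)",
         call. = FALSE)
  }
  (n - k) / (n - 1)
}

#' ERM bipartition test for one sister pair
#'
#' Computes both tail probabilities of a pair's diversity bipartition -- the
#' galler at least as diverse as observed, and the non-galler at least as
#' diverse as observed -- and flags each against the Bonferroni-corrected
#' threshold \code{alpha / nHypotheses} (two alternative hypotheses by
#' default, i.e. \eqn{\alpha/2 = 0.025} at \code{alpha = 0.05}).
#'
#' @param pair a single sister pair: a named list or one-row data.frame with
#'   at least \code{n_galler} and \code{n_nongaller} (and optionally
#'   \code{pair_id}), e.g. from [getPair()].
#' @param alpha nominal significance level before correction.
#' @param nHypotheses number of alternative hypotheses corrected for.
#' @return a [BipartitionResult-class].
#' @examples
#' res <- ermBipartitionTest(getPair(readSisterTable(table1Path()), "Apiomorpha"))
#' pValue(res)
#' @export
ermBipartitionTest <- function(pair, alpha = 0.05, nHypotheses = 2L) {
  pair <- as.list(pair)
  stopifnot(alpha > 0, alpha < 1, nHypotheses >= 1)
  kG <- as.numeric(pair$n_galler)
  kN <- as.numeric(pair$n_nongaller)
  n <- kG + kN
  pG <- ermProbability(kG, n)
  pN <- ermProbability(kN, n)
  aEff <- alpha / nHypotheses
  new("BipartitionResult",
      pairId = if (!is.null(pair$pair_id)) as.character(pair$pair_id) else NA_character_,
      nTotal = n, pGaller = pG, pNongaller = pN, alphaEffective = aEff,
      sigGaller = pG < aEff, sigNongaller = pN < aEff)
}

#' ERM bipartition report over a whole sister-pair table
#'
#' Runs [ermBipartitionTest()] on every pair, preserving input order, and
#' counts how many pairs have the galling sister more diverse.
#'
#' @param table a [SisterPairTable-class].
#' @inheritParams ermBipartitionTest
#' @return an [ErmReport-class].
#' @examples
#' rep <- ermTableReport(readSisterTable(table1Path()))
#' rep@nGallerMoreDiverse
#' @export
ermTableReport <- function(table, alpha = 0.05, nHypotheses = 2L) {
  stopifnot(is(table, "SisterPairTable"))
  df <- table@pairs
  res <- lapply(seq_len(nrow(df)), function(i) {
    ermBipartitionTest(df[i, , drop = FALSE], alpha = alpha,
                       nHypotheses = nHypotheses)
  })
  out <- data.frame(
    pair_id = vapply(res, function(r) r@pairId, ""),
    n = vapply(res, function(r) r@nTotal, 0),
    p_galler = vapply(res, function(r) r@pGaller, 0),
    p_nongaller = vapply(res, function(r) r@pNongaller, 0),
    sig_galler = vapply(res, function(r) r@sigGaller, NA),
    sig_nongaller = vapply(res, function(r) r@sigNongaller, NA),
    stringsAsFactors = FALSE)
  new("ErmReport", results = out, alphaEffective = alpha / nHypotheses,
      nGallerMoreDiverse = sum(df$n_galler > df$n_nongaller))
}

#' @describeIn pValue the two tail probabilities, named \code{galler} and
#'   \code{nongaller}.
#' @export
setMethod("pValue", "BipartitionResult", function(x) {
  c(galler = x@pGaller, nongaller = x@pNongaller)
})

setMethod("show", "BipartitionResult", function(object) {
  cat(sprintf("ERM bipartition test%s (n = %d)\n",
              if (is.na(object@pairId)) "" else paste0(": ", object@pairId),
              as.integer(object@nTotal)))
  cat(sprintf("  P(galler >= observed)    = %.4g%s\n", object@pGaller,
              if (object@sigGaller) "  *" else ""))
  cat(sprintf("  P(nongaller >= observed) = %.4g%s\n", object@pNongaller,
              if (object@sigNongaller) "  *" else ""))
  cat(sprintf("  threshold after correction: %.4g\n", object@alphaEffective))
})

setMethod("show", "ErmReport", function(object) {
  cat(sprintf("ERM bipartition report: %d pair(s), threshold %.4g\n",
              nrow(object@results), object@alphaEffective))
  cat(sprintf("  galler more diverse in %d of %d comparison(s)\n",
              object@nGallerMoreDiverse, nrow(object@results)))
  print(object@results, digits = 3)
})
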