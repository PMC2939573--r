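#' @include AllClasses.R
NULL

#' Number of sister pairs in a table
#' @param x a [SisterPairTable-class].
#' @return integer count of pairs.
#' @export
setGeneric("nPairs", function(x) standardGeneric("nPairs"))

#' Pair identifiers
#' @param x a [SisterPairTable-class].
#' @return character vector of pair ids, in table order.
#' @export
setGeneric("pairIds", function(x) standardGeneric("pairIds"))

#' Per-tip extant richness
#' @param x a [RichnessTree-class].
#' @return named numeric vector of richness counts, one per tip.
#' @export
setGeneric("tipRichness", function(x) standardGeneric("tipRichness"))

#' Root age of an ultrametric tree
#' @param x a [RichnessTree-class].
#' @return the root age in the tree's time units.
#' @export
setGeneric("rootAge", function(x) standardGeneric("rootAge"))

#' Stem ages of the terminal clades
#'
#' The stem age of a tip is the age of its parent node: the time since the
#' tip's clade split from its sister.
#'
#' @param x a [RichnessTree-class].
#' @return named numeric vector of stem ages, one per tip.
#' @export
setGeneric("stemAges", function(x) standardGeneric("stemAges"))

#' Internal node ages, sorted descending
#' @param x a [RichnessTree-class].
#' @return numeric vector of internal-node ages sorted from the root down;
#'   length equals the number of internal nodes.
#' @export
setGeneric("branchingTimes", function(x) standardGeneric("branchingTimes"))

#' Rescale a tree to a fixed root height
#'
#' Multiplies every branch length by \code{target / rootAge(x)}, so that the
#' root age equals \code{target}. Topology and richness are unchanged. Used
#' to place trees on the conventional arbitrary root height of 100 before
#' rate fitting (only relative node heights matter to the likelihood, which
#' is invariant under the joint rescaling \eqn{t \to ct, r \to r/c}).
#'
#' @param x a [RichnessTree-class].
#' @param target new root age (> 0).
#' @return a [RichnessTree-class] with \code{rootAge(x) == target}.
#' @examples
#' tr <- readRichnessTree("((A:1,B:1):1,C:2);",
#'                        c(A = 1, B = 1, C = 1))
#' rootAge(scaleRootHeight(tr, 100))
#' @export
setGeneric("scaleRootHeight", function(x, target) standardGeneric("scaleRootHeight"))

#' P-value of a test result
#' @param x a [ContrastResult-class] or [BipartitionResult-class].
#' @return the p-value(s) carried by the result object.
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))

#' Which significance test was dispatched
#' @param x a [ContrastResult-class].
#' @return character name of the dispatched test.
#' @export
setGeneric("testUsed", function(x) standardGeneric("testUsed"))

#' Net diversification rate of a rate class
#' @param x a [BDParams-class].
#' @return the net rate \eqn{r}.
#' @export
setGeneric("netRate", function(x) standardGeneric("netRate"))

#' Relative extinction of a rate class
#' @param x a [BDParams-class].
#' @return \eqn{\epsilon = \mu/\lambda}.
#' @export
setGeneric("relExtinction", function(x) standardGeneric("relExtinction"))

#' Rate classes of a fitted model
#' @param x a [RateShiftFit-class].
#' @return list of [BDParams-class], background class first.
#' @export
setGeneric("rateClasses", function(x) standardGeneric("rateClasses"))

#' Shift branches of a fitted model
#' @param x a [RateShiftFit-class].
#' @return integer edge indices (rows of \code{phy$edge}) of the accepted
#'   shift stem branches; empty for the fixed model.
#' @export
setGeneric("shiftEdges", function(x) standardGeneric("shiftEdges"))

#' Log-likelihood of a fitted model
#' @param x a [RateShiftFit-class].
#' @return the maximized log-likelihood.
#' @export
setGeneric("fitLogL", function(x) standardGeneric("fitLogL"))

#' AIC of a fitted model
#' @param x a [RateShiftFit-class].
#' @return \code{2 * nParams - 2 * logL}.
#' @export
setGeneric("fitAIC", function(x) standardGeneric("fitAIC"))

#' Likelihood-ratio-test p-value of a flexible fit
#' @param x a [RateShiftFit-class].
#' @return the LRT p-value against the nested fixed model (\code{NA} when
#'   not applicable).
#' @export
setGeneric("lrtPvalue", function(x) standardGeneric("lrtPvalue"))
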