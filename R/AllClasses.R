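#' @include utils.R
NULL

setOldClass("phylo")

# ---------------------------------------------------------------------------
# Sister-pair table
# ---------------------------------------------------------------------------

#' SisterPairTable: galler / non-galler sister-clade comparisons
#'
#' One row per sister-pair comparison between a gall-inducing clade and its
#' non-galling sister: clade names, extant described species richness, and
#' host breadth quantified as the age (Ma) of the most recent common ancestor
#' of the host plants. An age of 0 encodes hosts confined to a single
#' terminal host lineage (no resolvable MRCA depth).
#'
#' @slot pairs data.frame with columns \code{pair_id}, \code{galler_name},
#'   \code{n_galler}, \code{host_age_galler}, \code{nongaller_name},
#'   \code{n_nongaller}, \code{host_age_nongaller} and optionally
#'   \code{age_note} (footnote flags carried through from the source table).
#' @seealso [readSisterTable()], [ermTableReport()],
#'   [diversityContrastAnalysis()], [hostSpecificityTest()]
#' @export
setClass("SisterPairTable", representation(pairs = "data.frame"))

.requiredPairCols <- c("pair_id", "galler_name", "n_galler", "host_age_galler",
                       "nongaller_name", "n_nongaller", "host_age_nongaller")

.checkPairFrame <- function(df) {
  missing <- setdiff(.requiredPairCols, names(df))
  if (length(missing)) {
    stop("sister-pair table validation: missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(df) < 1L) {
    stop("sister-pair table validation: table must contain at least one pair",
         call. = FALSE)
  }
  for (f in c("n_galler", "n_nongaller")) {
    v <- df[[f]]
    bad <- which(!.isCount(suppressWarnings(as.numeric(v)), min = 1))
    if (length(bad)) {
      .fieldError(bad[1L], f,
                  "species count must be an integer >= 1 (every clade has at least one described species)")
    }
  }
  for (f in c("host_age_galler", "host_age_nongaller")) {
    v <- suppressWarnings(as.numeric(df[[f]]))
    bad <- which(!is.finite(v) | v < 0)
    if (length(bad)) {
      .fieldError(bad[1L], f, "host MRCA age must be a non-negative number (Ma)")
    }
  }
  ids <- as.character(df$pair_id)
  if (anyDuplicated(ids)) {
    stop("sister-pair table validation: duplicated pair_id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  if (any(!nzchar(ids))) {
    .fieldError(which(!nzchar(ids))[1L], "pair_id", "pair_id must be non-empty")
  }
  invisible(TRUE)
}

setValidity("SisterPairTable", function(object) {
  out <- tryCatch({ .checkPairFrame(object@pairs); TRUE },
                  error = function(e) conditionMessage(e))
  out
})

# ---------------------------------------------------------------------------
# Richness tree
# ---------------------------------------------------------------------------

#' RichnessTree: ultrametric tree with per-tip extant richness
#'
#' A rooted ultrametric tree whose terminal nodes stand for whole clades and
#' carry their extant species richness. This is the structure consumed by the
#' stem-age taxonomic birth-death likelihood: each tip contributes its
#' richness \eqn{n_i} observed at stem age \eqn{t_i} (the age of its parent
#' node). All ages are measured backward from the present; tips sit at age 0.
#'
#' @slot phy an ape \code{phylo} object with non-negative branch lengths.
#' @slot richness named numeric vector of integer richness (>= 1), one per
#'   tip, in \code{phy$tip.label} order.
#' @slot rootAge age of the root (maximum root-to-tip path length).
#' @seealso [readRichnessTree()], [scaleRootHeight()], [branchingTimes()],
#'   [stemAges()], [fitFixedRate()]
#' @export
setClass("RichnessTree",
         representation(phy = "phylo", richness = "numeric",
                        rootAge = "numeric"))

setValidity("RichnessTree", function(object) {
  phy <- object@phy
  msg <- character()
  if (is.null(phy$edge.length)) msg <- c(msg, "tree has no branch lengths")
  else if (any(phy$edge.length < 0)) msg <- c(msg, "negative branch lengths")
  if (length(object@richness) != length(phy$tip.label)) {
    msg <- c(msg, "one richness value per tip required")
  } else if (!identical(names(object@richness), phy$tip.label)) {
    msg <- c(msg, "richness names must match tip labels (in order)")
  }
  if (!all(.isCount(object@richness, min = 1))) {
    msg <- c(msg, "richness values must be integers >= 1")
  }
  if (length(object@rootAge) != 1L || !is.finite(object@rootAge) ||
      object@rootAge <= 0) {
    msg <- c(msg, "rootAge must be a single positive number")
  }
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# ERM results
# ---------------------------------------------------------------------------

#' BipartitionResult: ERM tail probabilities for one diversity bipartition
#'
#' Holds the two Equal Rates Markov tail probabilities of a sister-pair
#' diversity split -- the probability, under a uniform split of the combined
#' richness \eqn{n} into two non-empty sisters, that the focal clade is at
#' least as diverse as observed -- together with the Bonferroni-corrected
#' significance threshold and per-tail significance flags. The two tails
#' always satisfy \eqn{p_g + p_{ng} = n/(n-1)} (they overlap in one split).
#'
#' @slot pairId pair label.
#' @slot nTotal combined richness of the two sisters.
#' @slot pGaller,pNongaller the two ERM tail probabilities.
#' @slot alphaEffective significance threshold after correction
#'   (\code{alpha / nHypotheses}).
#' @slot sigGaller,sigNongaller logical significance flags.
#' @seealso [ermBipartitionTest()]
#' @export
setClass("BipartitionResult",
         representation(pairId = "character", nTotal = "numeric",
                        pGaller = "numeric", pNongaller = "numeric",
                        alphaEffective = "numeric",
                        sigGaller = "logical", sigNongaller = "logical"))

setValidity("BipartitionResult", function(object) {
  msg <- character()
  for (p in c(object@pGaller, object@pNongaller)) {
    if (!(p > 0 && p <= 1)) msg <- c(msg, "tail probabilities must lie in (0, 1]")
  }
  n <- object@nTotal
  if (abs(object@pGaller + object@pNongaller - n / (n - 1)) > 1e-10) {
    msg <- c(msg, "tail-sum identity p_galler + p_nongaller = n/(n-1) violated")
  }
  if (length(msg)) msg else TRUE
})

#' ErmReport: batch of ERM bipartition results
#'
#' @slot results data.frame with columns \code{pair_id}, \code{n},
#'   \code{p_galler}, \code{p_nongaller}, \code{sig_galler},
#'   \code{sig_nongaller}, one row per pair in input order.
#' @slot alphaEffective the per-tail significance threshold used.
#' @slot nGallerMoreDiverse count of pairs in which the galling sister holds
#'   the larger richness.
#' @seealso [ermTableReport()]
#' @export
setClass("ErmReport",
         representation(results = "data.frame", alphaEffective = "numeric",
                        nGallerMoreDiverse = "integer"))

# ---------------------------------------------------------------------------
# Contrast results
# ---------------------------------------------------------------------------

#' ContrastResult: a contrast metric with its dispatched significance test
#'
#' Per-pair contrast values between sisters, the test statistic, the test
#' actually dispatched for the realized sample size (exact zeros are dropped
#' before ranking), and its p-value. The dispatch rule is: at most 10
#' non-zero contrasts, full sign-permutation randomization; 11--19, exact
#' Wilcoxon signed-rank by enumeration; 20 or more, normal approximation of
#' the signed-rank test.
#'
#' @slot metric one of \code{"raw"}, \code{"proportional"},
#'   \code{"logratio"}.
#' @slot contrasts named per-pair contrast values (zeros included).
#' @slot statistic the test statistic: the contrast sum for the
#'   sign-permutation test, the signed-rank statistic \eqn{W^+} otherwise.
#' @slot testUsed one of \code{"sign_permutation"}, \code{"wilcoxon_exact"},
#'   \code{"wilcoxon_normal"}, \code{"binomial"}.
#' @slot tails \code{"one"} or \code{"two"}.
#' @slot pValue the test p-value.
#' @slot nUsed number of contrasts entering the test after zero removal.
#' @slot extra list of ancillary quantities (dropped pair ids, direction
#'   counts, printed-value discrepancy flags).
#' @seealso [diversityContrastAnalysis()], [hostSpecificityTest()]
#' @export
setClass("ContrastResult",
         representation(metric = "character", contrasts = "numeric",
                        statistic = "numeric", testUsed = "character",
                        tails = "character", pValue = "numeric",
                        nUsed = "integer", extra = "list"))

setValidity("ContrastResult", function(object) {
  msg <- character()
  if (!(object@pValue > 0 && object@pValue <= 1)) {
    msg <- c(msg, "p-value must lie in (0, 1]")
  }
  if (object@nUsed > length(object@contrasts)) {
    msg <- c(msg, "nUsed cannot exceed the number of contrasts")
  }
  if (!object@testUsed %in% c("sign_permutation", "wilcoxon_exact",
                              "wilcoxon_normal", "binomial")) {
    msg <- c(msg, "unknown testUsed")
  }
  if (!object@tails %in% c("one", "two")) msg <- c(msg, "tails must be one/two")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# Birth-death fits
# ---------------------------------------------------------------------------

#' BDParams: net diversification rate and relative extinction
#'
#' Parameterizes a birth-death rate class by the net diversification rate
#' \eqn{r = \lambda - \mu} (per unit time) and the relative extinction
#' \eqn{\epsilon = \mu/\lambda \in [0, 1)}. The implied per-lineage rates
#' are \eqn{\lambda = r/(1-\epsilon)} and \eqn{\mu = \lambda\epsilon}.
#'
#' @slot r net diversification rate (>= 0; 0 sits at the lower boundary).
#' @slot eps relative extinction in \code{[0, 1)}.
#' @seealso [netRate()], [relExtinction()], [cladeRichnessLogProb()]
#' @export
setClass("BDParams", representation(r = "numeric", eps = "numeric"))

setValidity("BDParams", function(object) {
  msg <- character()
  if (length(object@r) != 1L || !is.finite(object@r) || object@r < 0) {
    msg <- c(msg, "r must be a single finite number >= 0")
  }
  if (length(object@eps) != 1L || !is.finite(object@eps) ||
      object@eps < 0 || object@eps >= 1) {
    msg <- c(msg, "eps must lie in [0, 1)")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a BDParams rate class
#' @param r net diversification rate (speciation minus extinction).
#' @param eps relative extinction \eqn{\mu/\lambda} in \code{[0, 1)}.
#' @return a [BDParams-class] object.
#' @examples BDParams(0.05, 0.5)
#' @export
BDParams <- function(r, eps = 0) new("BDParams", r = r, eps = eps)

#' RateShiftFit: a fitted diversification model on a richness tree
#'
#' @slot model one of \code{"fixed"}, \code{"flexible"}, \code{"stepwise"}.
#' @slot classes list of [BDParams-class], one per rate class (background
#'   first, then one per accepted shift in order of addition).
#' @slot shiftEdges integer indices into \code{phy$edge} rows of the
#'   richness tree: the stem branches at which rate classes shift (empty for
#'   the fixed model). The shifted class applies from the stem branch
#'   downward, inclusive.
#' @slot tipClasses named integer vector assigning each tip to a rate class
#'   (1 = background).
#' @slot logL maximized log-likelihood.
#' @slot nParams parameter count used for the AIC.
#' @slot AIC \code{2 * nParams - 2 * logL}.
#' @slot lrtP likelihood-ratio-test p-value against the nested fixed model
#'   (\code{NA} where not applicable).
#' @slot details list of diagnostics (per-branch log-likelihoods, optimizer
#'   boundary flags, stepwise AIC trace).
#' @seealso [fitFixedRate()], [fitFlexibleRate()], [stepwiseShiftSearch()]
#' @export
setClass("RateShiftFit",
         representation(model = "character", classes = "list",
                        shiftEdges = "integer", tipClasses = "integer",
                        logL = "numeric", nParams = "integer",
                        AIC = "numeric", lrtP = "numeric", details = "list"))

setValidity("RateShiftFit", function(object) {
  msg <- character()
  if (!object@model %in% c("fixed", "flexible", "stepwise")) {
    msg <- c(msg, "unknown model type")
  }
  if (length(object@classes) != length(object@shiftEdges) + 1L) {
    msg <- c(msg, "classes count must equal shifts + 1")
  }
  if (is.finite(object@logL) &&
      abs(object@AIC - (2 * object@nParams - 2 * object@logL)) > 1e-6) {
    msg <- c(msg, "AIC inconsistent with logL and nParams")
  }
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# Simulation containers and the pipeline report
# ---------------------------------------------------------------------------

#' BDSimulation: one simulated birth-death tree
#'
#' @slot fullTree the complete simulated tree including extinct lineages
#'   (ape \code{phylo}).
#' @slot tree the reconstructed (extant-only, ultrametric) tree, or
#'   \code{NULL} when fewer than two lineages survive.
#' @slot extantTips labels of extant tips in \code{fullTree}.
#' @slot shiftedTips labels of extant tips belonging to the shifted rate
#'   class (empty when no shift was simulated).
#' @slot params list of the simulation settings used.
#' @slot status \code{"ok"}, \code{"extinct"} (no survivors) or
#'   \code{"single"} (one survivor; no reconstructed tree).
#' @seealso [simulateBDTree()], [collapseToRichnessTree()]
#' @export
setClass("BDSimulation",
         representation(fullTree = "phylo", tree = "ANY",
                        extantTips = "character", shiftedTips = "character",
                        params = "list", status = "character"))

#' AnalysisReport: the assembled sister-pair reproduction report
#'
#' Bundle returned by [reproduceTable1()]: ERM bipartition results for every
#' pair, the three diversity-contrast analyses, the host-specificity test,
#' the binomial sign test on the direction counts, and an exhaustive table
#' of comparisons against the printed reference values with discrepancy
#' flags (mismatches are first-class entries, never silently reconciled).
#'
#' @slot table the input [SisterPairTable-class].
#' @slot erm the [ErmReport-class].
#' @slot contrasts named list of [ContrastResult-class], one per metric.
#' @slot hostTest the host-specificity [ContrastResult-class].
#' @slot binomialP exact two-tailed binomial p for the direction counts.
#' @slot nGallerMoreDiverse count of pairs with the galler more diverse.
#' @slot comparisons data.frame comparing every computed quantity with its
#'   printed reference value (\code{matches} flag; \code{known_discrepancy}
#'   marks the documented mismatches).
#' @slot provenance list (package version, input table, alpha).
#' @seealso [reproduceTable1()], [writeAnalysisReport()]
#' @export
setClass("AnalysisReport",
         representation(table = "SisterPairTable", erm = "ErmReport",
                        contrasts = "list", hostTest = "ContrastResult",
                        binomialP = "numeric",
                        nGallerMoreDiverse = "integer",
                        comparisons = "data.frame", provenance = "list"))
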