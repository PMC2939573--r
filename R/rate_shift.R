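#' @include contrasts.R
NULL

# log(beta) and log(1 - beta) for the survival-conditioned birth-death
# richness law, computed stably across the full range of r*t.
#   beta = (e^{rt} - 1) / (e^{rt} - eps) = expm1(rt) / (expm1(rt) + 1 - eps)
# For r -> 0 this tends to 0 continuously (expm1 keeps full precision);
# for large rt both logs are evaluated in log space to avoid overflow.
.betaLogs <- function(t, r, eps) {
  A <- r * t
  n <- length(A)
  logB <- numeric(n)
  log1mB <- numeric(n)
  big <- A > 30
  if (any(big)) {
    aa <- A[big]
    logDen <- aa + log1p(-eps * exp(-aa))
    logB[big] <- aa + log1p(-exp(-aa)) - logDen
    log1mB[big] <- log1p(-eps) - logDen
  }
  if (any(!big)) {
    aa <- A[!big]
    em <- expm1(aa)
    den <- em + (1 - eps)
    logB[!big] <- ifelse(em > 0, log(em) - log(den), -Inf)
    log1mB[!big] <- log1p(-eps) - log(den)
  }
  list(logBeta = logB, log1mBeta = log1mB)
}

# beta itself (used by the richness sampler).
.betaVal <- function(t, r, eps) {
  em <- expm1(pmin(r * t, 700))
  em / (em + (1 - eps))
}

#' Log-probability of a clade's extant richness given its stem age
#'
#' The stem-age taxonomic likelihood of a terminal clade: the probability
#' that a single stem lineage of age \eqn{t}, evolving under a birth-death
#' process with net rate \eqn{r} and relative extinction \eqn{\epsilon},
#' leaves exactly \eqn{n} extant species, conditioned on leaving at least
#' one (observed clades survive by construction). This is geometric:
#' \deqn{P(n) = (1 - \beta)\,\beta^{\,n-1}, \qquad
#'   \beta = \frac{e^{rt} - 1}{e^{rt} - \epsilon},}
#' with \eqn{\beta = 1 - e^{-rt}} at \eqn{\epsilon = 0} and continuous
#' behaviour as \eqn{r \to 0} (computed via \code{expm1}). The pmf sums to
#' 1 over \eqn{n \ge 1}, and the unconditional expected richness of a stem
#' lineage is \eqn{e^{rt}}.
#'
#' @param n extant richness (integer >= 1); vectorized.
#' @param t stem age (> 0); vectorized, recycled against \code{n}.
#' @param r net diversification rate (>= 0), or a [BDParams-class] object
#'   (in which case \code{eps} is taken from it).
#' @param eps relative extinction in \code{[0, 1)}.
#' @return numeric vector of log-probabilities.
#' @examples
#' exp(cladeRichnessLogProb(1, 10, 0.1, 0))  # e^{-1}
#' @export
cladeRichnessLogProb <- function(n, t, r, eps = 0) {
  if (is(r, "BDParams")) {
    eps <- r@eps
    r <- r@r
  }
  stopifnot(all(.isCount(n, min = 1)), all(is.finite(t)), all(t > 0),
            length(r) == 1L, is.finite(r), r >= 0,
            length(eps) == 1L, eps >= 0, eps < 1)
  k <- max(length(n), length(t))
  n <- rep_len(n, k)
  t <- rep_len(t, k)
  b <- .betaLogs(t, r, eps)
  out <- b$log1mBeta
  gt1 <- n > 1
  out[gt1] <- out[gt1] + (n[gt1] - 1) * b$logBeta[gt1]
  out
}

# ---------------------------------------------------------------------------
# Single-class ML fitting
# ---------------------------------------------------------------------------

# Maximize the summed richness log-likelihood for one rate class.
# eps is a fixed value in [0,1) or "free". rMax bounds the net-rate search;
# the per-clade MLE log(n_i)/t_i never exceeds log(sum n)/min t, so twice
# that is a safe bracket. Deterministic 3-point multi-start guards against
# flat likelihoods when eps is free.
.fitClass <- function(n, t, eps, rMax = NULL, candidates = NULL) {
  if (is.null(rMax)) rMax <- 2 * log(sum(n) + 2) / min(t)
  logL0 <- if (all(n == 1)) sum(cladeRichnessLogProb(n, t, 0, if (identical(eps, "free")) 0 else eps)) else -Inf
  if (identical(eps, "free")) {
    obj <- function(p) {
      v <- sum(cladeRichnessLogProb(n, t, p[1L], p[2L]))
      if (!is.finite(v)) return(1e10)
      -v
    }
    rInit <- max(log(mean(n) + 1) / mean(t), 1e-6 / mean(t))
    starts <- list(c(rInit, 0.05), c(rInit * 0.5, 0.5), c(rInit * 1.5, 0.9))
    best <- NULL
    for (s in starts) {
      s[1L] <- min(max(s[1L], 1e-9), rMax)
      fit <- tryCatch(
        stats::optim(s, obj, method = "L-BFGS-B",
                     lower = c(1e-10, 0), upper = c(rMax, 0.999),
                     control = list(maxit = 500)),
        error = function(e) NULL)
      if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
    }
    if (is.null(best)) stop("rate optimization failed for all starts", call. = FALSE)
    r <- best$par[1L]
    epsHat <- best$par[2L]
    logL <- -best$value
    for (cand in candidates) {  # e.g. the nested fixed-model optimum
      v <- -obj(cand)
      if (v > logL) {
        r <- cand[1L]; epsHat <- cand[2L]; logL <- v
      }
    }
    if (logL0 > logL) {
      r <- 0; epsHat <- 0; logL <- logL0
    }
    list(r = r, eps = epsHat, logL = logL,
         boundary = r < 1e-6 * rMax || r > (1 - 1e-6) * rMax)
  } else {
    f <- function(r) {
      v <- sum(cladeRichnessLogProb(n, t, r, eps))
      if (!is.finite(v)) -1e10 else v
    }
    opt <- stats::optimize(f, c(1e-12, rMax), maximum = TRUE,
                           tol = .Machine$double.eps^0.5 * rMax)
    r <- opt$maximum
    logL <- opt$objective
    for (cand in candidates) {
      v <- f(cand[1L])
      if (v > logL) {
        r <- cand[1L]; logL <- v
      }
    }
    if (logL0 > logL) {
      r <- 0; logL <- logL0
    }
    list(r = r, eps = eps, logL = logL,
         boundary = r < 1e-6 * rMax || r > (1 - 1e-6) * rMax)
  }
}

#' Fit the fixed (single-rate) birth-death model to a richness tree
#'
#' Maximizes \eqn{\sum_i \log P(n_i \mid t_i, r, \epsilon)} over the net
#' rate \eqn{r} (and \eqn{\epsilon} when free) across all terminal clades:
#' a single diversification rate for every lineage. With all tip richness
#' equal to 1 the estimate sits at the \eqn{r = 0} boundary and is flagged
#' in \code{details$boundary}.
#'
#' @param tree a [RichnessTree-class] with at least 2 tips.
#' @param eps relative extinction: a fixed value in \code{[0, 1)} (the
#'   conventional sensitivity grid is 0 and 0.95) or \code{"free"} to
#'   estimate it.
#' @return a [RateShiftFit-class] with one rate class and
#'   \code{nParams = 1} (fixed \code{eps}) or 2 (free).
#' @examples
#' tr <- readRichnessTree("((A:10,B:10):10,C:20);",
#'                        c(A = 5, B = 3, C = 10))
#' fitFixedRate(tr, eps = 0)
#' @export
fitFixedRate <- function(tree, eps = 0) {
  stopifnot(is(tree, "RichnessTree"))
  n <- tipRichness(tree)
  t <- stemAges(tree)
  if (length(n) < 2L) stop("tree must have at least 2 tips", call. = FALSE)
  fit <- .fitClass(n, t, eps)
  nP <- if (identical(eps, "free")) 2L else 1L
  new("RateShiftFit", model = "fixed",
      classes = list(background = BDParams(fit$r, fit$eps)),
      shiftEdges = integer(0),
      tipClasses = stats::setNames(rep(1L, length(n)), names(n)),
      logL = fit$logL, nParams = nP, AIC = 2 * nP - 2 * fit$logL,
      lrtP = NA_real_,
      details = list(boundary = fit$boundary, eps = eps))
}

# Tip index sets subtended by each edge of a phylo object
# (single postorder pass).
.edgeTipSets <- function(phy) {
  ntip <- length(phy$tip.label)
  desc <- vector("list", ntip + phy$Nnode)
  for (i in seq_len(ntip)) desc[[i]] <- i
  po <- ape::reorder.phylo(phy, "postorder")
  for (e in seq_len(nrow(po$edge))) {
    p <- po$edge[e, 1L]
    c_ <- po$edge[e, 2L]
    desc[[p]] <- c(desc[[p]], desc[[c_]])
  }
  lapply(seq_len(nrow(phy$edge)), function(e) sort(desc[[phy$edge[e, 2L]]]))
}

#' Fit the flexible (one-shift) birth-death model
#'
#' For every branch of the richness tree, allows the ancestral net rate to
#' shift to a descendant rate along that branch: tips inside the subtree
#' below the branch get their own \eqn{(r_2, \epsilon_2)}, tips outside keep
#' \eqn{(r_1, \epsilon_1)} (the shifted class applies from the stem branch
#' downward, inclusive). The two class likelihoods are separable, so each
#' side is maximized independently. The branch with maximal total
#' log-likelihood is returned, with a likelihood-ratio test against the
#' fixed model: \eqn{\chi^2} with 1 df when \eqn{\epsilon} is fixed (only
#' the extra rate), 2 df when free per class. No multiple-testing correction
#' is applied across candidate branches.
#'
#' @param tree a [RichnessTree-class] with at least 3 tips.
#' @inheritParams fitFixedRate
#' @return a [RateShiftFit-class] with two rate classes (background first),
#'   the best shift branch in \code{shiftEdges}, the LRT p-value in
#'   \code{lrtP}, and the per-branch log-likelihood profile in
#'   \code{details$profile}.
#' @export
fitFlexibleRate <- function(tree, eps = 0) {
  stopifnot(is(tree, "RichnessTree"))
  n <- tipRichness(tree)
  t <- stemAges(tree)
  if (length(n) < 3L) stop("tree must have at least 3 tips", call. = FALSE)
  base <- fitFixedRate(tree, eps)
  phy <- tree@phy
  ntip <- length(n)
  sets <- .edgeTipSets(phy)
  rMax <- 2 * log(sum(n) + 2) / min(t)
  baseCand <- list(c(base@classes[[1L]]@r, base@classes[[1L]]@eps))
  cache <- new.env(parent = emptyenv())
  classFit <- function(idx) {
    key <- paste(idx, collapse = ",")
    got <- cache[[key]]
    if (is.null(got)) {
      got <- .fitClass(n[idx], t[idx], eps, rMax = rMax, candidates = baseCand)
      cache[[key]] <- got
    }
    got
  }
  nEdge <- nrow(phy$edge)
  logLs <- rep(-Inf, nEdge)
  fits <- vector("list", nEdge)
  for (e in seq_len(nEdge)) {
    inside <- sets[[e]]
    if (length(inside) >= ntip) next  # degenerate: whole tree shifted
    outside <- setdiff(seq_len(ntip), inside)
    fi <- classFit(inside)
    fo <- classFit(outside)
    logLs[e] <- fi$logL + fo$logL
    fits[[e]] <- list(inside = fi, outside = fo)
  }
  bestE <- which.max(logLs)
  bf <- fits[[bestE]]
  df <- if (identical(eps, "free")) 2L else 1L
  lrt <- max(0, 2 * (logLs[bestE] - base@logL))
  nP <- if (identical(eps, "free")) 5L else 3L  # rates (+eps) + shift position
  cls <- rep(1L, ntip)
  cls[sets[[bestE]]] <- 2L
  new("RateShiftFit", model = "flexible",
      classes = list(background = BDParams(bf$outside$r, bf$outside$eps),
                     shifted = BDParams(bf$inside$r, bf$inside$eps)),
      shiftEdges = bestE,
      tipClasses = stats::setNames(cls, names(n)),
      logL = logLs[bestE], nParams = nP, AIC = 2 * nP - 2 * logLs[bestE],
      lrtP = stats::pchisq(lrt, df, lower.tail = FALSE),
      details = list(profile = data.frame(edge = seq_len(nEdge), logL = logLs),
                     fixedLogL = base@logL, fixedFit = base, df = df,
                     shiftTips = names(n)[sets[[bestE]]]))
}

#' Stepwise AIC search for multiple diversification-rate shifts
#'
#' Starts from the one-class model with free relative extinction and
#' iteratively adds the single stem-branch shift that most decreases the
#' AIC, stopping when the best improvement falls below
#' \code{deltaAICCut}. Each rate class carries its own
#' \eqn{(r, \epsilon)}; shifts cut at the stem (the shifted class applies
#' from the selected branch downward, nested shifts override outer ones),
#' and each accepted shift contributes one parameter for its location, so
#' \code{nParams = 2 * classes + shifts}.
#'
#' @param tree a [RichnessTree-class].
#' @param deltaAICCut minimum AIC improvement required to accept another
#'   shift (default 4).
#' @param maxShifts safety cap on the number of shifts.
#' @return a [RateShiftFit-class] with \code{model == "stepwise"} and the
#'   AIC trace in \code{details$trace}. With no acceptable shift this is
#'   the one-class free-extinction model.
#' @export
stepwiseShiftSearch <- function(tree, deltaAICCut = 4,
                                maxShifts = length(tipRichness(tree)) - 2L) {
  stopifnot(is(tree, "RichnessTree"), deltaAICCut > 0)
  n <- tipRichness(tree)
  t <- stemAges(tree)
  ntip <- length(n)
  phy <- tree@phy
  sets <- .edgeTipSets(phy)
  rMax <- 2 * log(sum(n) + 2) / min(t)
  cache <- new.env(parent = emptyenv())
  classFit <- function(idx) {
    key <- paste(idx, collapse = ",")
    got <- cache[[key]]
    if (is.null(got)) {
      got <- .fitClass(n[idx], t[idx], "free", rMax = rMax)
      cache[[key]] <- got
    }
    got
  }
  # edge indices on the root-ward path of each tip, tip-first: the class of
  # a tip is the first path edge that carries a shift ("cutAtStem" nesting).
  parentEdge <- match(seq_len(ntip + phy$Nnode), phy$edge[, 2L])
  rootNode <- ntip + 1L
  tipPaths <- lapply(seq_len(ntip), function(tip) {
    path <- integer(0)
    node <- tip
    while (node != rootNode) {
      e <- parentEdge[node]
      path <- c(path, e)
      node <- phy$edge[e, 1L]
    }
    path
  })
  assignClasses <- function(shiftSet) {
    vapply(tipPaths, function(p) {
      hit <- p[p %in% shiftSet]
      if (length(hit)) hit[1L] else 0L
    }, 0L)
  }
  evalModel <- function(shiftSet) {
    cls <- assignClasses(shiftSet)
    keys <- c(0L, shiftSet)
    if (!all(keys %in% cls)) return(NULL)  # some class has no tips
    groups <- split(seq_len(ntip), factor(cls, levels = keys))
    fits <- lapply(groups, classFit)
    logL <- sum(vapply(fits, `[[`, 0, "logL"))
    s <- length(shiftSet)
    nP <- 2L * (s + 1L) + s
    list(shiftSet = shiftSet, cls = cls, fits = fits, logL = logL,
         nParams = nP, AIC = 2 * nP - 2 * logL)
  }
  cur <- evalModel(integer(0))
  trace <- data.frame(step = 0L, edge = NA_integer_, AIC = cur$AIC,
                      logL = cur$logL)
  repeat {
    if (length(cur$shiftSet) >= maxShifts) break
    cand <- setdiff(seq_len(nrow(phy$edge)), cur$shiftSet)
    best <- NULL
    for (e in cand) {
      if (length(sets[[e]]) >= ntip) next
      mod <- evalModel(c(cur$shiftSet, e))
      if (is.null(mod)) next
      if (is.null(best) || mod$AIC < best$AIC) best <- mod
    }
    if (is.null(best) || cur$AIC - best$AIC < deltaAICCut) break
    cur <- best
    trace <- rbind(trace,
                   data.frame(step = length(cur$shiftSet),
                              edge = cur$shiftSet[length(cur$shiftSet)],
                              AIC = cur$AIC, logL = cur$logL))
  }
  classList <- lapply(cur$fits, function(f) BDParams(f$r, f$eps))
  names(classList) <- c("background",
                        if (length(cur$shiftSet))
                          paste0("shift_edge", cur$shiftSet))
  clsIdx <- match(cur$cls, c(0L, cur$shiftSet))
  new("RateShiftFit", model = "stepwise", classes = classList,
      shiftEdges = as.integer(cur$shiftSet),
      tipClasses = stats::setNames(as.integer(clsIdx), names(n)),
      logL = cur$logL, nParams = as.integer(cur$nParams), AIC = cur$AIC,
      lrtP = NA_real_,
      details = list(trace = trace, deltaAICCut = deltaAICCut))
}

# ---------------------------------------------------------------------------
# Accessors / show
# ---------------------------------------------------------------------------

#' @describeIn netRate net diversification rate.
#' @export
setMethod("netRate", "BDParams", function(x) x@r)

#' @describeIn relExtinction relative extinction fraction.
#' @export
setMethod("relExtinction", "BDParams", function(x) x@eps)

#' Speciation rate implied by a rate class
#' @param x a [BDParams-class].
#' @return \eqn{\lambda = r / (1 - \epsilon)}.
#' @export
lambdaRate <- function(x) {
  stopifnot(is(x, "BDParams"))
  x@r / (1 - x@eps)
}

#' Extinction rate implied by a rate class
#' @param x a [BDParams-class].
#' @return \eqn{\mu = \lambda \epsilon}.
#' @export
muRate <- function(x) lambdaRate(x) * x@eps

setMethod("show", "BDParams", function(object) {
  cat(sprintf("BDParams: r = %.4g, eps = %.4g (lambda = %.4g, mu = %.4g)\n",
              object@r, object@eps, lambdaRate(object), muRate(object)))
})

#' @describeIn rateClasses rate classes of the fit.
#' @export
setMethod("rateClasses", "RateShiftFit", function(x) x@classes)

#' @describeIn shiftEdges shift stem branches of the fit.
#' @export
setMethod("shiftEdges", "RateShiftFit", function(x) x@shiftEdges)

#' @describeIn fitLogL maximized log-likelihood.
#' @export
setMethod("fitLogL", "RateShiftFit", function(x) x@logL)

#' @describeIn fitAIC AIC of the fit.
#' @export
setMethod("fitAIC", "RateShiftFit", function(x) x@AIC)

#' @describeIn lrtPvalue LRT p-value (NA for fixed/stepwise fits).
#' @export
setMethod("lrtPvalue", "RateShiftFit", function(x) x@lrtP)

setMethod("show", "RateShiftFit", function(object) {
  cat(sprintf("RateShiftFit (%s model): logL = %.4f, AIC = %.4f (%d param)\n",
              object@model, object@logL, object@AIC, object@nParams))
  for (i in seq_along(object@classes)) {
    cl <- object@classes[[i]]
    cat(sprintf("  class %d (%s): r = %.4g, eps = %.4g\n", i,
                names(object@classes)[i], cl@r, cl@eps))
  }
  if (length(object@shiftEdges)) {
    cat("  shift branch(es): edge ",
        paste(object@shiftEdges, collapse = ", "), "\n", sep = "")
  }
  if (!is.na(object@lrtP)) {
    cat(sprintf("  LRT vs fixed model: p = %.4g\n", object@lrtP))
  }
})
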