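#' @include rate_shift.R
NULL

# All generators follow one RNG discipline: an optional `seed` argument
# seeds a private stream for that single call (the caller's stream is
# untouched); with seed = NULL they consume the current stream.

#' Simulate diversity bipartitions under the ERM null
#'
#' Under the Equal Rates Markov model every split of \eqn{n} species into
#' two non-empty sisters is equiprobable, so the focal richness \eqn{k} is
#' uniform on \eqn{\{1, \dots, n-1\}}.
#'
#' @param n total richness (>= 2).
#' @param reps number of splits to draw.
#' @param seed optional integer seed.
#' @return integer matrix with columns \code{k} and \code{n_minus_k}.
#' @examples
#' head(simulateErmSplits(153, 5, seed = 1))
#' @export
simulateErmSplits <- function(n, reps, seed = NULL) {
  stopifnot(.isCount(n, min = 2), .isCount(reps, min = 1))
  .withSeed(seed, {
    k <- sample.int(n - 1L, reps, replace = TRUE)
    cbind(k = k, n_minus_k = n - k)
  })
}

#' Sample clade richness under the birth-death model
#'
#' Draws extant richness for stem lineages of age \code{t} under net rate
#' \code{r} and relative extinction \code{eps}: geometric
#' \eqn{(1-\beta)\beta^{n-1}} on \eqn{n \ge 1} when conditioned on survival
#' (the same law the rate-shift likelihood evaluates), with an atom at 0
#' (extinction, probability \eqn{\epsilon\beta}) when unconditioned. The
#' unconditional mean is \eqn{e^{rt}}.
#'
#' @param reps number of clades to draw.
#' @param t stem age(s); recycled to length \code{reps}.
#' @param r net diversification rate.
#' @param eps relative extinction in \code{[0, 1)}.
#' @param conditionOnSurvival draw from the survival-conditioned law?
#' @param seed optional integer seed.
#' @return integer vector of clade sizes (zeros possible only when
#'   \code{conditionOnSurvival = FALSE}).
#' @export
sampleCladeRichness <- function(reps, t, r, eps = 0,
                                conditionOnSurvival = TRUE, seed = NULL) {
  stopifnot(.isCount(reps, min = 1), all(t > 0), r >= 0, eps >= 0, eps < 1)
  .withSeed(seed, {
    t <- rep_len(t, reps)
    # exact inverse-CDF geometric draw on the log scale; stable as beta -> 1
    # (where the mean grows like e^{rt} and naive samplers overflow)
    logBeta <- .betaLogs(t, r, eps)$logBeta
    u <- stats::runif(reps)
    n <- ifelse(logBeta == -Inf, 1, 1 + floor(log(u) / logBeta))
    if (!conditionOnSurvival) {
      beta <- .betaVal(t, r, eps)
      extinct <- stats::runif(reps) < eps * beta
      n[extinct] <- 0
    }
    n
  })
}

#' Generate a synthetic sister-pair table
#'
#' Emulates the statistical structure of a galler / non-galler comparison
#' table: for each pair, the two clade richnesses are survival-conditioned
#' birth-death draws at a common stem age, with the galling side's net rate
#' multiplied by \code{rateRatio} (1 = the equal-rates null). Host-MRCA ages
#' mimic empirical tables: a share of pairs (\code{tieProb}) has identical
#' ages on both sides, and tied or untied ages carry a point mass at 0 Ma
#' (\code{zeroAgeProb}) for host ranges confined to one terminal lineage.
#'
#' @param nPairs number of sister pairs (default 13, a typical survey size).
#' @param rateRatio galler net rate relative to the non-galler rate (> 0).
#' @param r baseline net diversification rate per Ma.
#' @param eps relative extinction.
#' @param stemAgeRange range (Ma) from which common stem ages are drawn
#'   uniformly.
#' @param hostAgeMax upper bound (Ma) of the uniform host-age draw.
#' @param tieProb probability that a pair's two host ages are identical.
#' @param zeroAgeProb probability that a drawn host age is exactly 0 Ma.
#' @param seed optional integer seed.
#' @return a [SisterPairTable-class].
#' @examples
#' generateSisterTable(5, rateRatio = 2, seed = 42)
#' @export
generateSisterTable <- function(nPairs = 13, rateRatio = 1, r = 0.05,
                                eps = 0, stemAgeRange = c(40, 120),
                                hostAgeMax = 150, tieProb = 0.5,
                                zeroAgeProb = 0.5, seed = NULL) {
  stopifnot(.isCount(nPairs, min = 1), rateRatio > 0, r >= 0,
            length(stemAgeRange) == 2L, all(stemAgeRange > 0))
  .withSeed(seed, {
    t <- stats::runif(nPairs, stemAgeRange[1L], stemAgeRange[2L])
    nG <- sampleCladeRichness(nPairs, t, r * rateRatio, eps)
    nN <- sampleCladeRichness(nPairs, t, r, eps)
    drawAge <- function(k) {
      ifelse(stats::runif(k) < zeroAgeProb, 0,
             stats::runif(k, 0, hostAgeMax))
    }
    tie <- stats::runif(nPairs) < tieProb
    ageG <- drawAge(nPairs)
    ageN <- drawAge(nPairs)
    ageN[tie] <- ageG[tie]
    idx <- seq_len(nPairs)
    SisterPairTable(data.frame(
      pair_id = sprintf("pair%02d", idx),
      galler_name = sprintf("galler%02d", idx),
      n_galler = nG,
      host_age_galler = ageG,
      nongaller_name = sprintf("nongaller%02d", idx),
      n_nongaller = nN,
      host_age_nongaller = ageN,
      stringsAsFactors = FALSE))
  })
}

# ---------------------------------------------------------------------------
# Birth-death tree simulation
# ---------------------------------------------------------------------------

# Growable lineage-record store.
.newRecords <- function() {
  env <- new.env(parent = emptyenv())
  env$parent <- integer(256)
  env$birth <- numeric(256)
  env$end <- numeric(256)
  env$type <- integer(256)   # 0 internal, 1 extant tip, 2 extinct tip
  env$cls <- integer(256)
  env$count <- 0L
  env
}

.addRecord <- function(env, parent, birth, end, type, cls) {
  i <- env$count + 1L
  if (i > length(env$parent)) {
    grow <- function(v) c(v, v)
    env$parent <- grow(env$parent); env$birth <- grow(env$birth)
    env$end <- grow(env$end); env$type <- grow(env$type)
    env$cls <- grow(env$cls)
  }
  env$parent[i] <- parent; env$birth[i] <- birth; env$end[i] <- end
  env$type[i] <- type; env$cls[i] <- cls
  env$count <- i
  i
}

# Simulate every open lineage forward until `cap`; events before `cap`
# close records (speciation spawns two children, extinction closes a tip);
# lineages reaching `cap` are returned open (memoryless truncation).
.simSegment <- function(env, items, cap, rates, maxLineages) {
  out <- list()
  while (length(items)) {
    it <- items[[length(items)]]
    items[[length(items)]] <- NULL
    rt <- rates[[it$cls]]
    tot <- rt$lambda + rt$mu
    w <- if (tot > 0) stats::rexp(1L, tot) else Inf
    tEv <- it$clock + w
    if (tEv >= cap) {
      it$clock <- cap
      out[[length(out) + 1L]] <- it
      next
    }
    if (env$count > maxLineages) {
      stop("simulated tree exceeds ", maxLineages,
           " lineages; lower the rates or the root age", call. = FALSE)
    }
    if (stats::runif(1L) < rt$lambda / tot) {
      id <- .addRecord(env, it$parent, it$birth, tEv, 0L, it$cls)
      items[[length(items) + 1L]] <- list(parent = id, birth = tEv,
                                          clock = tEv, cls = it$cls)
      items[[length(items) + 1L]] <- list(parent = id, birth = tEv,
                                          clock = tEv, cls = it$cls)
    } else {
      .addRecord(env, it$parent, it$birth, tEv, 2L, it$cls)
    }
  }
  out
}

# Convert a closed record store to an ape phylo (root = the initial split
# of the two founding lineages at forward time 0).
.recordsToPhylo <- function(env) {
  k <- env$count
  parent <- env$parent[seq_len(k)]
  birth <- env$birth[seq_len(k)]
  end <- env$end[seq_len(k)]
  type <- env$type[seq_len(k)]
  isTip <- type != 0L
  ntip <- sum(isTip)
  nnode <- sum(!isTip) + 1L
  tipNum <- integer(k)
  tipNum[isTip] <- seq_len(ntip)
  nodeNum <- integer(k)
  nodeNum[!isTip] <- ntip + 1L + seq_len(nnode - 1L)
  childNum <- ifelse(isTip, tipNum, nodeNum)
  parentNum <- ifelse(parent == 0L, ntip + 1L, nodeNum[pmax(parent, 1L)])
  lab <- ifelse(type == 1L, paste0("t", seq_len(k)), paste0("x", seq_len(k)))
  phy <- list(edge = cbind(parentNum, childNum),
              edge.length = end - birth,
              tip.label = lab[isTip],
              Nnode = nnode)
  attr(phy, "class") <- "phylo"
  attr(phy, "order") <- NULL
  dimnames(phy$edge) <- NULL
  ape::reorder.phylo(phy, "cladewise")
}

#' Simulate a birth-death tree, optionally with a rate shift
#'
#' Forward (Gillespie-style) constant-rate birth-death simulation started
#' from the two lineages of a root split, with two stopping rules: a fixed
#' root age (the present sits \code{rootAge} time units after the root), or
#' a target number of extant tips (the present is placed uniformly within
#' the waiting interval after the target count is first reached). Under the
#' root-age rule a rate shift can be simulated: at \code{shiftAge} before
#' the present, one uniformly chosen surviving lineage switches to
#' \code{(lambda2, mu2)}, inherited by all its descendants. The complete
#' tree (extinct lineages included) is kept, and the reconstructed
#' extant-only ultrametric tree is obtained by pruning extinct tips and
#' collapsing the resulting unifurcations. With
#' \code{conditionOnSurvival = TRUE} the simulation is rejection-sampled
#' until at least two tips survive.
#'
#' @param lambda,mu base speciation and extinction rates (per unit time).
#' @param rootAge age of the root split; exclusive with
#'   \code{nTipsTarget}.
#' @param nTipsTarget stop when this many lineages are simultaneously
#'   extant; exclusive with \code{rootAge} (and with the shift options).
#' @param lambda2,mu2 post-shift rates.
#' @param shiftAge age (before present) at which the shift occurs; requires
#'   the root-age stopping rule.
#' @param conditionOnSurvival reject simulations with fewer than two extant
#'   tips?
#' @param maxAttempts rejection-sampling cap.
#' @param seed optional integer seed (same seed, bit-identical trees).
#' @return a [BDSimulation-class].
#' @examples
#' sim <- simulateBDTree(0.1, 0.05, rootAge = 10, seed = 7)
#' sim@status
#' @export
simulateBDTree <- function(lambda, mu = 0, rootAge = NULL,
                           nTipsTarget = NULL, lambda2 = NULL, mu2 = NULL,
                           shiftAge = NULL, conditionOnSurvival = TRUE,
                           maxAttempts = 100000L, seed = NULL) {
  stopifnot(lambda >= 0, mu >= 0)
  if (is.null(rootAge) == is.null(nTipsTarget)) {
    stop("exactly one of rootAge / nTipsTarget must be given", call. = FALSE)
  }
  hasShift <- !is.null(shiftAge)
  if (hasShift) {
    if (is.null(rootAge)) {
      stop("a rate shift requires the root-age stopping rule (the shift age is measured from the present)",
           call. = FALSE)
    }
    if (is.null(lambda2)) stop("shiftAge given without lambda2", call. = FALSE)
    if (is.null(mu2)) mu2 <- 0
    stopifnot(shiftAge > 0, shiftAge < rootAge, lambda2 >= 0, mu2 >= 0)
  }
  .withSeed(seed, {
    for (attempt in seq_len(maxAttempts)) {
      env <- .newRecords()
      if (!is.null(rootAge)) {
        rates <- list(list(lambda = lambda, mu = mu),
                      if (hasShift) list(lambda = lambda2, mu = mu2))
        items <- list(list(parent = 0L, birth = 0, clock = 0, cls = 1L),
                      list(parent = 0L, birth = 0, clock = 0, cls = 1L))
        if (hasShift) {
          shiftTime <- rootAge - shiftAge
          alive <- .simSegment(env, items, shiftTime, rates, 1e6)
          if (length(alive)) {
            pick <- sample.int(length(alive), 1L)
            alive[[pick]]$cls <- 2L
          }
          open <- .simSegment(env, alive, rootAge, rates, 1e6)
        } else {
          open <- .simSegment(env, items, rootAge, rates, 1e6)
        }
        for (it in open) {
          .addRecord(env, it$parent, it$birth, rootAge, 1L, it$cls)
        }
      } else {
        # tip-count stopping rule (population-level Gillespie, one class)
        if (lambda <= 0 && nTipsTarget > 2L) {
          stop("nTipsTarget > 2 unreachable with lambda = 0", call. = FALSE)
        }
        openItems <- list(list(parent = 0L, birth = 0),
                          list(parent = 0L, birth = 0))
        tm <- 0
        tot <- lambda + mu
        ok <- TRUE
        while (length(openItems) > 0L && length(openItems) < nTipsTarget) {
          tm <- tm + stats::rexp(1L, length(openItems) * tot)
          i <- sample.int(length(openItems), 1L)
          it <- openItems[[i]]
          openItems[[i]] <- NULL
          if (stats::runif(1L) < lambda / tot) {
            id <- .addRecord(env, it$parent, it$birth, tm, 0L, 1L)
            openItems[[length(openItems) + 1L]] <- list(parent = id, birth = tm)
            openItems[[length(openItems) + 1L]] <- list(parent = id, birth = tm)
          } else {
            .addRecord(env, it$parent, it$birth, tm, 2L, 1L)
          }
          if (env$count > 1e6) stop("simulated tree too large", call. = FALSE)
        }
        if (length(openItems) == 0L) ok <- FALSE
        if (ok) {
          present <- if (tot > 0) {
            tm + stats::runif(1L) * stats::rexp(1L, length(openItems) * tot)
          } else tm + 1
          if (present <= 0) present <- 1  # degenerate: no event ever drawn
          for (it in openItems) {
            .addRecord(env, it$parent, it$birth, present, 1L, 1L)
          }
        } else if (conditionOnSurvival) next
      }
      full <- .recordsToPhylo(env)
      k <- env$count
      extant <- full$tip.label[grepl("^t", full$tip.label)]
      if (conditionOnSurvival && length(extant) < 2L) next
      shifted <- character(0)
      if (hasShift) {
        isTipRec <- env$type[seq_len(k)] == 1L
        labs <- paste0("t", which(isTipRec))
        shifted <- labs[env$cls[seq_len(k)][isTipRec] == 2L]
      }
      recon <- NULL
      status <- "ok"
      if (length(extant) >= 2L) {
        recon <- ape::keep.tip(full, extant)
        recon$root.edge <- NULL
      } else {
        status <- if (length(extant) == 1L) "single" else "extinct"
      }
      return(new("BDSimulation", fullTree = full, tree = recon,
                 extantTips = extant, shiftedTips = shifted,
                 params = list(lambda = lambda, mu = mu, rootAge = rootAge,
                               nTipsTarget = nTipsTarget, lambda2 = lambda2,
                               mu2 = mu2, shiftAge = shiftAge,
                               attempts = attempt),
                 status = status))
    }
    stop("no surviving simulation in ", maxAttempts,
         " attempts; increase the rates or lower the root age", call. = FALSE)
  })
}

setMethod("show", "BDSimulation", function(object) {
  cat(sprintf("BDSimulation (%s): %d extant tip(s), %d lineage record(s)\n",
              object@status, length(object@extantTips),
              length(object@fullTree$tip.label) + object@fullTree$Nnode))
  if (length(object@shiftedTips)) {
    cat(sprintf("  %d extant tip(s) in the shifted rate class\n",
                length(object@shiftedTips)))
  }
})

#' Collapse a reconstructed tree into a richness tree
#'
#' Every maximal clade whose stem branch crosses \code{collapseAge} becomes
#' a terminal clade carrying its extant richness; stem ages (parent-node
#' ages) are preserved, internal structure older than \code{collapseAge} is
#' untouched, and the total richness equals the original extant tip count
#' exactly.
#'
#' @param tree an ultrametric extant-only \code{phylo}, or a
#'   [BDSimulation-class] (its reconstructed tree is used).
#' @param collapseAge collapse depth, strictly between 0 and the root age.
#' @param tol relative ultrametricity tolerance passed through.
#' @return a [RichnessTree-class].
#' @examples
#' sim <- simulateBDTree(0.3, 0, rootAge = 10, seed = 11)
#' collapseToRichnessTree(sim, 3)
#' @export
collapseToRichnessTree <- function(tree, collapseAge, tol = 1e-6) {
  if (is(tree, "BDSimulation")) {
    if (is.null(tree@tree)) stop("simulation has no reconstructed tree", call. = FALSE)
    tree <- tree@tree
  }
  stopifnot(inherits(tree, "phylo"))
  ntip <- length(tree$tip.label)
  depths <- ape::node.depth.edgelength(tree)
  root_age <- max(depths[seq_len(ntip)])
  if (!(collapseAge > 0 && collapseAge < root_age)) {
    stop(sprintf("collapseAge must lie strictly between 0 and the root age (%.6g)",
                 root_age), call. = FALSE)
  }
  ages <- root_age - depths
  crossing <- which(ages[tree$edge[, 1L]] > collapseAge &
                      ages[tree$edge[, 2L]] <= collapseAge)
  sets <- .edgeTipSets(tree)
  reps <- character(length(crossing))
  rich <- numeric(length(crossing))
  for (i in seq_along(crossing)) {
    tipIdx <- sets[[crossing[i]]]
    reps[i] <- tree$tip.label[tipIdx[1L]]
    rich[i] <- length(tipIdx)
  }
  pruned <- ape::keep.tip(tree, reps)
  RichnessTree(pruned, stats::setNames(rich, reps)[pruned$tip.label], tol = tol)
}

#' Build a pectinate richness tree with prescribed stem ages
#'
#' Constructs an ultrametric caterpillar (pectinate) tree whose tips have
#' the given stem ages: the i-th internal node (sorted oldest first) is the
#' parent of the i-th tip, and the two youngest tips share the last node.
#' Useful for controlled likelihood experiments where a set of
#' (stem age, richness) clades is wanted without a stochastic topology.
#'
#' @param stemAges vector of \code{nTips - 1} distinct node ages; the
#'   resulting tips have stem ages \code{sort(stemAges, TRUE)} with the
#'   youngest duplicated.
#' @param richness integer richness for each of the \code{nTips} tips
#'   (ordered by decreasing stem age).
#' @return a [RichnessTree-class] with \code{length(stemAges) + 1} tips.
#' @examples
#' richnessTreeFromStemAges(c(30, 20, 10), c(8, 4, 2, 1))
#' @export
richnessTreeFromStemAges <- function(stemAges, richness) {
  stopifnot(length(stemAges) >= 1L, all(stemAges > 0),
            length(richness) == length(stemAges) + 1L)
  a <- sort(stemAges, decreasing = TRUE)
  m <- length(a)
  ntip <- m + 1L
  # nodes numbered ntip+1 (root, age a[1]) .. ntip+m (age a[m])
  parentNode <- ntip + seq_len(m)
  edge <- matrix(0L, nrow = 2L * m, ncol = 2L)
  len <- numeric(2L * m)
  row <- 0L
  for (i in seq_len(m)) {
    row <- row + 1L  # tip i hangs off node i
    edge[row, ] <- c(parentNode[i], i)
    len[row] <- a[i]
    if (i < m) {     # chain to the next (younger) node
      row <- row + 1L
      edge[row, ] <- c(parentNode[i], parentNode[i + 1L])
      len[row] <- a[i] - a[i + 1L]
    }
  }
  row <- row + 1L    # last node carries the final tip as second child
  edge[row, ] <- c(parentNode[m], ntip)
  len[row] <- a[m]
  phy <- list(edge = edge, edge.length = len,
              tip.label = paste0("c", seq_len(ntip)), Nnode = m)
  attr(phy, "class") <- "phylo"
  phy <- ape::reorder.phylo(phy, "cladewise")
  RichnessTree(phy, stats::setNames(as.numeric(richness),
                                    paste0("c", seq_len(ntip))))
}

#' Simulate a richness tree containing one diversification-rate shift
#'
#' Builds a controlled parameter-recovery instance: a pure-birth backbone
#' topology with \code{nTips} terminal clades (simulated with
#' [simulateBDTree()] under the tip-count stopping rule and rescaled to the
#' conventional arbitrary root height of 100, so the rates are per unit of
#' that scale), one internal clade of approximately \code{shiftCladeSize}
#' tips designated as the shifted class, and per-tip richness drawn from
#' the survival-conditioned geometric law at each tip's stem age --
#' \code{(r1, eps1)} outside the shifted clade, \code{(r2, eps2)} inside.
#' Children of the root are never chosen, because the complementary root
#' branch would define the identical bipartition and make the "true" stem
#' branch ambiguous.
#'
#' @param nTips number of terminal clades in the backbone.
#' @param shiftCladeSize target tip count of the shifted clade (the
#'   eligible clade closest in size is used).
#' @param r1,eps1 background net rate and relative extinction.
#' @param r2,eps2 shifted-class net rate and relative extinction.
#' @param rootHeight height the backbone is rescaled to before richness is
#'   drawn; the backbone simulation rate only shapes the topology.
#' @param seed optional integer seed.
#' @return list with elements \code{tree} (a [RichnessTree-class]),
#'   \code{shiftEdge} (index of the true stem branch in
#'   \code{tree@phy$edge}), \code{shiftNode} and \code{shiftTips}.
#' @examples
#' inst <- simulateShiftedRichnessTree(seed = 5)
#' inst$shiftEdge
#' @export
simulateShiftedRichnessTree <- function(nTips = 30, shiftCladeSize = 10,
                                        r1 = 0.05, eps1 = 0, r2 = 0.15,
                                        eps2 = 0, rootHeight = 100,
                                        seed = NULL) {
  stopifnot(nTips >= 6, shiftCladeSize >= 2, shiftCladeSize <= nTips - 2)
  .withSeed(seed, {
    sim <- simulateBDTree(1, 0, nTipsTarget = nTips,
                          conditionOnSurvival = TRUE)
    phy <- sim@tree
    depths0 <- ape::node.depth.edgelength(phy)
    phy$edge.length <- phy$edge.length *
      (rootHeight / max(depths0[seq_along(phy$tip.label)]))
    ntip <- length(phy$tip.label)
    sets <- .edgeTipSets(phy)
    rootNode <- ntip + 1L
    sizes <- lengths(sets)
    eligible <- which(phy$edge[, 1L] != rootNode & phy$edge[, 2L] > ntip &
                        sizes <= ntip - 2L)
    if (!length(eligible)) stop("backbone has no eligible shift clade", call. = FALSE)
    shiftEdge <- eligible[which.min(abs(sizes[eligible] - shiftCladeSize))]
    inside <- sets[[shiftEdge]]
    depths <- ape::node.depth.edgelength(phy)
    root_age <- max(depths[seq_len(ntip)])
    parent <- phy$edge[match(seq_len(ntip), phy$edge[, 2L]), 1L]
    stem <- root_age - depths[parent]
    rich <- numeric(ntip)
    outIdx <- setdiff(seq_len(ntip), inside)
    rich[outIdx] <- sampleCladeRichness(length(outIdx), stem[outIdx], r1, eps1)
    rich[inside] <- sampleCladeRichness(length(inside), stem[inside], r2, eps2)
    tree <- RichnessTree(phy, stats::setNames(rich, phy$tip.label))
    list(tree = tree, shiftEdge = shiftEdge,
         shiftNode = phy$edge[shiftEdge, 2L],
         shiftTips = phy$tip.label[inside])
  })
}
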