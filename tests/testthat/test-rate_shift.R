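test_that("richness log-probability matches closed forms and normalizes", {
  # pure birth, rt = 1: P(1) = e^{-1}
  expect_equal(exp(cladeRichnessLogProb(1, 10, 0.1, 0)), exp(-1))
  # vanishing stem age concentrates all mass at n = 1
  expect_gt(exp(cladeRichnessLogProb(1, 1e-8, 0.1, 0.5)), 1 - 1e-6)
  # r = 0 with eps < 1 degenerates to a single surviving lineage
  expect_equal(cladeRichnessLogProb(1, 5, 0, 0.3), 0)
  expect_equal(cladeRichnessLogProb(2, 5, 0, 0.3), -Inf)
  # geometric normalization over a parameter grid (truncated + tail bound)
  for (par in list(c(0.1, 10, 0), c(0.05, 40, 0.5), c(0.2, 30, 0.9))) {
    lp <- cladeRichnessLogProb(seq_len(50000), par[2], par[1], par[3])
    beta <- 1 - exp(cladeRichnessLogProb(1, par[2], par[1], par[3]))
    tail <- beta^50000  # mass beyond the truncation
    expect_equal(sum(exp(lp)) + tail, 1, tolerance = 1e-9)
  }
  # extreme rt stays finite (beta ~ 1: the size term vanishes numerically)
  lp <- cladeRichnessLogProb(c(1, 100), 1e4, 0.5, 0.2)
  expect_true(all(is.finite(lp)))
  expect_true(lp[2] >= lp[1])  # big clades no less likely than n = 1
  expect_error(cladeRichnessLogProb(0, 1, 0.1), "isCount|>= 1|n")
  expect_error(cladeRichnessLogProb(2, -1, 0.1))
})

test_that("likelihood is invariant under joint time/rate rescaling", {
  n <- c(5, 3, 10)
  t <- c(12, 7, 20)
  for (cc in c(0.1, 10, 100)) {
    expect_equal(sum(cladeRichnessLogProb(n, t * cc, 0.08 / cc, 0.4)),
                 sum(cladeRichnessLogProb(n, t, 0.08, 0.4)))
  }
})

test_that("BDParams validates and exposes the implied per-lineage rates", {
  p <- BDParams(0.05, 0.5)
  expect_equal(netRate(p), 0.05)
  expect_equal(relExtinction(p), 0.5)
  expect_equal(lambdaRate(p), 0.1)
  expect_equal(muRate(p), 0.05)
  expect_error(BDParams(-1, 0))
  expect_error(BDParams(0.1, 1))
})

test_that("fixed-rate fit handles boundaries and single-clade closed forms", {
  flat <- readRichnessTree("((A:1,B:1):1,C:2);", c(A = 1, B = 1, C = 1))
  f <- fitFixedRate(flat, eps = 0)
  expect_equal(netRate(rateClasses(f)[[1]]), 0, tolerance = 1e-6)
  expect_equal(fitLogL(f), 0, tolerance = 1e-6)   # P(1 | t, r = 0) = 1
  expect_true(f@details$boundary)
  expect_equal(fitAIC(f), 2 - 2 * fitLogL(f))
  # two identical clades with n = e^{r t} at t = 20: the MLE solves
  # beta-hat = (n - 1)/n, i.e. r-hat = log(n)/t
  tr <- readRichnessTree("(A:20,B:20);", c(A = 3, B = 3))
  f2 <- fitFixedRate(tr, eps = 0)
  expect_equal(netRate(rateClasses(f2)[[1]]), log(3) / 20, tolerance = 1e-4)
})

test_that("fixed-rate fit recovers the generating rate on simulated clades", {
  ages <- seq(80, 20, length.out = 29)
  rich <- sampleCladeRichness(30, c(ages, ages[29]), 0.05, 0, seed = 77)
  tr <- richnessTreeFromStemAges(ages, rich)
  f <- fitFixedRate(tr, eps = 0)
  expect_lt(abs(netRate(rateClasses(f)[[1]]) - 0.05) / 0.05, 0.3)
  # free-eps fit can only improve the likelihood over eps fixed at truth
  ffree <- fitFixedRate(tr, eps = "free")
  expect_gte(fitLogL(ffree), fitLogL(f) - 1e-6)
  expect_equal(ffree@nParams, 2L)
  eps <- relExtinction(rateClasses(ffree)[[1]])
  expect_true(eps >= 0 && eps < 1)
})

test_that("flexible fit nests the fixed fit and degenerates with no signal", {
  # three identical clades: no shift can help; r1 = r2 at the optimum
  same <- readRichnessTree("((A:10,B:10):10,C:20);", c(A = 4, B = 4, C = 4))
  f0 <- fitFixedRate(same, 0)
  f1 <- fitFlexibleRate(same, 0)
  expect_gte(fitLogL(f1), fitLogL(f0) - 1e-8)
  # nesting inequality across random instances
  set.seed(55)
  for (i in 1:8) {
    inst <- simulateShiftedRichnessTree(nTips = 12, shiftCladeSize = 4,
                                        r1 = 0.04, r2 = 0.04)
    a <- fitFixedRate(inst$tree, 0)
    b <- fitFlexibleRate(inst$tree, 0)
    expect_gte(fitLogL(b), fitLogL(a) - 1e-8)
    expect_true(b@lrtP > 0 && b@lrtP <= 1)
    expect_equal(length(shiftEdges(b)), 1L)
    expect_equal(sort(unique(unname(b@tipClasses))), c(1L, 2L))
  }
})

test_that("flexible fit locates an unmistakable simulated shift", {
  # a five-fold rate increase leaves no ambiguity about the shifted clade
  for (s in c(2, 5, 8)) {
    inst <- simulateShiftedRichnessTree(nTips = 30, shiftCladeSize = 10,
                                        r1 = 0.05, r2 = 0.25, seed = s)
    fit <- fitFlexibleRate(inst$tree, 0)
    expect_equal(shiftEdges(fit), inst$shiftEdge)
    expect_gt(netRate(rateClasses(fit)$shifted),
              netRate(rateClasses(fit)$background))
    expect_equal(sort(fit@details$shiftTips), sort(inst$shiftTips))
  }
})

test_that("stepwise search stops at the one-class model when told to", {
  tr <- toyRichnessTree()
  sw <- stepwiseShiftSearch(tr, deltaAICCut = Inf)
  expect_equal(length(shiftEdges(sw)), 0L)
  expect_equal(sw@nParams, 2L)            # one class, free extinction
  base <- fitFixedRate(tr, eps = "free")
  expect_equal(fitLogL(sw), fitLogL(base), tolerance = 1e-6)
  # and never returns anything worse than the one-class model
  sw4 <- stepwiseShiftSearch(tr, deltaAICCut = 4)
  expect_lte(fitAIC(sw4), fitAIC(base) + 1e-8)
})

test_that("stepwise search finds a strong simulated shift at its stem", {
  inst <- simulateShiftedRichnessTree(nTips = 25, shiftCladeSize = 8,
                                      r1 = 0.05, eps1 = 0, r2 = 0.2,
                                      eps2 = 0.9, seed = 31)
  sw <- stepwiseShiftSearch(inst$tree, deltaAICCut = 4)
  expect_gte(length(shiftEdges(sw)), 1L)
  expect_true(inst$shiftEdge %in% shiftEdges(sw))
  expect_equal(sw@nParams, 2L * (length(shiftEdges(sw)) + 1L) +
                 length(shiftEdges(sw)))
  # the AIC trace is monotone decreasing by at least the cutoff
  expect_true(all(diff(sw@details$trace$AIC) <= -4))
})
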