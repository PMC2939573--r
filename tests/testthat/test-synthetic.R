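test_that("ERM split simulator is uniform, degenerate at n = 2, seeded", {
  sp <- simulateErmSplits(2, 50, seed = 1)
  expect_true(all(sp[, "k"] == 1 & sp[, "n_minus_k"] == 1))
  expect_identical(simulateErmSplits(153, 100, seed = 9),
                   simulateErmSplits(153, 100, seed = 9))
  sp <- simulateErmSplits(20, 40000, seed = 2)
  expect_true(all(sp[, "k"] + sp[, "n_minus_k"] == 20))
  # uniformity: frequency of each split within 3 SE of 1/19
  freq <- tabulate(sp[, "k"], 19) / 40000
  se <- sqrt((1 / 19) * (18 / 19) / 40000)
  expect_true(all(abs(freq - 1 / 19) < 3.5 * se))
})

test_that("conditioned clade sizes follow the geometric law of the likelihood", {
  # dual route: the mechanistic event-level simulator (oracle) must agree
  # with the closed-form law used by both the sampler and the likelihood
  set.seed(3)
  for (eps in c(0, 0.5)) {
    lambda <- 0.1 / (1 - eps)
    sizes <- gillespieCladeSize(20000, 10, lambda, lambda * eps)
    surv <- sizes[sizes > 0]
    beta <- 1 - exp(cladeRichnessLogProb(1, 10, 0.1, eps))
    expect_gt(geometricGofP(surv, beta), 0.01)
    # unconditional mean is e^{rt}
    se <- stats::sd(sizes) / sqrt(length(sizes))
    expect_lt(abs(mean(sizes) - exp(0.1 * 10)), 3 * se)
  }
  # and the package sampler draws from that same law
  draws <- sampleCladeRichness(20000, 10, 0.1, 0.5, seed = 4)
  expect_true(all(draws >= 1))
  beta <- 1 - exp(cladeRichnessLogProb(1, 10, 0.1, 0.5))
  expect_gt(geometricGofP(draws, beta), 0.01)
  expect_identical(sampleCladeRichness(50, 10, 0.1, 0.5, seed = 8),
                   sampleCladeRichness(50, 10, 0.1, 0.5, seed = 8))
})

test_that("synthetic sister tables are valid and respond to rate bias", {
  tab <- generateSisterTable(13, seed = 21)
  expect_s4_class(tab, "SisterPairTable")
  expect_equal(nPairs(tab), 13L)
  one <- generateSisterTable(1, seed = 22)
  expect_equal(nPairs(one), 1L)
  expect_identical(as.data.frame(generateSisterTable(13, seed = 23)),
                   as.data.frame(generateSisterTable(13, seed = 23)))
  # a five-fold rate advantage shifts the log-ratio contrasts upward
  biased <- generateSisterTable(200, rateRatio = 5, seed = 24)
  df <- as.data.frame(biased)
  expect_gt(median(log(df$n_galler / df$n_nongaller)), 0)
  # host ages: ties and zero-age point mass both realized
  expect_gt(sum(df$host_age_galler == df$host_age_nongaller), 0)
  expect_gt(sum(df$host_age_galler == 0), 0)
})

test_that("birth-death tree simulation is seeded, pruned and ultrametric", {
  a <- simulateBDTree(0.15, 0.05, rootAge = 20, seed = 31)
  b <- simulateBDTree(0.15, 0.05, rootAge = 20, seed = 31)
  expect_identical(ape::write.tree(a@fullTree), ape::write.tree(b@fullTree))
  expect_identical(ape::write.tree(a@tree), ape::write.tree(b@tree))
  expect_gte(length(a@extantTips), 2L)
  # reconstructed tree has exactly the extant tips, all at the present
  expect_setequal(a@tree$tip.label, a@extantTips)
  d <- ape::node.depth.edgelength(a@tree)
  tipD <- d[seq_along(a@tree$tip.label)]
  expect_lt(diff(range(tipD)), 1e-8 * max(tipD))
  # lambda = 0: nothing speciates; both root lineages persist
  quiet <- simulateBDTree(0, 0, rootAge = 5, seed = 32)
  expect_equal(length(quiet@extantTips), 2L)
})

test_that("pure-birth tip counts match the Yule expectation", {
  set.seed(33)
  counts <- vapply(seq_len(1200), function(i) {
    length(simulateBDTree(0.1, 0, rootAge = 10,
                          conditionOnSurvival = FALSE)@extantTips)
  }, 0L)
  se <- stats::sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - 2 * exp(1)), 3 * se)
})

test_that("a simulated rate shift marks one clade of extant tips", {
  sim <- simulateBDTree(0.08, 0, rootAge = 30, lambda2 = 0.3,
                        shiftAge = 15, seed = 35)
  expect_true(length(sim@shiftedTips) >= 1)
  expect_true(all(sim@shiftedTips %in% sim@extantTips))
  # shifted tips are monophyletic in the reconstructed tree when both
  # classes are represented
  if (length(sim@shiftedTips) >= 2 &&
      length(sim@shiftedTips) < length(sim@extantTips)) {
    expect_true(ape::is.monophyletic(sim@tree, sim@shiftedTips))
  }
  expect_error(simulateBDTree(0.1, 0, nTipsTarget = 10, lambda2 = 0.2,
                              shiftAge = 5), "root-age stopping rule")
})

test_that("collapsing to a richness tree conserves richness and ages", {
  sim <- simulateBDTree(0.25, 0.05, rootAge = 20, seed = 41)
  nExtant <- length(sim@extantTips)
  rt <- collapseToRichnessTree(sim, 8)
  expect_equal(sum(tipRichness(rt)), nExtant)
  expect_true(all(branchingTimes(rt) >= 8))
  expect_true(all(stemAges(rt) >= 8))
  # collapsing just above the present keeps every tip with richness 1
  eps <- collapseToRichnessTree(sim, 1e-8)
  expect_equal(length(tipRichness(eps)), nExtant)
  expect_true(all(tipRichness(eps) == 1))
  expect_error(collapseToRichnessTree(sim, 50), "between 0 and the root age")
  expect_error(collapseToRichnessTree(sim, 0), "between 0 and the root age")
})

test_that("pectinate builder realizes the prescribed stem ages", {
  tr <- richnessTreeFromStemAges(c(30, 20, 10), c(8, 4, 2, 1))
  expect_equal(rootAge(tr), 30)
  expect_equal(sort(unname(stemAges(tr)), decreasing = TRUE),
               c(30, 20, 10, 10))
  expect_equal(sum(tipRichness(tr)), 15)
  expect_equal(branchingTimes(tr), c(30, 20, 10))
})

test_that("shifted richness instances designate a clean non-root clade", {
  inst <- simulateShiftedRichnessTree(nTips = 20, shiftCladeSize = 6,
                                      seed = 51)
  tr <- inst$tree
  phy <- tr@phy
  expect_equal(rootAge(tr), 100, tolerance = 1e-8)
  expect_true(ape::is.monophyletic(phy, inst$shiftTips))
  # the recorded edge subtends exactly the shifted tips
  expect_equal(phy$edge[inst$shiftEdge, 2L],
               ape::getMRCA(phy, inst$shiftTips))
  # and its parent is not the root (no complement ambiguity)
  expect_false(phy$edge[inst$shiftEdge, 1L] ==
                 length(phy$tip.label) + 1L)
})
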