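test_that("contrast metrics follow their closed forms", {
  expect_equal(contrastValues(150, 3, "logratio"), log(50))
  expect_equal(contrastValues(41, 46, "proportional"), -5 / 87)
  expect_equal(contrastValues(7, 7, "raw"), 0)
  expect_equal(contrastValues(c(2, 3), c(1, 3), "raw"), c(1, 0))
  expect_error(contrastValues(0, 3, "logratio"), "positive")
  expect_error(contrastValues(3, -1, "proportional"), "positive")
})

test_that("sign-permutation test matches hand enumeration on small cases", {
  expect_equal(signPermutationTest(c(1, 2, 3))$p.value, 2 / 8)
  expect_equal(signPermutationTest(c(5, 5))$p.value, 2 / 4)
  expect_equal(signPermutationTest(4)$p.value, 1)   # both signs tie on |sum|
  expect_error(signPermutationTest(c(0, 0)), "non-zero")
})

test_that("sign-permutation test equals the brute-force oracle", {
  set.seed(42)
  for (i in 1:40) {
    m <- sample(1:10, 1)
    x <- sample(c(-9:-1, 1:9), m, replace = TRUE)
    expect_equal(signPermutationTest(x)$p.value, bruteSignPermP(x))
    # two-tailed p is invariant under a global sign flip and reordering
    expect_equal(signPermutationTest(-x)$p.value,
                 signPermutationTest(x)$p.value)
    expect_equal(signPermutationTest(x[sample.int(length(x))])$p.value,
                 signPermutationTest(x)$p.value)
  }
})

test_that("exact signed-rank test matches enumeration, wilcox.test and symmetry", {
  # all-positive m = 5: the two extreme assignments out of 32
  expect_equal(wilcoxonSignedRankExact(c(1, 2, 3, 4, 5))$p.value, 1 / 16)
  # perfectly balanced W+ = W- gives the maximal two-tailed p
  expect_equal(wilcoxonSignedRankExact(c(2, -2, 5, -5))$p.value, 1)
  set.seed(43)
  for (i in 1:25) {
    m <- sample(3:12, 1)
    x <- round(stats::rnorm(m), 2)
    x <- x[x != 0]
    if (length(x) < 2) next
    mine <- wilcoxonSignedRankExact(x)
    expect_equal(mine$p.value, bruteWilcoxP(x))
    if (!any(duplicated(abs(x)))) {  # tie-free: stats must agree exactly
      ref <- suppressWarnings(stats::wilcox.test(x, exact = TRUE))
      expect_equal(unname(mine$statistic), unname(ref$statistic))
      expect_equal(mine$p.value, ref$p.value)
    }
    expect_equal(wilcoxonSignedRankExact(-x)$p.value, mine$p.value)
  }
  # ties: average ranks, enumeration on realized ranks
  xt <- c(3, -3, 3, 1, -2)
  expect_equal(wilcoxonSignedRankExact(xt)$p.value, bruteWilcoxP(xt))
})

test_that("normal approximation is centered and converges to the exact test", {
  # W+ exactly at its null mean: p = 1 by construction
  expect_equal(wilcoxonNormalApprox(c(1, -2, -3, 4))$p.value, 1)
  # all positive at m = 20 is overwhelming evidence
  expect_lt(wilcoxonNormalApprox(1:20)$p.value, 0.001)
  set.seed(44)
  gaps <- replicate(30, {
    x <- stats::rnorm(20)
    abs(wilcoxonNormalApprox(x)$p.value - wilcoxonSignedRankExact(x)$p.value)
  })
  expect_lt(max(gaps), 0.02)
})

test_that("binomial sign test doubles the smaller tail, capped at one", {
  expect_equal(binomialSignTest(7, 13)$p.value, 1)
  expect_equal(binomialSignTest(0, 4)$p.value, 0.125)
  expect_equal(binomialSignTest(1, 1)$p.value, 1)
  expect_equal(binomialSignTest(2, 10)$p.value,
               binomialSignTest(8, 10)$p.value)  # symmetry
  expect_error(binomialSignTest(5, 4))
})

test_that("diversity contrasts dispatch the test by usable sample size", {
  tab <- readSisterTable(table1Path())
  res <- diversityContrastAnalysis(tab, "logratio")
  expect_equal(res@nUsed, 13L)
  expect_equal(testUsed(res), "wilcoxon_exact")
  expect_equal(res@statistic, 50)            # W+ on the log-ratio contrasts
  expect_equal(res@extra$nPositive, 7L)
  # small tables go to the randomization test
  small <- generateSisterTable(8, seed = 5)
  expect_equal(testUsed(diversityContrastAnalysis(small, "logratio")),
               "sign_permutation")
  # large tables go to the normal approximation
  big <- generateSisterTable(24, seed = 6)
  expect_equal(testUsed(diversityContrastAnalysis(big, "logratio")),
               "wilcoxon_normal")
  # a table with identical sisters everywhere has nothing to test
  eq <- data.frame(pair_id = paste0("p", 1:3), galler_name = "g",
                   n_galler = c(2L, 5L, 9L), host_age_galler = 0,
                   nongaller_name = "n", n_nongaller = c(2L, 5L, 9L),
                   host_age_nongaller = 0)
  expect_error(diversityContrastAnalysis(SisterPairTable(eq), "logratio"),
               "non-zero")
})

test_that("contrast tests are invariant to pair order", {
  tab <- as.data.frame(readSisterTable(table1Path()))
  set.seed(9)
  shuf <- SisterPairTable(tab[sample(nrow(tab)), ])
  for (metric in c("logratio", "raw", "proportional")) {
    a <- diversityContrastAnalysis(readSisterTable(table1Path()), metric)
    b <- diversityContrastAnalysis(shuf, metric)
    expect_equal(b@pValue, a@pValue)
    expect_equal(b@statistic, a@statistic)
  }
})

test_that("host-specificity test: direction, exact p and printed flag", {
  tab <- readSisterTable(table1Path())
  host <- hostSpecificityTest(tab)
  expect_equal(host@tails, "one")
  expect_equal(host@extra$nNonzero, 6L)
  expect_equal(host@extra$nFavorGaller, 6L)  # every difference favors gallers
  # all six positive: one-tailed exact p is (1/2)^6 under drop-zeros
  expect_equal(pValue(host), 2^-6)
  expect_equal(pValue(host), bruteWilcoxP(host@contrasts, "greater"))
  expect_false(host@extra$matchesPrinted)    # printed reference is 0.050
  # a single positive difference can only reach p = 0.5
  one <- SisterPairTable(data.frame(
    pair_id = "p1", galler_name = "g", n_galler = 2, host_age_galler = 10,
    nongaller_name = "n", n_nongaller = 3, host_age_nongaller = 30))
  expect_equal(pValue(hostSpecificityTest(one)), 0.5)
  # no resolvable differences at all is an error
  zero <- SisterPairTable(data.frame(
    pair_id = "p1", galler_name = "g", n_galler = 2, host_age_galler = 10,
    nongaller_name = "n", n_nongaller = 3, host_age_nongaller = 10))
  expect_error(hostSpecificityTest(zero), "non-zero")
})

test_that("Pratt zero-inclusion ranks zeros but fixes their signed rank at 0", {
  tab <- readSisterTable(table1Path())
  drop <- hostSpecificityTest(tab, "drop")
  pratt <- hostSpecificityTest(tab, "pratt")
  expect_gt(pratt@statistic, drop@statistic)  # zeros push non-zero ranks up
  expect_true(pratt@pValue > 0 && pratt@pValue <= 1)
  expect_equal(pratt@extra$nFavorGaller, drop@extra$nFavorGaller)
})

test_that("log-ratio test holds its size under the equal-rates null", {
  set.seed(20)
  rejections <- vapply(seq_len(1000), function(i) {
    tab <- generateSisterTable(13, rateRatio = 1)
    diversityContrastAnalysis(tab, "logratio")@pValue < 0.05
  }, NA)
  expect_lte(mean(rejections), 0.06)
})
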