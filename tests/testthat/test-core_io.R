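test_that("packaged comparison table reads with verbatim counts and ages", {
  tab <- readSisterTable(table1Path())
  expect_s4_class(tab, "SisterPairTable")
  expect_equal(nPairs(tab), 13L)
  df <- as.data.frame(tab)
  # row order preserved: the sawfly pair comes first
  expect_equal(df$pair_id[1], "Euurina")
  expect_equal(df$n_galler[1], 400L)
  expect_equal(df$n_nongaller[1], 25L)
  apio <- getPair(tab, "Apiomorpha")
  expect_equal(apio$n_galler, 150L)
  expect_equal(apio$n_nongaller, 3L)
  expect_equal(apio$host_age_galler, 65)
  # the asterisked host age is stored as its value plus a footnote flag
  micro <- getPair(tab, "Micronematus")
  expect_equal(micro$host_age_galler, 70)
  expect_equal(micro$age_note, "*")
})

test_that("table validation names the offending row and field", {
  good <- data.frame(pair_id = "p1", galler_name = "g", n_galler = 5,
                     host_age_galler = 1, nongaller_name = "n",
                     n_nongaller = 2, host_age_nongaller = 3,
                     stringsAsFactors = FALSE)
  bad <- good
  bad$n_galler <- 0
  expect_error(SisterPairTable(bad), "row 1, field 'n_galler'")
  bad <- good
  bad$n_nongaller <- 2.5
  expect_error(SisterPairTable(bad), "row 1, field 'n_nongaller'")
  bad <- good
  bad$host_age_galler <- -1
  expect_error(SisterPairTable(bad), "row 1, field 'host_age_galler'")
  expect_error(SisterPairTable(good[, -3]), "missing column")
  expect_error(SisterPairTable(rbind(good, good)), "duplicated pair_id")
  expect_error(SisterPairTable(good[0, ]), "at least one pair")
})

test_that("sister tables round-trip through CSV unchanged", {
  tab <- readSisterTable(table1Path())
  f <- withr::local_tempfile(fileext = ".csv")
  writeSisterTable(tab, f)
  back <- readSisterTable(f)
  expect_equal(as.data.frame(back), as.data.frame(tab))
})

test_that("richness trees read with stem ages taken off branch lengths", {
  tr <- readRichnessTree("((A:1,B:1):1,C:2);", c(A = 1, B = 1, C = 1))
  expect_equal(rootAge(tr), 2)
  expect_equal(stemAges(tr), c(A = 1, B = 1, C = 2))
  expect_equal(unname(tipRichness(tr)), c(1, 1, 1))
  # richness map must cover every tip, and only tips
  expect_error(readRichnessTree("((A:1,B:1):1,C:2);", c(A = 1, B = 1)),
               "missing from the richness map: C")
  expect_error(readRichnessTree("((A:1,B:1):1,C:2);",
                                c(A = 1, B = 1, C = 1, D = 2)),
               "absent from the tree: D")
  # ultrametricity violations report the deviation
  expect_error(readRichnessTree("((A:1,B:1.5):1,C:2);",
                                c(A = 1, B = 1, C = 1)),
               "not ultrametric.*0\\.5")
})

test_that("label|count encoding is an accepted richness carrier", {
  tr <- readRichnessTree("((A|4:1,B|1:1):1,C|10:2);")
  expect_equal(tipRichness(tr), c(A = 4, B = 1, C = 10))
  f <- withr::local_tempfile(fileext = ".nwk")
  writeRichnessTree(tr, f)  # label|count round trip
  back <- readRichnessTree(f)
  expect_equal(tipRichness(back), tipRichness(tr))
  expect_equal(stemAges(back), stemAges(tr))
  # sidecar CSV round trip is value-identical too
  f2 <- withr::local_tempfile(fileext = ".nwk")
  f3 <- withr::local_tempfile(fileext = ".csv")
  writeRichnessTree(tr, f2, f3)
  back2 <- readRichnessTree(f2, f3)
  expect_equal(tipRichness(back2), tipRichness(tr))
  expect_equal(branchingTimes(back2), branchingTimes(tr))
})

test_that("polytomies are permitted and flagged", {
  expect_message(
    tr <- readRichnessTree("((A:1,B:1,C:1):1,D:2);",
                           c(A = 1, B = 2, C = 3, D = 1)),
    "polytomies")
  expect_equal(rootAge(tr), 2)
})

test_that("root-height scaling is linear, idempotent and composes", {
  tr <- readRichnessTree("((A:1,B:1):1,C:2);", c(A = 2, B = 1, C = 7))
  s <- scaleRootHeight(tr, 100)
  expect_equal(rootAge(s), 100)
  expect_equal(stemAges(s), c(A = 50, B = 50, C = 100))  # all lengths x50
  expect_equal(tipRichness(s), tipRichness(tr))
  # identity at the current root age
  same <- scaleRootHeight(tr, rootAge(tr))
  expect_equal(stemAges(same), stemAges(tr))
  # a tip stem age of 10 on a root of 50 becomes 20 at root 100
  tr50 <- readRichnessTree("((A:10,B:10):40,C:50);", c(A = 1, B = 1, C = 1))
  expect_equal(unname(stemAges(scaleRootHeight(tr50, 100))["A"]), 20)
  # idempotence and multiplicative composition
  expect_equal(stemAges(scaleRootHeight(s, 100)), stemAges(s))
  expect_equal(stemAges(scaleRootHeight(scaleRootHeight(tr, 10), 100)),
               stemAges(scaleRootHeight(tr, 100)))
  expect_error(scaleRootHeight(tr, -1))
})

test_that("branching times are descending node ages with the root first", {
  tr <- readRichnessTree("((A:1,B:1):1,C:2);", c(A = 1, B = 1, C = 1))
  expect_equal(branchingTimes(tr), c(2, 1))
  bal <- readRichnessTree("((A:1,B:1):2,(C:1,D:1):2);",
                          c(A = 1, B = 1, C = 1, D = 1))
  expect_equal(branchingTimes(bal), c(3, 1, 1))
  # n - 1 entries on a binary tree, max equals the root age; scaling scales
  set.seed(7)
  for (i in 1:5) {
    sim <- simulateBDTree(0.4, 0, rootAge = 8)
    rt <- RichnessTree(sim@tree,
                       stats::setNames(rep(1, length(sim@tree$tip.label)),
                                       sim@tree$tip.label))
    bt <- branchingTimes(rt)
    expect_length(bt, length(tipRichness(rt)) - 1L)
    expect_equal(max(bt), rootAge(rt))
    expect_equal(branchingTimes(scaleRootHeight(rt, 100)),
                 bt * 100 / rootAge(rt))
  }
})
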