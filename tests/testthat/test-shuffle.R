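test_that("site extraction: degeneracy, allowed sets and 3-1 context", {
  s0 <- extractSites(codingSequence("ATGTGG"))  # Met, Trp
  expect_false(any(s0$degenerate))

  s1 <- extractSites(codingSequence("TTTAAA"))  # Phe, Lys
  expect_equal(s1$allowedThird, c("CT", "AG"))
  expect_equal(s1$n1Next, c("A", NA))

  # 6-fold split: CTG is Leu CUN (4-fold), AGT is Ser AGY (2-fold)
  s2 <- extractSites(codingSequence("CTGAGT"))
  expect_equal(s2$familyId, c("L4", "S2"))
  expect_equal(s2$allowedThird, c("ACGT", "CT"))
})

test_that("fully constrained pools shuffle to the identity", {
  x <- codingSequence("TTTAAA")  # pool {T, A}: T only fits Phe, A only Lys
  set.seed(410)
  for (i in 1:20)
    for (m in c("N3", "DN23", "DN31", "DN231"))
      expect_equal(codons(shuffleSynonymous(x, m)), codons(x))
})

test_that("every mode preserves the protein and its conservation contract", {
  set.seed(411)
  for (i in 1:60) {
    x <- randomTestCds(sample(20:120, 1))
    for (m in c("N3", "GC3", "DN23", "DN31", "DN231")) {
      y <- suppressWarnings(shuffleSynonymous(x, m))
      chk <- conservationChecks(x, y)
      expect_true(chk$aa, label = paste(m, "protein"))
      expect_true(chk$p12, label = paste(m, "positions 1-2"))
      expect_true(chk$gc3, label = paste(m, "GC3 within 1"))
      if (m %in% c("N3", "DN23", "DN31", "DN231"))
        expect_true(chk$n3, label = paste(m, "third-position counts"))
      if (m %in% c("DN23", "DN231"))
        expect_true(chk$d23, label = paste(m, "2-3 dinucleotides"))
      if (m %in% c("DN31", "DN231"))
        expect_true(chk$d31, label = paste(m, "3-1 dinucleotides"))
    }
  }
})

test_that("N3 pool redistribution and randomize comparison mode keep contracts", {
  set.seed(412)
  for (i in 1:15) {
    x <- randomTestCds(60)
    y <- shuffleSynonymous(x, "N3", method = "pool")
    chk <- conservationChecks(x, y)
    expect_true(chk$aa && chk$n3)
    z <- shuffleSynonymous(x, "N3", method = "randomize")
    expect_equal(aaSequence(z), aaSequence(x))  # counts only in expectation
  }
  expect_error(shuffleSynonymous(randomTestCds(10), "DN23", method = "pool"),
               "only available")
})

test_that("the spec'd two-Thr toy visits both DN23 arrangements equally", {
  toy <- codingSequence("ACAACG")
  set.seed(413)
  draws <- vapply(1:2000, function(i)
    paste(codons(shuffleSynonymous(toy, "DN23")), collapse = ""),
    character(1))
  p <- mean(draws == "ACAACG")
  expect_setequal(unique(draws), c("ACAACG", "ACGACA"))
  expect_lt(abs(p - 0.5), 0.05)
})

test_that("swap engine is uniform over enumerable feasible arrangements", {
  # Y,Y,R,R,N,N sites with pool {T,C,A,G,A,C}; 18 feasible arrangements.
  # A longer mixing length than the replicate-engine default is used so the
  # chain reaches its stationary (uniform) law before sampling.
  toy <- codingSequence("TTTTTCAAAAAGGGAGGC")
  keys <- enumerateArrangements(toy)
  expect_length(keys, 18L)
  set.seed(414)
  draws <- vapply(1:10000, function(i)
    degenerateThirds(shuffleSynonymous(toy, "N3", swapSweeps = 60)),
    character(1))
  tab <- table(factor(draws, levels = keys))
  expect_true(all(tab > 0))
  expect_gt(stats::chisq.test(tab)$p.value, 0.01)
})

test_that("infeasible GC3 rebalancing returns the identity with a warning", {
  x <- codingSequence("AAAAAAAAA")  # Lys only: pool {A,A,A}, no T possible
  expect_warning(y <- shuffleSynonymous(x, "GC3"), "infeasible")
  expect_equal(codons(y), codons(x))
})

test_that("replicate engine: degenerate cases and reproducibility", {
  # only Met/Trp: no degenerate family, ENC undefined
  mw <- codingSequence("ATGTGGATGTGG")
  expect_error(runShuffleReplicates(mw, shuffleSpec("N3", replicates = 5)),
               "undefined-ENC")

  # exactly one feasible arrangement: sd 0, mean = original
  forced <- codingSequence("TTTTTTATTATTGTTGTTCTTCTT")
  rs <- runShuffleReplicates(forced, shuffleSpec("N3", replicates = 30,
                                                 seed = 5))
  expect_equal(rs@encSd, 0)
  expect_equal(rs@encMean, rs@encOriginal)
  expect_false(isSignificant(rs@call))

  set.seed(415)
  x <- randomTestCds(80)
  a <- runShuffleReplicates(x, shuffleSpec("DN23", replicates = 40, seed = 9))
  b <- runShuffleReplicates(x, shuffleSpec("DN23", replicates = 40, seed = 9))
  expect_identical(a@encMean, b@encMean)
  expect_identical(a@encSd, b@encSd)
  expect_true(a@encMean >= min(40, a@encMean) &&
              a@encSd >= 0)
})

test_that("replicate summary keeps per-replicate values when asked", {
  set.seed(416)
  x <- randomTestCds(60)
  rs <- runShuffleReplicates(x, shuffleSpec("N3", replicates = 25, seed = 3,
                                            keepReplicates = TRUE))
  expect_length(rs@encValues, 25L)
  expect_equal(mean(rs@encValues), rs@encMean)
  expect_true(rs@encMean >= min(rs@encValues) &&
              rs@encMean <= max(rs@encValues))
})
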