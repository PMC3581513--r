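test_that("third-position frequency sampling: simplex membership and strategies", {
  set.seed(417)
  for (i in 1:50) {
    f <- freqs(sampleThirdPositionFrequencies("extreme"))
    expect_equal(sum(f), 1, tolerance = 1e-9)
    expect_true(all(f >= 0))
  }
  fx <- sampleThirdPositionFrequencies("fixed",
                                       fixed = c(0.1, 0.2, 0.3, 0.4))
  expect_equal(unname(freqs(fx)), c(0.1, 0.2, 0.3, 0.4))
  expect_error(sampleThirdPositionFrequencies("dirichlet", alpha = 0),
               "domain error")
  expect_error(simulationSpec(alpha = -1), "domain error")
})

test_that("the extreme sampler covers both near-vertex and balanced draws", {
  set.seed(418)
  mx <- vapply(1:1000, function(i)
    max(freqs(sampleThirdPositionFrequencies("extreme"))), numeric(1))
  expect_gte(mean(mx > 0.9), 0.05)
  expect_gte(mean(mx < 0.5), 0.05)
})

test_that("generated sequences are valid, sized and composition-faithful", {
  set.seed(419)
  x <- generateRandomCds(3334, c(A = .25, C = .25, G = .25, T = .25))
  expect_equal(nchar(ntSequence(x)), 10002L)
  # revalidation proves frame-correctness and absence of stops
  expect_equal(aaSequence(codingSequence(ntSequence(x))), aaSequence(x))

  # one-hot T: pyrimidine and 4-fold families always end in T; purine-only
  # families (Lys, Gln, Glu) fall back to uniform over {A, G}
  suppressMessages(y <- generateRandomCds(500, c(A = 0, C = 0, G = 0, T = 1),
                                          id = "oneT"))
  s <- extractSites(y)
  tOk <- grepl("T", s$allowedThird)
  expect_true(all(s$n3[s$degenerate & tOk] == "T"))
  expect_true(all(s$n3[s$degenerate & !tOk] %in% c("A", "G")))
})

test_that("target third-position frequencies are recovered at 4-fold sites", {
  set.seed(420)
  tf <- c(A = .4, C = .3, G = .2, T = .1)
  x <- generateRandomCds(10000, tf)
  s <- extractSites(x)
  four <- s$allowedThird == "ACGT"
  realized <- table(factor(s$n3[four], levels = NUC4)) / sum(four)
  expect_true(all(abs(as.numeric(realized) - tf) < 0.02))
})

test_that("panels are reproducible from the seed and span deep bias", {
  spec <- simulationSpec(nSequences = 8, nCodons = 120, seed = 21)
  p1 <- generatePanel(spec)
  p2 <- generatePanel(spec)
  expect_identical(vapply(p1, ntSequence, character(1)),
                   vapply(p2, ntSequence, character(1)))
  expect_identical(attr(p1, "targets"), attr(p2, "targets"))
  expect_length(p1, 8L)
  expect_true(all(vapply(p1, codonCount, integer(1)) == 120L))
})

test_that("ENC falls with the variance of the generating composition, not raw GC3", {
  set.seed(421)
  panel <- generatePanel(simulationSpec(nSequences = 200, nCodons = 500,
                                        seed = 422))
  tg <- attr(panel, "targets")
  encs <- vapply(panel, function(x)
    tryCatch(encValue(effectiveNumberOfCodons(x)),
             error = function(e) NA_real_), numeric(1))
  ok <- !is.na(encs)
  expect_gt(mean(ok), 0.9)
  v3 <- apply(tg, 1, function(f)
    compositionVariance(frequencyVector(f, NUC4)))
  gc3 <- tg[, "C"] + tg[, "G"]
  expect_lt(cor(encs[ok], v3[ok], method = "spearman"), -0.9)
  expect_lt(abs(cor(encs[ok], gc3[ok], method = "spearman")), 0.5)
  expect_lt(min(encs, na.rm = TRUE), 35)  # deep bias is reached
})

test_that("planted 2-3 dinucleotide penalties suppress the targeted codons", {
  set.seed(423)
  x <- generateRandomCds(2000, c(A = .25, C = .25, G = .25, T = .25),
                         pairBias23 = c(CG = 0.05))
  r <- rdbValues(relativeDinucleotideBias(x, "23"))
  expect_lt(r[["CG"]], 0.4)
  r31 <- rdbValues(relativeDinucleotideBias(x, "31"))
  expect_gt(r31[["CG"]], 0.6)  # the 3-1 pair is untouched by the penalty
})
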