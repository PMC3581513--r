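test_that("ENC anchors: one codon per amino acid gives 20, equal use of 61 gives 61", {
  e20 <- effectiveNumberOfCodons(oneCodonPerAaCds())
  expect_equal(encValue(e20), 20)
  expect_true(all(abs(encFamilyHomozygosity(e20)[
    !is.na(encFamilyHomozygosity(e20))] - 1) < 1e-12))

  e61 <- effectiveNumberOfCodons(allCodonsEqualCds(100),
                                 estimator = "frequency")
  expect_equal(encValue(e61), 61)
  expect_false(e61@capped)

  # the corrected estimator inflates small-sample homozygosity above the
  # frequency form, so the same sequence hits the 61 cap
  ec <- effectiveNumberOfCodons(allCodonsEqualCds(100))
  expect_true(ec@capped)
  expect_equal(encValue(ec), 61)
})

test_that("Wright's corrected homozygosity on the Phe toy and missing classes", {
  # TTT:3, TTC:1 -> F-hat = (4 * 0.625 - 1) / 3 = 0.5
  counts <- setNames(rep(8, 61), senseCodons())
  counts["TTT"] <- 3; counts["TTC"] <- 1
  e <- encFromCounts(counts)
  expect_equal(unname(encFamilyHomozygosity(e)["F"]), 0.5)

  # a sequence with only 2-fold information has no computable 4/6 classes
  expect_error(encFromCounts(c(TTT = 3, TTC = 1)), "undefined-ENC")

  # absent Ile is interpolated from the 2- and 4-fold class means
  noIle <- counts
  noIle[c("ATT", "ATC", "ATA")] <- 0
  e2 <- encFromCounts(noIle)
  cm <- encClassMeans(e2)
  expect_equal(cm[["3"]], (cm[["2"]] + cm[["4"]]) / 2)
})

test_that("ENC matches an independent brute-force evaluation on random tables", {
  set.seed(407)
  for (i in 1:60) {
    counts <- setNames(rpois(61, lambda = sample(c(2, 5, 20), 1)) +
                         (runif(61) < 0.8), senseCodons())
    oracle <- bruteEnc(counts)
    if (is.na(oracle)) {
      expect_error(encFromCounts(counts), "undefined-ENC")
    } else {
      expect_equal(encValue(encFromCounts(counts)), oracle,
                   tolerance = 1e-9)
    }
  }
})

test_that("ENC decreases as a single 2-fold family grows more biased", {
  base <- setNames(rep(10, 61), senseCodons())
  encs <- vapply(list(c(50, 50), c(60, 40), c(75, 25), c(90, 10), c(100, 0)),
                 function(s) {
                   b <- base; b["TTT"] <- s[1]; b["TTC"] <- s[2]
                   encFromCounts(b, estimator = "frequency")@encRaw
                 }, numeric(1))
  expect_true(all(diff(encs) <= 1e-12))
})

test_that("ENC of long unbiased sequences approaches 61", {
  set.seed(408)
  x <- codingSequence(paste(sample(senseCodons(), 10000, replace = TRUE),
                            collapse = ""))
  e <- effectiveNumberOfCodons(x)
  expect_lt(abs(e@encRaw - 61), 0.5)
})

test_that("Wright's expected-ENC curve: closed-form values and domain", {
  expect_equal(wrightExpectedEnc(0.5), 60.5)
  expect_equal(wrightExpectedEnc(0), 31.0)
  expect_error(wrightExpectedEnc(-0.1), "domain error")
  expect_error(wrightExpectedEnc(1.2), "domain error")
})

test_that("simulated G=C, A=T sequences track the Wright curve as an envelope", {
  # Wright's closed form is approximate; composition-driven sequences may
  # exceed it by a small margin but never substantially
  set.seed(409)
  for (gc in c(0.1, 0.3, 0.5, 0.7, 0.9)) {
    tf <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    z <- generateRandomCds(3334, tf)
    e <- encValue(effectiveNumberOfCodons(z, estimator = "frequency"))
    expect_lt(e, wrightExpectedEnc(gc3Content(z)) + 2)
  }
})

test_that("ENC-difference significance uses a strict threshold of 1", {
  call <- classifyEncDifference(50.0, 53.5)
  expect_equal(encDelta(call), 3.5)
  expect_true(isSignificant(call))
  expect_false(isSignificant(classifyEncDifference(50, 50.5)))
  expect_false(isSignificant(classifyEncDifference(50, 51)))   # exactly 1
  expect_true(isSignificant(classifyEncDifference(50, 48.95)))
  expect_error(classifyEncDifference(10, 50), "must lie in")
})
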