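test_that("positional nucleotide frequencies match direct counts", {
  x <- codingSequence("ATGAAA")
  expect_equal(freqs(positionalNucleotideFreqs(x, 3)),
               c(A = 0.5, C = 0, G = 0.5, T = 0))
  set.seed(402)
  for (i in 1:10) {
    y <- randomTestCds(sample(3:60, 1))
    for (p in 1:3)
      expect_equal(sum(freqs(positionalNucleotideFreqs(y, p))), 1)
  }
})

test_that("dinucleotide frequencies at pairs 23 and 31, with hand enumeration", {
  x <- codingSequence("ACGACGAGAAGA")  # ACG ACG AGA AGA
  f23 <- freqs(positionalDinucleotideFreqs(x, "23"))
  expect_equal(unname(f23[c("CG", "GA")]), c(0.5, 0.5))
  expect_equal(sum(f23), 1)
  # junctions: G|A, G|A, A|A over 3 boundaries (last codon contributes none)
  f31 <- freqs(positionalDinucleotideFreqs(x, "31"))
  expect_equal(unname(f31[c("GA", "AA")]), c(2 / 3, 1 / 3))
  expect_equal(sum(f31), 1)

  expect_error(positionalDinucleotideFreqs(codingSequence("ATG"), "31"),
               "empty-input")
})

test_that("dinucleotide tables equal a brute-force offset scan of the raw nt", {
  set.seed(403)
  for (i in 1:40) {
    x <- randomTestCds(sample(2:50, 1))
    for (pair in c("23", "31"))
      expect_equal(unname(freqs(positionalDinucleotideFreqs(x, pair))),
                   bruteDinucFreqs(ntSequence(x), pair), tolerance = 1e-12)
  }
})

test_that("relative dinucleotide bias: hand-derived values and identity", {
  # ACG TCG ACA TCA: CG observed 0.5; f(C2) = 1, f(G3) = 0.5 -> RDB 1
  x <- codingSequence("ACGTCGACATCA")
  expect_equal(rdbValues(relativeDinucleotideBias(x, "23"))[["CG"]], 1.0)
  # ACG ACG AGA AGA: 0.5 / (0.5 * 0.5) = 2
  y <- codingSequence("ACGACGAGAAGA")
  expect_equal(rdbValues(relativeDinucleotideBias(y, "23"))[["CG"]], 2.0)

  set.seed(404)
  for (i in 1:10) {
    z <- randomTestCds(sample(5:60, 1))
    for (pair in c("23", "31")) {
      tab <- relativeDinucleotideBias(z, pair)
      ok <- !is.na(rdbValues(tab))
      expect_equal(rdbValues(tab)[ok] * rdbExpected(tab)[ok],
                   rdbObserved(tab)[ok], tolerance = 1e-12)
      # undefined entries are NA, never zero-filled
      expect_true(all(is.na(rdbValues(tab)[rdbExpected(tab) == 0])))
    }
  }
})

test_that("RDB of long i.i.d.-random sequences approaches 1 everywhere", {
  set.seed(405)
  x <- codingSequence(paste(sample(senseCodons(), 20000, replace = TRUE),
                            collapse = ""))
  for (pair in c("23", "31")) {
    r <- rdbValues(relativeDinucleotideBias(x, pair))
    expect_true(all(abs(r[!is.na(r)] - 1) < 0.2))
  }
})

test_that("composition variance: direct values, zero iff uniform, permutation-invariant", {
  expect_equal(compositionVariance(frequencyVector(rep(0.25, 4), NUC4)), 0)
  expect_equal(compositionVariance(frequencyVector(c(GC = 0.6, AT = 0.4))),
               0.01)
  # one-hot with n = 4 attains the simplex maximum
  oneHot <- frequencyVector(c(1, 0, 0, 0), NUC4)
  expect_equal(compositionVariance(oneHot), 0.1875)
  set.seed(406)
  grid <- t(apply(matrix(rgamma(400, 1), ncol = 4), 1, function(g) g / sum(g)))
  vars <- apply(grid, 1, function(v)
    compositionVariance(frequencyVector(v, NUC4)))
  expect_true(all(vars <= 0.1875 + 1e-12))
  expect_true(all(vars[rowSums(abs(grid - 0.25)) > 1e-9] > 0))
  # permutation invariance
  v <- c(0.5, 0.3, 0.15, 0.05)
  expect_equal(compositionVariance(frequencyVector(v, NUC4)),
               compositionVariance(frequencyVector(rev(v), NUC4)))
})
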