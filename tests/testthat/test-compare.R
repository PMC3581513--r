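# codons chosen so that no CpG occurs at pair 2-3 or 3-1 while both
# expectations stay positive: RDB(CpG) is exactly 0 at both pairs
cpgFreeCds <- function(order, id) {
  codingSequence(paste(order, collapse = ""), id = id)
}

test_that("identical per-sequence RDB at both pairs gives p = 1, zero difference", {
  base <- c("GCA", "TCC", "AGG", "AAA")
  xs <- list(cpgFreeCds(base, "a"),
             cpgFreeCds(base[c(1, 3, 2, 4)], "b"),
             cpgFreeCds(base[c(4, 1, 2, 3)], "c"))
  # per sequence both RDBs are 0 -> the two groups coincide
  for (x in xs) {
    expect_equal(rdbValues(relativeDinucleotideBias(x, "23"))[["CG"]], 0)
    expect_equal(rdbValues(relativeDinucleotideBias(x, "31"))[["CG"]], 0)
  }
  cmp <- cpgPositionalComparison(xs)
  expect_equal(comparisonPValue(cmp), 1)
  expect_equal(unname(diff(comparisonMeans(cmp))), 0)
})

test_that("a planted 2-3-only CpG depletion is detected at n = 50", {
  set.seed(426)
  xs <- lapply(1:50, function(i)
    generateRandomCds(300, c(A = .25, C = .25, G = .25, T = .25),
                      pairBias23 = c(CG = 0.1), id = paste0("d", i)))
  cmp <- cpgPositionalComparison(xs)
  expect_lt(cmp@meanA, cmp@meanB)
  expect_lt(comparisonPValue(cmp), 0.01)
  # Welch variant stays in range and agrees qualitatively
  cmpW <- cpgPositionalComparison(xs, welch = TRUE)
  expect_lt(comparisonPValue(cmpW), 0.01)
})

test_that("amino-acid preference: direct ratio and planted correlation", {
  x <- codingSequence("ATTCTT")
  res <- aminoAcidPreferenceAnalysis(list(
    x, codingSequence("ATTATTCTT"), codingSequence("ATTCTTCTT")))
  expect_equal(res$table$ileLeu, c(1, 2, 0.5))

  # sweep third-position A content and tie the Ile-vs-Leu odds to it
  set.seed(427)
  aSweep <- seq(0.1, 0.7, length.out = 40)
  xs <- lapply(seq_along(aSweep), function(i) {
    a <- aSweep[i]
    tf <- c(A = a, C = (1 - a) / 3, G = (1 - a) / 3, T = (1 - a) / 3)
    aaP <- setNames(rep(1, 20), names(geneticCodeFamilies(
      standardGeneticCode(), "enc")))
    aaP["I"] <- 4 * a; aaP["L"] <- 4 * (1 - a)
    generateRandomCds(400, tf, aaDistribution = aaP / sum(aaP),
                      id = paste0("sw", i))
  })
  res <- aminoAcidPreferenceAnalysis(xs)
  rho <- res$correlations
  expect_gt(rho$rho[rho$pair == "ileLeu vs a3"], 0.8)
  expect_lt(rho$p[rho$pair == "ileLeu vs a3"], 1e-4)
})

test_that("sequences without leucine are excluded and small n errors out", {
  noLeu <- codingSequence("ATGAAAGGG")
  expect_message(
    expect_error(aminoAcidPreferenceAnalysis(list(noLeu, noLeu, noLeu)),
                 "correlation undefined"),
    "without leucine")
})
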