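#' Two-group comparison result
#'
#' Holds the per-sequence statistics of two groups, their means and standard
#' errors, and the p-value of a two-sample Student's t-test (equal-variance
#' by default, matching the classical two-sample form; Welch available).
#'
#' @slot statsA,statsB per-sequence statistic in each group.
#' @slot meanA,meanB,semA,semB group means and standard errors of the mean.
#' @slot pValue two-sided t-test p-value.
#' @slot rho optional rank-correlation coefficient (NA when not applicable).
#' @slot dropped number of sequences dropped (undefined statistic).
#' @slot label what was compared.
#' @export
setClass("ComparisonResult", representation(
  statsA = "numeric", statsB = "numeric",
  meanA = "numeric", meanB = "numeric", semA = "numeric", semB = "numeric",
  pValue = "numeric", rho = "numeric", dropped = "integer",
  label = "character"
))

setValidity("ComparisonResult", function(object) {
  if (!is.na(object@pValue) &&
      (object@pValue < 0 || object@pValue > 1))
    return("p-value must lie in [0, 1]")
  TRUE
})

#' @rdname ComparisonResult-class
#' @param object a \code{ComparisonResult}.
#' @export
comparisonPValue <- function(object) object@pValue

#' @rdname ComparisonResult-class
#' @export
comparisonMeans <- function(object) c(A = object@meanA, B = object@meanB)

setMethod("show", "ComparisonResult", function(object) {
  cat("ComparisonResult:", object@label, "\n")
  cat(sprintf("  group A: mean %.4f (sem %.4f, n %d)\n",
              object@meanA, object@semA, length(object@statsA)))
  cat(sprintf("  group B: mean %.4f (sem %.4f, n %d)\n",
              object@meanB, object@semB, length(object@statsB)))
  cat(sprintf("  t-test p = %.4g", object@pValue))
  if (object@dropped > 0L) cat("  [", object@dropped, "dropped ]")
  cat("\n")
})

.sem <- function(x) sd(x) / sqrt(length(x))

#' Positional CpG bias comparison across a dataset
#'
#' For every sequence the relative CpG dinucleotide bias (observed/expected)
#' is computed at codon-position pairs 2-3 and 3-1; the two sets are compared
#' with a two-sided two-sample Student's t-test. A CpG deficit specific to
#' positions 2-3 is the signature of dinucleotide pressure acting on
#' synonymous codon choice rather than uniformly on the genome.
#'
#' @param cdsList list of [CodingSequence-class] (>= 2).
#' @param welch use the unequal-variance (Welch) t-test.
#' @return a [ComparisonResult-class]: group A = RDB(CpG, 2-3), group B =
#'   RDB(CpG, 3-1).
#' @export
cpgPositionalComparison <- function(cdsList, welch = FALSE) {
  if (length(cdsList) < 2L)
    stop("need at least 2 sequences")
  a <- vapply(cdsList, function(x)
    rdbValues(relativeDinucleotideBias(x, "23"))[["CG"]], numeric(1))
  b <- vapply(cdsList, function(x)
    rdbValues(relativeDinucleotideBias(x, "31"))[["CG"]], numeric(1))
  keep <- !is.na(a) & !is.na(b)
  dropped <- sum(!keep)
  if (dropped > 0L)
    message("dropped ", dropped, " sequence(s) with undefined CpG RDB")
  a <- a[keep]; b <- b[keep]
  if (length(a) < 2L) stop("fewer than 2 sequences with defined CpG RDB")
  p <- if (all(a == b) || (sd(a) == 0 && sd(b) == 0 && mean(a) == mean(b)))
    1 else t.test(a, b, var.equal = !welch)$p.value
  new("ComparisonResult", statsA = a, statsB = b,
      meanA = mean(a), meanB = mean(b), semA = .sem(a), semB = .sem(b),
      pValue = p, rho = NA_real_, dropped = as.integer(dropped),
      label = "CpG RDB at codon positions 2-3 (A) vs 3-1 (B)")
}

.aaCount <- function(cds, aa) {
  v <- strsplit(aaSequence(cds), "")[[1]]
  sum(v %in% aa)
}

#' Amino-acid preference vs nucleotide content analysis
#'
#' Tests whether genomic nucleotide content reaches through the genetic code
#' into the encoded protein: the ratio of isoleucine (ATH codons) to leucine
#' (CTN and TTR codons) should track third-position A content, valine (GTN)
#' to leucine should track third-position G, while the arginine (CGN, AGR) to
#' glycine (GGN) ratio is a negative control for G content; C content at the
#' (mostly non-synonymous) positions 1+2 is compared with C at position 3.
#' Spearman rank correlations (average ranks for ties) are computed across
#' the dataset. Sequences without leucine are excluded (with a message);
#' ratios with a zero denominator are dropped pairwise.
#'
#' @param cdsList list of [CodingSequence-class] (>= 3 usable sequences).
#' @return list with \code{table} (per-sequence statistics) and
#'   \code{correlations} (data.frame: pair, rho, p, n).
#' @export
aminoAcidPreferenceAnalysis <- function(cdsList) {
  hasLeu <- vapply(cdsList, function(x) .aaCount(x, "L") > 0, logical(1))
  if (any(!hasLeu))
    message("excluded ", sum(!hasLeu), " sequence(s) without leucine")
  cdsList <- cdsList[hasLeu]
  if (length(cdsList) < 3L)
    stop("correlation undefined: fewer than 3 usable sequences")

  tab <- do.call(rbind, lapply(cdsList, function(x) {
    f3 <- freqs(positionalNucleotideFreqs(x, 3))
    f1 <- freqs(positionalNucleotideFreqs(x, 1))
    f2 <- freqs(positionalNucleotideFreqs(x, 2))
    nL <- .aaCount(x, "L"); nG <- .aaCount(x, "G")
    data.frame(
      id = seqId(x),
      ileLeu = .aaCount(x, "I") / nL,
      valLeu = .aaCount(x, "V") / nL,
      argGly = if (nG > 0) .aaCount(x, "R") / nG else NA_real_,
      a3 = unname(f3[["A"]]), g3 = unname(f3[["G"]]),
      c3 = unname(f3[["C"]]),
      c12 = unname((f1[["C"]] + f2[["C"]]) / 2))
  }))

  pairs <- list(
    c("ileLeu", "a3"), c("valLeu", "g3"), c("argGly", "g3"),
    c("c12", "c3"))
  correlations <- do.call(rbind, lapply(pairs, function(p) {
    x <- tab[[p[1]]]; y <- tab[[p[2]]]
    keep <- is.finite(x) & is.finite(y)
    if (sum(keep) < 3L)
      return(data.frame(pair = paste(p, collapse = " vs "),
                        rho = NA_real_, p = NA_real_, n = sum(keep)))
    ct <- suppressWarnings(cor.test(x[keep], y[keep], method = "spearman"))
    data.frame(pair = paste(p, collapse = " vs "),
               rho = unname(ct$estimate), p = ct$p.value, n = sum(keep))
  }))
  list(table = tab, correlations = correlations)
}
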