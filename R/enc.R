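#' Effective number of codons (ENC) result
#'
#' ENC summarises codon usage bias on a 20-61 scale: 61 means all synonymous
#' codons are used equally, 20 means a single codon per amino acid (extreme
#' bias). The statistic averages per-family codon homozygosity estimates
#' within degeneracy classes (2-, 3-, 4- and 6-fold) and combines the class
#' means as ENC = 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6. Leu, Ser and Arg are scored
#' here as whole 6-fold families (the shuffling algorithms, by contrast, split
#' them; see [extractSites()]).
#'
#' @slot enc the capped ENC value in [20, 61].
#' @slot encRaw the uncapped value.
#' @slot capped TRUE if encRaw exceeded 61.
#' @slot estimator "corrected" or "frequency".
#' @slot familyF named per-family homozygosity estimates.
#' @slot familyN named per-family codon totals.
#' @slot classMeans mean homozygosity for classes "2", "3", "4", "6".
#' @export
setClass("EncResult", representation(
  enc = "numeric", encRaw = "numeric", capped = "logical",
  estimator = "character", familyF = "numeric", familyN = "numeric",
  classMeans = "numeric"
))

#' @rdname EncResult-class
#' @param object an \code{EncResult}.
#' @export
encValue <- function(object) object@enc

#' @rdname EncResult-class
#' @export
encClassMeans <- function(object) object@classMeans

#' @rdname EncResult-class
#' @export
encFamilyHomozygosity <- function(object) object@familyF

setMethod("show", "EncResult", function(object) {
  cat("ENC = ", format(object@enc, digits = 6),
      " (", object@estimator, " estimator",
      if (object@capped) ", capped at 61" else "", ")\n", sep = "")
  cat("  class means F:",
      paste(names(object@classMeans),
            round(object@classMeans, 4), sep = "=", collapse = "  "), "\n")
})

#' Codon counts of a coding sequence
#'
#' @param cds a [CodingSequence-class].
#' @param code a [GeneticCode-class].
#' @return named integer vector over the sense codons of \code{code}.
#' @export
codonUsage <- function(cds, code = standardGeneticCode()) {
  sense <- senseCodons(code)
  tab <- tabulate(match(codons(cds), sense), nbins = length(sense))
  setNames(tab, sense)
}

# Per-family homozygosity. corrected: Wright's F-hat = (n*sum(p^2)-1)/(n-1);
# frequency: F = sum(p^2). Families with n <= 1 (and, for the corrected
# estimator, F-hat <= 0) carry no information and are dropped from the class
# mean.
.familyHomozygosity <- function(counts, family, estimator) {
  n <- sum(counts[family$codons])
  if (n <= 1L) return(c(f = NA_real_, n = n))
  p <- counts[family$codons] / n
  sp2 <- sum(p^2)
  f <- if (estimator == "corrected") (n * sp2 - 1) / (n - 1) else sp2
  if (f <= 0) f <- NA_real_
  c(f = f, n = n)
}

#' Effective number of codons from codon counts
#'
#' Workhorse behind [effectiveNumberOfCodons()]; useful when codon counts are
#' already tabulated. The corrected estimator is Wright's bias-adjusted
#' homozygosity F-hat = (n * sum(p_i^2) - 1) / (n - 1); the frequency
#' estimator is the plain F = sum(p_i^2) (which makes the equal-use-of-61
#' -codons limit exactly 61). A family observed at most once is dropped from
#' its class mean; a missing 3-fold class (no informative Ile family) is
#' estimated as the average of the 2- and 4-fold class means; any other
#' missing class makes ENC undefined (an error). Values above 61 are capped
#' (with \code{capped = TRUE}); 20 is the floor of the scale.
#'
#' @param counts named codon counts (names are codons).
#' @param estimator \code{"corrected"} (default) or \code{"frequency"}.
#' @param code a [GeneticCode-class].
#' @return an [EncResult-class].
#' @export
encFromCounts <- function(counts, estimator = c("corrected", "frequency"),
                          code = standardGeneticCode()) {
  estimator <- match.arg(estimator)
  sense <- senseCodons(code)
  full <- setNames(numeric(length(sense)), sense)
  counts <- counts[names(counts) %in% sense]
  full[names(counts)] <- counts
  fams <- geneticCodeFamilies(code, "enc")
  fams <- Filter(function(f) f$class >= 2L, fams)

  fh <- vapply(fams, .familyHomozygosity, numeric(2),
               counts = full, estimator = estimator)
  familyF <- fh["f", ]
  familyN <- fh["n", ]
  classes <- vapply(fams, function(f) f$class, numeric(1))

  classMeans <- setNames(rep(NA_real_, 4), c("2", "3", "4", "6"))
  for (k in c(2, 3, 4, 6)) {
    fk <- familyF[classes == k & !is.na(familyF)]
    if (length(fk) > 0) classMeans[as.character(k)] <- mean(fk)
  }
  # Wright's fallback: a missing 3-fold class (Ile absent or uninformative)
  # is interpolated from the 2- and 4-fold means
  if (is.na(classMeans[["3"]]) &&
      !is.na(classMeans[["2"]]) && !is.na(classMeans[["4"]]))
    classMeans[["3"]] <- (classMeans[["2"]] + classMeans[["4"]]) / 2
  if (anyNA(classMeans))
    stop("undefined-ENC error: degeneracy class(es) ",
         paste(names(classMeans)[is.na(classMeans)], collapse = ", "),
         " have no informative family")

  raw <- 2 + 9 / classMeans[["2"]] + 1 / classMeans[["3"]] +
    5 / classMeans[["4"]] + 3 / classMeans[["6"]]
  capped <- raw > 61
  enc <- min(max(raw, 20), 61)
  new("EncResult", enc = enc, encRaw = unname(raw), capped = capped,
      estimator = estimator, familyF = familyF, familyN = familyN,
      classMeans = classMeans)
}

#' @rdname encFromCounts
#' @param cds a [CodingSequence-class] with at least one degenerate family
#'   represented.
#' @examples
#' # all 61 sense codons used equally: no bias at all
#' cds <- codingSequence(paste(rep(senseCodons(), 2), collapse = ""))
#' encValue(effectiveNumberOfCodons(cds, estimator = "frequency")) # 61
#' @export
effectiveNumberOfCodons <- function(cds,
                                    estimator = c("corrected", "frequency"),
                                    code = standardGeneticCode()) {
  encFromCounts(codonUsage(cds, code), estimator = estimator, code = code)
}

#' Wright's expected ENC at a given GC3
#'
#' The theoretical ENC of a sequence whose synonymous codon choice is driven
#' only by third-position GC content s (with G = C and A = T):
#' ENC(s) = 2 + s + 29 / (s^2 + (1 - s)^2). Plotted against GC3 it forms the
#' upper envelope of the ENC of composition-driven sequences.
#'
#' @param s GC3 fraction(s) in [0, 1].
#' @return expected ENC value(s).
#' @examples
#' wrightExpectedEnc(0.5) # 60.5
#' wrightExpectedEnc(0)   # 31
#' @export
wrightExpectedEnc <- function(s) {
  if (any(!is.finite(s)) || any(s < 0) || any(s > 1))
    stop("domain error: s must lie in [0, 1]")
  2 + s + 29 / (s^2 + (1 - s)^2)
}

#' Significance call for an ENC difference
#'
#' The replicate engine compares the ENC of the original sequence with the
#' mean ENC of shuffled replicates; a difference of more than 1 effective
#' codon (strictly) is called significant. The threshold reflects that
#' per-virus replicate standard deviations are a few tenths of an ENC unit,
#' so formal tests would flag negligible differences.
#'
#' @slot delta shuffled mean minus original ENC.
#' @slot threshold significance threshold (default 1).
#' @slot significant TRUE iff |delta| > threshold.
#' @export
setClass("SignificanceCall", representation(
  delta = "numeric", threshold = "numeric", significant = "logical"
))

#' @rdname SignificanceCall-class
#' @param original ENC of the original sequence (in [20, 61]).
#' @param shuffledMean mean ENC over shuffled replicates.
#' @param threshold significance threshold, default 1.
#' @return a \code{SignificanceCall}.
#' @examples
#' classifyEncDifference(50, 53.5)  # delta 3.5, significant
#' @export
classifyEncDifference <- function(original, shuffledMean, threshold = 1.0) {
  stopifnot(is.finite(original), is.finite(shuffledMean))
  if (original < 20 - 1e-9 || original > 61 + 1e-9 ||
      shuffledMean < 20 - 1e-9 || shuffledMean > 61 + 1e-9)
    stop("ENC values must lie in [20, 61]")
  delta <- shuffledMean - original
  new("SignificanceCall", delta = delta, threshold = threshold,
      significant = abs(delta) > threshold)
}

#' @rdname SignificanceCall-class
#' @param object a \code{SignificanceCall}.
#' @export
isSignificant <- function(object) object@significant

#' @rdname SignificanceCall-class
#' @export
encDelta <- function(object) object@delta

setMethod("show", "SignificanceCall", function(object) {
  cat("ENC difference ", format(object@delta, digits = 4),
      if (object@significant) " (significant, |delta| > "
      else " (not significant at threshold ",
      object@threshold, ")\n", sep = "")
})
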