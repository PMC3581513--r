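#' @import methods
#' @importFrom stats rgamma runif rbinom sd t.test cor.test setNames var
#' @importFrom utils write.table packageVersion head tail
NULL

NUCS <- c("A", "C", "G", "T")

DINUCS <- as.vector(outer(NUCS, NUCS, paste0))

#' Genetic code with synonymous-family bookkeeping
#'
#' A \code{GeneticCode} bundles a codon-to-amino-acid table with two family
#' decompositions of the 61 sense codons: whole amino-acid families (used for
#' the effective number of codons, where Leu/Ser/Arg are scored as 6-fold
#' classes) and 6-fold-split families (used by the shuffling algorithms, where
#' Leu, Ser and Arg are treated as independent 2-fold and 4-fold sub-families
#' so that codon positions 1-2 are fixed within every family).
#'
#' @slot codonToAa named character vector of length 64 mapping codons to
#'   one-letter amino-acid symbols, with \code{"*"} for stop codons.
#' @slot encFamilies list of amino-acid family records (\code{id}, \code{aa},
#'   \code{codons}, \code{class}) used for ENC.
#' @slot shuffleFamilies list of split family records (\code{id}, \code{aa},
#'   \code{codons}, \code{allowedThird}, \code{class}) used for shuffling.
#' @slot codonToShuffleFamily named character vector mapping each sense codon
#'   to its split family id.
#'
#' @seealso [standardGeneticCode()]
#' @export
setClass("GeneticCode", representation(
  codonToAa = "character",
  encFamilies = "list",
  shuffleFamilies = "list",
  codonToShuffleFamily = "character"
))

setValidity("GeneticCode", function(object) {
  msg <- NULL
  aa <- object@codonToAa
  if (length(aa) != 64L) msg <- c(msg, "codonToAa must have 64 entries")
  if (sum(aa == "*") != 3L && length(aa) == 64L)
    msg <- c(msg, "expected 3 stop codons")
  sense <- names(aa)[aa != "*"]
  mapped <- names(object@codonToShuffleFamily)
  if (!setequal(sense, mapped))
    msg <- c(msg, "every sense codon must belong to exactly one shuffle family")
  if (is.null(msg)) TRUE else msg
})

# Split map for the three 6-fold amino acids: 2-fold (UUR, AGY, AGR) and
# 4-fold (CUN, UCN, CGN) sub-families.
.SIXFOLD_SPLIT <- list(
  L2 = c("TTA", "TTG"), L4 = c("CTA", "CTC", "CTG", "CTT"),
  S2 = c("AGC", "AGT"), S4 = c("TCA", "TCC", "TCG", "TCT"),
  R2 = c("AGA", "AGG"), R4 = c("CGA", "CGC", "CGG", "CGT")
)

.buildGeneticCode <- function(codonToAa) {
  codonToAa <- codonToAa[order(names(codonToAa))]
  sense <- names(codonToAa)[codonToAa != "*"]

  aas <- sort(unique(codonToAa[sense]))
  encFamilies <- lapply(aas, function(a) {
    cods <- sort(sense[codonToAa[sense] == a])
    list(id = a, aa = a, codons = cods, class = length(cods))
  })
  names(encFamilies) <- aas

  # 6-fold families are split so positions 1-2 are constant within a family
  shuffleFamilies <- list()
  for (a in aas) {
    cods <- encFamilies[[a]]$codons
    if (length(cods) == 6L) {
      ids <- names(.SIXFOLD_SPLIT)[vapply(.SIXFOLD_SPLIT, function(s)
        all(s %in% cods), logical(1))]
      for (id in ids) {
        sub <- .SIXFOLD_SPLIT[[id]]
        shuffleFamilies[[id]] <- list(
          id = id, aa = a, codons = sub,
          allowedThird = sort(unique(substr(sub, 3, 3))),
          class = length(sub))
      }
    } else {
      shuffleFamilies[[a]] <- list(
        id = a, aa = a, codons = cods,
        allowedThird = sort(unique(substr(cods, 3, 3))),
        class = length(cods))
    }
  }

  codonToShuffleFamily <- character(0)
  for (f in shuffleFamilies)
    codonToShuffleFamily[f$codons] <- f$id

  new("GeneticCode",
      codonToAa = codonToAa,
      encFamilies = encFamilies,
      shuffleFamilies = shuffleFamilies,
      codonToShuffleFamily = codonToShuffleFamily)
}

.standardCodeCache <- new.env(parent = emptyenv())

#' The standard genetic code
#'
#' Built from [Biostrings::GENETIC_CODE]. The object is cached, so repeated
#' calls are cheap.
#'
#' @return a [GeneticCode-class] object for the standard nuclear code.
#' @examples
#' gc <- standardGeneticCode()
#' geneticCodeFamilies(gc, "enc")[["F"]]$codons # TTC, TTT
#' @export
standardGeneticCode <- function() {
  if (is.null(.standardCodeCache$std)) {
    tab <- Biostrings::GENETIC_CODE
    .standardCodeCache$std <- .buildGeneticCode(setNames(as.character(tab),
                                                         names(tab)))
  }
  .standardCodeCache$std
}

#' @describeIn GeneticCode-class translate a codon vector to amino acids.
#' @param code a [GeneticCode-class] object.
#' @param codons character vector of triplets.
#' @export
codonTranslate <- function(codons, code = standardGeneticCode()) {
  unname(code@codonToAa[codons])
}

#' Family decompositions of a genetic code
#'
#' @param code a [GeneticCode-class].
#' @param which \code{"enc"} for whole amino-acid families (6-fold amino acids
#'   intact), \code{"shuffle"} for the 6-fold-split families.
#' @return named list of family records.
#' @export
geneticCodeFamilies <- function(code, which = c("enc", "shuffle")) {
  which <- match.arg(which)
  if (which == "enc") code@encFamilies else code@shuffleFamilies
}

#' @rdname geneticCodeFamilies
#' @export
senseCodons <- function(code = standardGeneticCode()) {
  names(code@codonToAa)[code@codonToAa != "*"]
}

#' @rdname geneticCodeFamilies
#' @export
stopCodons <- function(code = standardGeneticCode()) {
  names(code@codonToAa)[code@codonToAa == "*"]
}

setMethod("show", "GeneticCode", function(object) {
  cat("GeneticCode:", sum(object@codonToAa != "*"), "sense codons,",
      sum(object@codonToAa == "*"), "stops;",
      length(object@encFamilies), "amino-acid families,",
      length(object@shuffleFamilies), "shuffle families (6-fold split)\n")
})
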