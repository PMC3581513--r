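#' In-frame coding sequence
#'
#' The unit all statistics and shuffles operate on: an in-frame nucleotide
#' sequence over \{A,C,G,T\} together with its derived amino-acid sequence.
#' Input is normalised (upper case, U to T) and validated: the length must be
#' a positive multiple of 3 and no internal stop codon may occur. A single
#' terminal stop codon is stripped and recorded.
#'
#' @slot id text label.
#' @slot nt nucleotide string over A/C/G/T.
#' @slot aa derived amino-acid string.
#' @slot codons cached character vector of codons (performance).
#' @slot terminalStopStripped TRUE if the input ended in a stop codon.
#' @slot droppedCodons number of codons removed in permissive ambiguity mode.
#'
#' @seealso [codingSequence()], [translateCds()]
#' @export
setClass("CodingSequence", representation(
  id = "character",
  nt = "character",
  aa = "character",
  codons = "character",
  terminalStopStripped = "logical",
  droppedCodons = "integer"
))

setValidity("CodingSequence", function(object) {
  msg <- NULL
  if (nchar(object@nt) %% 3L != 0L || nchar(object@nt) == 0L)
    msg <- c(msg, "nt length must be a positive multiple of 3")
  if (grepl("[^ACGT]", object@nt))
    msg <- c(msg, "nt must be over the A/C/G/T alphabet")
  if (nchar(object@aa) * 3L != nchar(object@nt))
    msg <- c(msg, "aa length inconsistent with nt length")
  if (is.null(msg)) TRUE else msg
})

.splitCodons <- function(nt) {
  n <- nchar(nt)
  substring(nt, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
}

#' Construct and validate a coding sequence
#'
#' \code{codingSequence()} (alias \code{translateCds()}) normalises a
#' nucleotide string (upper case, U to T), checks the reading frame, translates
#' it and validates the result. A single terminal stop codon is stripped and
#' recorded; an internal stop codon is an error reporting the codon index.
#' Ambiguity codes are rejected by default; \code{ambiguity = "drop"} removes
#' affected codons from the sequence (and hence from every downstream
#' statistic and shuffle pool), with a message stating how many.
#'
#' @param nt nucleotide string (A/C/G/T/U, case-insensitive).
#' @param id text label for the sequence.
#' @param code a [GeneticCode-class]; the standard code by default.
#' @param ambiguity \code{"error"} (default) or \code{"drop"}.
#' @return a [CodingSequence-class] object.
#' @examples
#' x <- codingSequence("ATGTTTAAA")
#' aaSequence(x)    # "MFK"
#' codonCount(x)    # 3
#' codingSequence("ATGTTTTAA")  # terminal stop stripped -> "MF"
#' @export
codingSequence <- function(nt, id = "", code = standardGeneticCode(),
                           ambiguity = c("error", "drop")) {
  ambiguity <- match.arg(ambiguity)
  stopifnot(is.character(nt), length(nt) == 1L)
  nt <- chartr("u", "T", chartr("U", "T", toupper(nt)))
  nt <- gsub("[[:space:]]", "", nt)
  if (nchar(nt) == 0L)
    stop("empty input: no nucleotides in record '", id, "'")
  if (nchar(nt) %% 3L != 0L)
    stop("frame error: length ", nchar(nt), " of record '", id,
         "' is not a multiple of 3")
  codons <- .splitCodons(nt)
  dropped <- 0L
  bad <- grepl("[^ACGT]", codons)
  if (any(bad)) {
    if (ambiguity == "error")
      stop("ambiguity codes or invalid characters in record '", id,
           "' (first at codon ", which(bad)[1L], "); use ambiguity = \"drop\"",
           " to discard affected codons")
    dropped <- sum(bad)
    message("dropped ", dropped, " codon(s) with ambiguity codes from '",
            id, "'")
    codons <- codons[!bad]
    if (length(codons) == 0L)
      stop("empty input: record '", id, "' has no unambiguous codons")
  }
  aa <- codonTranslate(codons, code)
  stopIdx <- which(aa == "*")
  stripped <- FALSE
  if (length(stopIdx) > 0L) {
    if (stopIdx[length(stopIdx)] == length(codons) && length(stopIdx) == 1L) {
      codons <- codons[-length(codons)]
      aa <- aa[-length(aa)]
      stripped <- TRUE
      if (length(codons) == 0L)
        stop("empty input: record '", id, "' is a bare stop codon")
    } else {
      stop("validity error: internal stop codon at codon index ",
           stopIdx[1L], " in record '", id, "'")
    }
  }
  new("CodingSequence",
      id = as.character(id),
      nt = paste(codons, collapse = ""),
      aa = paste(aa, collapse = ""),
      codons = codons,
      terminalStopStripped = stripped,
      droppedCodons = dropped)
}

#' @rdname codingSequence
#' @export
translateCds <- codingSequence

# internal fast constructor: codons already validated, stop-free
.newCds <- function(codons, aa, id, stripped = FALSE, dropped = 0L) {
  new("CodingSequence", id = id, nt = paste(codons, collapse = ""),
      aa = paste(aa, collapse = ""), codons = codons,
      terminalStopStripped = stripped, droppedCodons = dropped)
}

#' @rdname codingSequence
#' @param x a [CodingSequence-class].
#' @export
ntSequence <- function(x) x@nt

#' @rdname codingSequence
#' @export
aaSequence <- function(x) x@aa

#' @rdname codingSequence
#' @export
codons <- function(x) x@codons

#' @rdname codingSequence
#' @export
codonCount <- function(x) length(x@codons)

#' @rdname codingSequence
#' @export
seqId <- function(x) x@id

#' @rdname codingSequence
#' @export
terminalStopStripped <- function(x) x@terminalStopStripped

setMethod("show", "CodingSequence", function(object) {
  n <- codonCount(object)
  cat("CodingSequence '", object@id, "': ", n, " codons (",
      nchar(object@nt), " nt)", sep = "")
  if (object@terminalStopStripped) cat(" [terminal stop stripped]")
  cat("\n  aa: ", if (n > 20) paste0(substr(object@aa, 1, 20), "...")
      else object@aa, "\n", sep = "")
})

setMethod("length", "CodingSequence", function(x) codonCount(x))
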