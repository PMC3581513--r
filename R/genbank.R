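#' Minimal GenBank flat-file reader
#'
#' Parses the subset of the GenBank flat-file format needed to build ORF
#' concatemers: the LOCUS/ACCESSION header, the CDS features (with
#' \code{join()} and \code{complement()} locations and their \code{/gene}
#' and \code{/product} qualifiers) and the ORIGIN sequence. Multi-record
#' files are supported (records are separated by \code{//}).
#'
#' @param path GenBank flat file.
#' @return list of records; each record is a list with elements
#'   \code{accession}, \code{definition}, \code{sequence} (upper-case
#'   character string) and \code{cds}, a list of features each holding
#'   \code{gene}, \code{product}, \code{complement} (logical) and
#'   \code{ranges} (an [IRanges::IRanges] of exon coordinates in genomic
#'   order).
#' @export
readGenBank <- function(path) {
  if (!file.exists(path)) stop("unreadable file: ", path)
  lines <- readLines(path, warn = FALSE)
  recStarts <- grep("^LOCUS", lines)
  if (length(recStarts) == 0L) stop("no LOCUS line: not a GenBank file")
  recEnds <- grep("^//", lines)
  if (length(recEnds) < length(recStarts))
    recEnds <- c(recEnds, length(lines))
  records <- vector("list", length(recStarts))
  for (k in seq_along(recStarts)) {
    records[[k]] <- .parseGenBankRecord(lines[recStarts[k]:recEnds[k]])
  }
  records
}

.parseLocation <- function(loc) {
  loc <- gsub("[<>]", "", gsub("[[:space:]]", "", loc))
  comp <- grepl("complement", loc)
  loc <- gsub("complement\\(|join\\(|order\\(|\\)", "", loc)
  parts <- strsplit(loc, ",")[[1]]
  se <- lapply(parts, function(p) {
    xs <- as.integer(strsplit(p, "\\.\\.")[[1]])
    if (length(xs) == 1L) xs <- c(xs, xs)
    xs
  })
  starts <- vapply(se, `[`, integer(1), 1L)
  ends <- vapply(se, `[`, integer(1), 2L)
  if (any(is.na(starts)) || any(is.na(ends)) || any(ends < starts))
    stop("cannot parse feature location: ", loc)
  list(ranges = IRanges::IRanges(start = starts, end = ends),
       complement = comp)
}

.parseGenBankRecord <- function(lines) {
  accession <- NA_character_
  accLine <- grep("^ACCESSION", lines, value = TRUE)
  if (length(accLine)) accession <- strsplit(trimws(
    sub("^ACCESSION", "", accLine[1])), "\\s+")[[1]][1]
  defLine <- grep("^DEFINITION", lines, value = TRUE)
  definition <- if (length(defLine)) trimws(sub("^DEFINITION", "",
                                                defLine[1])) else ""

  featStart <- grep("^FEATURES", lines)
  originStart <- grep("^ORIGIN", lines)
  if (length(originStart) == 0L) stop("GenBank record has no ORIGIN block")

  seqLines <- lines[(originStart[1] + 1L):length(lines)]
  seqLines <- seqLines[!grepl("^//", seqLines)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seqLines, collapse = "")))

  cds <- list()
  if (length(featStart)) {
    featLines <- lines[(featStart[1] + 1L):(originStart[1] - 1L)]
    # feature keys sit at column 6; qualifier/continuation lines at column 22
    keyIdx <- grep("^ {5}\\S", featLines)
    for (fi in seq_along(keyIdx)) {
      i0 <- keyIdx[fi]
      i1 <- if (fi < length(keyIdx)) keyIdx[fi + 1L] - 1L
            else length(featLines)
      key <- strsplit(trimws(featLines[i0]), "\\s+")[[1]][1]
      if (key != "CDS") next
      block <- featLines[i0:i1]
      body <- trimws(block)
      body[1] <- trimws(sub("^\\s*CDS", "", block[1]))
      qualStart <- grep("^/", body)
      locEnd <- if (length(qualStart)) qualStart[1] - 1L else length(body)
      loc <- paste(body[seq_len(locEnd)], collapse = "")
      getQual <- function(q) {
        m <- grep(paste0("^/", q, "="), body, value = TRUE)
        if (!length(m)) return(NA_character_)
        gsub("\"", "", sub(paste0("^/", q, "="), "", m[1]))
      }
      parsed <- .parseLocation(loc)
      cds[[length(cds) + 1L]] <- list(
        gene = getQual("gene"), product = getQual("product"),
        complement = parsed$complement, ranges = parsed$ranges)
    }
  }
  list(accession = accession, definition = definition,
       sequence = sequence, cds = cds)
}

.revComp <- function(x) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]), collapse = "")
}

# extract the (spliced, oriented) nucleotide sequence of one CDS feature,
# optionally dropping genomic positions in `excise`
.extractFeature <- function(record, feature, excise = NULL) {
  keep <- feature$ranges
  if (!is.null(excise) && length(excise) > 0L)
    keep <- IRanges::setdiff(keep, excise)
  if (sum(IRanges::width(keep)) == 0L)
    stop("feature entirely excised")
  chunks <- vapply(seq_along(keep), function(i)
    substr(record$sequence, IRanges::start(keep)[i], IRanges::end(keep)[i]),
    character(1))
  s <- paste(chunks, collapse = "")
  if (feature$complement) .revComp(s) else s
}

#' Recipe for an ORF concatemer
#'
#' Selects CDS features across one or more GenBank records and describes how
#' to join them in frame into a single analysis sequence. With
#' \code{excludeOverlaps}, genomic regions covered by two or more CDS
#' features of the same record (overlapping reading frames) are excised from
#' each feature before joining; each piece is then re-framed from its own 5'
#' end and truncated to a codon multiple.
#'
#' @slot selectors list with one element per record: \code{"all"}, a vector
#'   of feature indices, or a vector of gene names.
#' @slot excludeOverlaps logical.
#' @slot expectedLength optional total nt length to validate against.
#' @slot id label of the resulting sequence.
#' @export
setClass("ConcatemerRecipe", representation(
  selectors = "list", excludeOverlaps = "logical",
  expectedLength = "numeric", id = "character"
))

#' @rdname ConcatemerRecipe-class
#' @param selectors,excludeOverlaps,expectedLength,id see slots; with a
#'   single-record input \code{selectors} may be omitted to select all CDS.
#' @export
concatemerRecipe <- function(selectors = list("all"),
                             excludeOverlaps = FALSE,
                             expectedLength = NULL, id = "concatemer") {
  new("ConcatemerRecipe", selectors = selectors,
      excludeOverlaps = excludeOverlaps,
      expectedLength = if (is.null(expectedLength)) NA_real_
                       else as.numeric(expectedLength),
      id = id)
}

.selectFeatures <- function(record, selector) {
  n <- length(record$cds)
  if (identical(selector, "all")) return(seq_len(n))
  if (is.numeric(selector)) {
    if (any(selector < 1 | selector > n))
      stop("missing feature: CDS index out of range in record ",
           record$accession)
    return(as.integer(selector))
  }
  genes <- vapply(record$cds, function(f)
    if (is.na(f$gene)) "" else f$gene, character(1))
  idx <- match(selector, genes)
  if (anyNA(idx))
    stop("missing feature: gene '", selector[which(is.na(idx))[1]],
         "' not found in record ", record$accession)
  idx
}

#' Build an ORF concatemer from GenBank records
#'
#' CDS features are extracted in recipe order (honouring \code{join()}
#' coordinates and strand), each is stripped of a terminal stop codon, and
#' the pieces are concatenated in frame into one [CodingSequence-class].
#' When \code{excludeOverlaps} is set, genomic regions annotated as covered
#' by two or more CDS features are excised first and each piece is truncated
#' to a codon multiple anchored at its own start. The result is validated
#' (frame-correct, internally stop-free) and, when the recipe carries an
#' \code{expectedLength}, checked against it.
#'
#' @param recipe a [ConcatemerRecipe-class].
#' @param records output of [readGenBank()] (or one record).
#' @param code a [GeneticCode-class].
#' @return a [CodingSequence-class].
#' @export
buildConcatemer <- function(recipe, records,
                            code = standardGeneticCode()) {
  stopifnot(is(recipe, "ConcatemerRecipe"))
  if (!is.null(records$sequence)) records <- list(records)
  if (length(recipe@selectors) == 1L && length(records) > 1L)
    selectors <- rep(recipe@selectors, length(records))
  else selectors <- recipe@selectors
  if (length(selectors) != length(records))
    stop("recipe has ", length(selectors), " selector(s) for ",
         length(records), " record(s)")

  pieces <- character(0)
  for (k in seq_along(records)) {
    rec <- records[[k]]
    idx <- .selectFeatures(rec, selectors[[k]])
    excise <- NULL
    if (recipe@excludeOverlaps && length(rec$cds) > 1L) {
      allR <- do.call(c, lapply(rec$cds, function(f) f$ranges))
      cov <- IRanges::coverage(allR)
      excise <- IRanges::slice(cov, lower = 2L, rangesOnly = TRUE)
    }
    for (i in idx) {
      s <- tryCatch(.extractFeature(rec, rec$cds[[i]], excise),
                    error = function(e)
                      stop("out-of-frame excision in record ",
                           rec$accession, ", CDS ", i, ": ",
                           conditionMessage(e)))
      s <- substr(s, 1L, (nchar(s) %/% 3L) * 3L)   # re-frame from 5' end
      if (nchar(s) == 0L)
        stop("missing feature: CDS ", i, " of record ", rec$accession,
             " is empty after excision")
      # strip a terminal stop before joining
      last <- substr(s, nchar(s) - 2L, nchar(s))
      if (last %in% stopCodons(code)) s <- substr(s, 1L, nchar(s) - 3L)
      pieces <- c(pieces, s)
    }
  }
  cds <- codingSequence(paste(pieces, collapse = ""), id = recipe@id,
                        code = code)
  if (!is.na(recipe@expectedLength) &&
      nchar(ntSequence(cds)) != recipe@expectedLength)
    stop("concatemer length ", nchar(ntSequence(cds)),
         " does not match expected length ", recipe@expectedLength)
  cds
}
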