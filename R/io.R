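#' Read in-frame coding sequences from FASTA
#'
#' Each FASTA record is validated as a [CodingSequence-class] (frame, alphabet,
#' internal stops); records that fail are collected in a per-record failure
#' table with the reason, and the valid records are returned. Lower case and
#' U are normalised on input.
#'
#' @param path FASTA file, one CDS per record.
#' @param code a [GeneticCode-class].
#' @param ambiguity passed to [codingSequence()].
#' @return list with elements \code{sequences} (list of
#'   [CodingSequence-class]) and \code{failures} (data.frame with columns
#'   \code{id}, \code{reason}).
#' @seealso [writeCdsFasta()]
#' @export
readCdsFasta <- function(path, code = standardGeneticCode(),
                         ambiguity = "error") {
  if (!file.exists(path)) stop("unreadable file: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("unreadable FASTA: ",
                                           conditionMessage(e)))
  if (length(set) == 0L) stop("empty file: ", path)
  ids <- sub("\\s.*$", "", names(set))
  sequences <- list()
  failures <- data.frame(id = character(0), reason = character(0))
  for (i in seq_along(set)) {
    res <- tryCatch(
      codingSequence(as.character(set[[i]]), id = ids[i], code = code,
                     ambiguity = ambiguity),
      error = function(e) e)
    if (inherits(res, "error")) {
      failures <- rbind(failures,
                        data.frame(id = ids[i],
                                   reason = conditionMessage(res)))
    } else {
      sequences[[length(sequences) + 1L]] <- res
    }
  }
  list(sequences = sequences, failures = failures)
}

#' Write coding sequences to FASTA
#'
#' @param cdsList a [CodingSequence-class] or list of them.
#' @param path output file.
#' @export
writeCdsFasta <- function(cdsList, path) {
  if (is(cdsList, "CodingSequence")) cdsList <- list(cdsList)
  ids <- vapply(cdsList, seqId, character(1))
  ids[ids == ""] <- paste0("seq_", which(ids == ""))
  set <- Biostrings::DNAStringSet(vapply(cdsList, ntSequence, character(1)))
  names(set) <- ids
  Biostrings::writeXStringSet(set, filepath = path)
  invisible(path)
}
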