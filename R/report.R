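#' Full per-sequence and panel-level codon usage report
#'
#' For each input sequence: ENC (corrected estimator), one shuffled-replicate
#' summary per shuffling mode (GC3, N3, DN23, DN31, DN231), relative
#' dinucleotide bias tables at codon-position pairs 2-3 and 3-1, and the
#' composition-variance descriptors (GC3 with n = 2, third-position
#' mononucleotides with n = 4, pair 2-3 dinucleotides with n = 16). With two
#' or more sequences the positional CpG comparison is added; with three or
#' more, the amino-acid preference correlations. Per-sequence failures are
#' collected, not fatal to the batch. The run is fully determined by
#' \code{seed}.
#'
#' @param cdsList list of [CodingSequence-class] (>= 1 valid CDS).
#' @param replicates shuffled replicates per mode (default 1000).
#' @param seed RNG seed for the whole report.
#' @param swapSweeps swap attempts per eligible site.
#' @param threshold ENC-difference significance threshold.
#' @param modes shuffle modes to run.
#' @param code a [GeneticCode-class].
#' @return object of class \code{cubReport}: a list with elements
#'   \code{config}, \code{sequences} (per-sequence results),
#'   \code{failures}, and optional \code{cpgComparison} /
#'   \code{aaPreference}.
#' @seealso [writeReportJson()], [writeReportTsv()]
#' @export
fullReport <- function(cdsList, replicates = 1000L, seed = 1L,
                       swapSweeps = 10L, threshold = 1.0,
                       modes = SHUFFLE_MODES,
                       code = standardGeneticCode()) {
  if (is(cdsList, "CodingSequence")) cdsList <- list(cdsList)
  if (length(cdsList) < 1L) stop("need at least one CDS")
  set.seed(seed)
  sequences <- list()
  failures <- list()
  for (x in cdsList) {
    res <- tryCatch({
      enc <- effectiveNumberOfCodons(x, code = code)
      shuffles <- do.call(rbind, lapply(modes, function(m)
        summaryRow(runShuffleReplicates(
          x, shuffleSpec(m, replicates = replicates,
                         swapSweeps = swapSweeps, threshold = threshold),
          code = code))))
      list(
        id = seqId(x),
        codons = codonCount(x),
        enc = encValue(enc),
        encClassMeans = as.list(encClassMeans(enc)),
        gc3 = gc3Content(x),
        shuffles = shuffles,
        rdb23 = rdbAsDataFrame(relativeDinucleotideBias(x, "23")),
        rdb31 = if (codonCount(x) >= 2L)
          rdbAsDataFrame(relativeDinucleotideBias(x, "31")) else NULL,
        variances = list(
          gc3 = compositionVariance(gc3FrequencyVector(x)),
          mono3 = compositionVariance(positionalNucleotideFreqs(x, 3)),
          dinuc23 = compositionVariance(positionalDinucleotideFreqs(x, "23"))
        ))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1L]] <-
        list(id = seqId(x), reason = conditionMessage(res))
    } else {
      sequences[[length(sequences) + 1L]] <- res
    }
  }
  ok <- vapply(sequences, function(s) s$id, character(1))
  report <- list(
    config = list(seed = seed, replicates = replicates,
                  swapSweeps = swapSweeps, threshold = threshold,
                  modes = modes,
                  version = as.character(packageVersion("codonShuffle"))),
    sequences = sequences,
    failures = failures)
  okCds <- cdsList[vapply(cdsList, seqId, character(1)) %in% ok]
  if (length(okCds) >= 2L)
    report$cpgComparison <- tryCatch(cpgPositionalComparison(okCds),
                                     error = function(e) NULL)
  if (length(okCds) >= 3L)
    report$aaPreference <- tryCatch(aminoAcidPreferenceAnalysis(okCds),
                                    error = function(e) NULL)
  class(report) <- "cubReport"
  report
}

.comparisonAsList <- function(cmp) {
  list(meanA = cmp@meanA, meanB = cmp@meanB,
       semA = cmp@semA, semB = cmp@semB,
       pValue = cmp@pValue, dropped = cmp@dropped, label = cmp@label)
}

#' Serialise a report
#'
#' JSON keeps full numeric precision; the TSV summary rounds to 4 decimal
#' places for human reading.
#'
#' @param report a \code{cubReport} from [fullReport()].
#' @param path output file.
#' @export
writeReportJson <- function(report, path) {
  out <- unclass(report)
  if (!is.null(out$cpgComparison))
    out$cpgComparison <- .comparisonAsList(out$cpgComparison)
  if (!is.null(out$aaPreference))
    out$aaPreference <- list(table = out$aaPreference$table,
                             correlations = out$aaPreference$correlations)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", null = "null")
  invisible(path)
}

#' @rdname writeReportJson
#' @export
writeReportTsv <- function(report, path) {
  rows <- do.call(rbind, lapply(report$sequences, function(s) {
    sh <- s$shuffles
    base <- data.frame(id = s$id, codons = s$codons,
                       enc = round(s$enc, 4), gc3 = round(s$gc3, 4),
                       var_gc3 = round(s$variances$gc3, 6),
                       var_mono3 = round(s$variances$mono3, 6),
                       var_dinuc23 = round(s$variances$dinuc23, 6))
    for (i in seq_len(nrow(sh))) {
      m <- tolower(sh$mode[i])
      base[[paste0("enc_mean_", m)]] <- round(sh$enc_mean[i], 4)
      base[[paste0("enc_sd_", m)]] <- round(sh$enc_sd[i], 4)
      base[[paste0("delta_", m)]] <- round(sh$delta[i], 4)
      base[[paste0("significant_", m)]] <- sh$significant[i]
    }
    base
  }))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.cubReport <- function(x, ...) {
  cat("cubReport:", length(x$sequences), "sequence(s),",
      length(x$failures), "failure(s); seed", x$config$seed,
      ", R =", x$config$replicates, "\n")
  for (s in x$sequences)
    cat(sprintf("  %s: ENC %.2f, GC3 %.3f\n", s$id, s$enc, s$gc3))
  invisible(x)
}
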