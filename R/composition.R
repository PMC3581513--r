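#' Frequency vector over nucleotide or dinucleotide states
#'
#' A thin container for a normalised frequency vector with an explicit state
#' space: 2 states for GC content, 4 for mononucleotides, 16 for
#' dinucleotides. The number of states is the \code{n} entering the
#' composition-variance descriptor.
#'
#' @slot states ordered state labels.
#' @slot x frequencies summing to 1.
#' @slot n number of states.
#' @seealso [compositionVariance()]
#' @export
setClass("FrequencyVector", representation(
  states = "character", x = "numeric", n = "integer"
))

setValidity("FrequencyVector", function(object) {
  msg <- NULL
  if (length(object@x) != object@n || length(object@states) != object@n)
    msg <- c(msg, "states, x and n must agree")
  if (any(object@x < -1e-12) || any(object@x > 1 + 1e-12))
    msg <- c(msg, "frequencies must lie in [0, 1]")
  if (abs(sum(object@x) - 1) > 1e-9)
    msg <- c(msg, "frequencies must sum to 1 (within 1e-9)")
  if (is.null(msg)) TRUE else msg
})

#' @rdname FrequencyVector-class
#' @param x numeric vector of frequencies (or counts, normalised when
#'   \code{normalize = TRUE}).
#' @param states state labels; default \code{names(x)}.
#' @param normalize divide by the total first.
#' @export
frequencyVector <- function(x, states = names(x), normalize = FALSE) {
  if (is.null(states)) stop("state labels required")
  if (normalize) {
    tot <- sum(x)
    if (tot <= 0) stop("empty-input error: nothing to normalise")
    x <- x / tot
  }
  new("FrequencyVector", states = as.character(states),
      x = unname(as.numeric(x)), n = length(x))
}

#' @rdname FrequencyVector-class
#' @param object a \code{FrequencyVector}.
#' @export
freqs <- function(object) setNames(object@x, object@states)

#' @rdname FrequencyVector-class
#' @export
nStates <- function(object) object@n

setMethod("show", "FrequencyVector", function(object) {
  cat("FrequencyVector (", object@n, " states)\n", sep = "")
  print(round(freqs(object), 4))
})

.posChars <- function(cds, position) {
  stopifnot(position %in% 1:3)
  substr(codons(cds), position, position)
}

#' Nucleotide counts and frequencies at one codon position
#'
#' @param cds a [CodingSequence-class].
#' @param position codon position 1, 2 or 3.
#' @return \code{positionalNucleotideCounts}: named integer vector over
#'   A,C,G,T. \code{positionalNucleotideFreqs}: a [FrequencyVector-class].
#' @examples
#' x <- codingSequence("ATGAAA")
#' freqs(positionalNucleotideFreqs(x, 3)) # A 0.5, G 0.5
#' @export
positionalNucleotideCounts <- function(cds, position) {
  ch <- .posChars(cds, position)
  tab <- table(factor(ch, levels = NUCS))
  setNames(as.integer(tab), NUCS)
}

#' @rdname positionalNucleotideCounts
#' @export
positionalNucleotideFreqs <- function(cds, position) {
  cnt <- positionalNucleotideCounts(cds, position)
  frequencyVector(cnt, states = NUCS, normalize = TRUE)
}

.pairChars <- function(cds, pair) {
  pair <- as.character(pair)
  cod <- codons(cds)
  switch(pair,
    "12" = paste0(substr(cod, 1, 1), substr(cod, 2, 2)),
    "23" = paste0(substr(cod, 2, 2), substr(cod, 3, 3)),
    "31" = {
      if (length(cod) < 2L)
        stop("empty-input error: pair 31 needs at least 2 codons")
      n <- length(cod)
      paste0(substr(cod[-n], 3, 3), substr(cod[-1L], 1, 1))
    },
    stop("pair must be one of 12, 23, 31"))
}

#' Dinucleotide counts and frequencies at a codon-position pair
#'
#' Pair 12 and 23 dinucleotides are read within each codon; pair 31 spans a
#' codon boundary (position 3 of codon k, position 1 of codon k+1), so the
#' final codon contributes nothing and a single-codon sequence is an error.
#'
#' @param cds a [CodingSequence-class].
#' @param pair one of \code{"12"}, \code{"23"}, \code{"31"} (numbers accepted).
#' @return counts: named integer vector over the 16 dinucleotides;
#'   freqs: a [FrequencyVector-class].
#' @export
positionalDinucleotideCounts <- function(cds, pair) {
  ch <- .pairChars(cds, pair)
  tab <- table(factor(ch, levels = DINUCS))
  setNames(as.integer(tab), DINUCS)
}

#' @rdname positionalDinucleotideCounts
#' @export
positionalDinucleotideFreqs <- function(cds, pair) {
  cnt <- positionalDinucleotideCounts(cds, pair)
  frequencyVector(cnt, states = DINUCS, normalize = TRUE)
}

#' Relative dinucleotide bias table
#'
#' Observed over expected dinucleotide frequencies at a codon-position pair,
#' the expectation being the product of the positional mononucleotide
#' frequencies: for dinucleotide (p,q) at pair 2-3 it is
#' f(p at position 2) x f(q at position 3); at pair 3-1,
#' f(p at position 3) x f(q at position 1). Entries with zero expectation are
#' undefined (NA), not 0.
#'
#' @slot pair "23" or "31".
#' @slot observed,expected,rdb numeric vectors over the 16 dinucleotides.
#' @slot nUnits number of dinucleotide observations.
#' @export
setClass("RdbTable", representation(
  pair = "character", observed = "numeric", expected = "numeric",
  rdb = "numeric", nUnits = "integer"
))

setValidity("RdbTable", function(object) {
  ok <- !is.na(object@rdb)
  if (any(abs(object@rdb[ok] * object@expected[ok] -
              object@observed[ok]) > 1e-9))
    return("rdb * expected must reconstruct observed wherever defined")
  TRUE
})

#' @rdname RdbTable-class
#' @param cds a [CodingSequence-class].
#' @param pair \code{"23"} or \code{"31"}.
#' @return a \code{RdbTable}.
#' @examples
#' x <- codingSequence("ACGACGAGAAGA")
#' rdbValues(relativeDinucleotideBias(x, "23"))[["CG"]] # 2
#' @export
relativeDinucleotideBias <- function(cds, pair = c("23", "31")) {
  pair <- match.arg(as.character(pair), c("23", "31"))
  obs <- positionalDinucleotideFreqs(cds, pair)
  p1 <- if (pair == "23") 2L else 3L
  p2 <- if (pair == "23") 3L else 1L
  f1 <- freqs(positionalNucleotideFreqs(cds, p1))
  f2 <- freqs(positionalNucleotideFreqs(cds, p2))
  expected <- as.vector(outer(f1, f2))          # column-major: f1 varies fast
  # outer(f1, f2)[i, j] = f1[i] * f2[j]; label rows as first base
  names(expected) <- as.vector(outer(NUCS, NUCS, paste0))
  expected <- expected[DINUCS]
  observed <- freqs(obs)
  rdb <- ifelse(expected > 0, observed / expected, NA_real_)
  new("RdbTable", pair = pair, observed = unname(observed),
      expected = unname(expected), rdb = unname(rdb),
      nUnits = if (pair == "23") codonCount(cds) else codonCount(cds) - 1L)
}

#' @rdname RdbTable-class
#' @param object a \code{RdbTable}.
#' @export
rdbValues <- function(object) setNames(object@rdb, DINUCS)

#' @rdname RdbTable-class
#' @export
rdbObserved <- function(object) setNames(object@observed, DINUCS)

#' @rdname RdbTable-class
#' @export
rdbExpected <- function(object) setNames(object@expected, DINUCS)

#' @rdname RdbTable-class
#' @export
rdbPair <- function(object) object@pair

#' @rdname RdbTable-class
#' @export
rdbAsDataFrame <- function(object) {
  data.frame(state = DINUCS, observed = object@observed,
              expected = object@expected, rdb = object@rdb)
}

setMethod("show", "RdbTable", function(object) {
  cat("RdbTable, codon-position pair ", object@pair, " (",
      object@nUnits, " dinucleotides)\n", sep = "")
  v <- round(setNames(object@rdb, DINUCS), 3)
  print(matrix(v, 4, 4, dimnames = list(first = NUCS, second = NUCS),
               byrow = TRUE))
})

#' Variance of a frequency vector around the uniform composition
#'
#' The mean squared deviation of the frequencies from uniform,
#' (1/n) * sum_i (x_i - 1/n)^2, where n is the number of states (2 for GC
#' content, 4 for mononucleotides, 16 for dinucleotides). Zero iff the vector
#' is uniform; invariant under permutation of states.
#'
#' @param x a [FrequencyVector-class] or a named numeric frequency vector.
#' @return non-negative scalar.
#' @examples
#' compositionVariance(frequencyVector(c(GC = 0.6, AT = 0.4))) # 0.01
#' @export
compositionVariance <- function(x) {
  if (is(x, "FrequencyVector")) {
    v <- x@x; n <- x@n
  } else {
    v <- as.numeric(x); n <- length(v)
    if (abs(sum(v) - 1) > 1e-9)
      stop("frequencies must sum to 1")
  }
  mean((v - 1 / n)^2)
}

#' Combined G+C frequency at the third codon position
#'
#' @param cds a [CodingSequence-class].
#' @return scalar in [0, 1] (the s of Wright's expected-ENC curve).
#' @export
gc3Content <- function(cds) {
  f <- freqs(positionalNucleotideFreqs(cds, 3))
  unname(f[["G"]] + f[["C"]])
}

#' @rdname gc3Content
#' @export
gc3FrequencyVector <- function(cds) {
  f <- freqs(positionalNucleotideFreqs(cds, 3))
  frequencyVector(c(GC = unname(f[["G"]] + f[["C"]]),
                    AT = unname(f[["A"]] + f[["T"]])))
}
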