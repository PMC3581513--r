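#' Specification for the simulated coding-sequence panel
#'
#' Defaults reproduce the study conditions of the composition-vs-ENC
#' analysis: 1000 sequences of 3334 codons (10002 nt) each, amino acids drawn
#' uniformly over the 20 amino acids, and an "extreme" third-position
#' frequency sampler (sparse symmetric Dirichlet, alpha = 0.3) chosen so that
#' a 1000-draw panel covers both near-vertex and near-uniform compositions.
#'
#' @slot nSequences number of sequences (default 1000).
#' @slot nCodons codons per sequence (default 3334).
#' @slot seed RNG seed.
#' @slot strategy "extreme", "dirichlet" or "fixed".
#' @slot alpha Dirichlet concentration (strategies extreme/dirichlet).
#' @slot fixed fixed frequency 4-vector (strategy "fixed").
#' @slot aaDistribution named probability vector over the 20 amino acids
#'   (empty = uniform).
#' @export
setClass("SimulationSpec", representation(
  nSequences = "integer", nCodons = "integer", seed = "numeric",
  strategy = "character", alpha = "numeric", fixed = "numeric",
  aaDistribution = "numeric"
))

#' @rdname SimulationSpec-class
#' @param nSequences,nCodons,seed,strategy,alpha,fixed,aaDistribution see
#'   slots.
#' @export
simulationSpec <- function(nSequences = 1000L, nCodons = 3334L,
                           seed = NA_real_,
                           strategy = c("extreme", "dirichlet", "fixed"),
                           alpha = 0.3, fixed = NULL,
                           aaDistribution = NULL) {
  strategy <- match.arg(strategy)
  stopifnot(nSequences >= 1L, nCodons >= 1L)
  if (alpha <= 0) stop("domain error: alpha must be positive")
  new("SimulationSpec", nSequences = as.integer(nSequences),
      nCodons = as.integer(nCodons), seed = as.numeric(seed),
      strategy = strategy, alpha = alpha,
      fixed = if (is.null(fixed)) numeric(0) else as.numeric(fixed),
      aaDistribution = if (is.null(aaDistribution)) numeric(0)
                       else aaDistribution)
}

#' Sample a third-position nucleotide frequency vector
#'
#' The \code{"extreme"} strategy draws from a sparse symmetric Dirichlet
#' (default alpha = 0.3), so that a panel of draws covers the theoretically
#' possible composition range, from near-uniform to near-vertex;
#' \code{"dirichlet"} is the same law with a caller-chosen alpha;
#' \code{"fixed"} returns the supplied vector unchanged.
#'
#' @param strategy \code{"extreme"}, \code{"dirichlet"} or \code{"fixed"}.
#' @param alpha Dirichlet concentration parameter (> 0).
#' @param fixed frequency 4-vector over A,C,G,T for strategy "fixed".
#' @return a [FrequencyVector-class] over A, C, G, T.
#' @export
sampleThirdPositionFrequencies <- function(strategy = c("extreme",
                                                        "dirichlet",
                                                        "fixed"),
                                           alpha = 0.3, fixed = NULL) {
  strategy <- match.arg(strategy)
  if (strategy == "fixed") {
    if (is.null(fixed) || length(fixed) != 4L)
      stop("strategy 'fixed' needs a frequency 4-vector")
    return(frequencyVector(as.numeric(fixed), states = NUCS,
                           normalize = TRUE))
  }
  if (alpha <= 0) stop("domain error: alpha must be positive")
  g <- rgamma(4L, shape = alpha)
  while (sum(g) == 0) g <- rgamma(4L, shape = alpha)
  frequencyVector(g / sum(g), states = NUCS)
}

.aaProbs <- function(aaDistribution, code) {
  aas <- names(geneticCodeFamilies(code, "enc"))
  if (length(aaDistribution) == 0L)
    return(setNames(rep(1 / length(aas), length(aas)), aas))
  if (!all(names(aaDistribution) %in% aas))
    stop("aaDistribution has unknown amino-acid symbols")
  p <- setNames(numeric(length(aas)), aas)
  p[names(aaDistribution)] <- aaDistribution
  if (sum(p) <= 0) stop("aaDistribution must have positive mass")
  p / sum(p)
}

#' Generate a random coding sequence with controlled third-position content
#'
#' Amino acids are drawn i.i.d. from \code{aaDistribution} (uniform over the
#' 20 amino acids by default). Within each synonymous family the codon is
#' chosen with probability proportional to the target third-position
#' frequency of its third base (restricted and renormalised to the family's
#' allowed set); for a 6-fold amino acid this makes the third base follow the
#' target exactly conditional on the sub-family. A family whose allowed set
#' carries zero target mass falls back to the uniform distribution over its
#' codons (with a message). No stop codons are produced.
#'
#' @param nCodons number of codons (>= 1).
#' @param thirdFreqs a [FrequencyVector-class] (or numeric 4-vector) of
#'   target third-position frequencies over A, C, G, T.
#' @param aaDistribution optional named probability vector over amino acids.
#' @param pairBias23 optional named multipliers on the codon weight by the
#'   codon's own position 2-3 dinucleotide, e.g. \code{c(CG = 0.05)} plants a
#'   CpG depletion acting only at codon positions 2-3.
#' @param id sequence label.
#' @param code a [GeneticCode-class].
#' @return a [CodingSequence-class] of length \code{3 * nCodons} nt.
#' @examples
#' set.seed(1)
#' x <- generateRandomCds(3334, c(A = .25, C = .25, G = .25, T = .25))
#' nchar(ntSequence(x)) # 10002
#' @export
generateRandomCds <- function(nCodons, thirdFreqs, aaDistribution = NULL,
                              pairBias23 = NULL,
                              id = "sim", code = standardGeneticCode()) {
  stopifnot(nCodons >= 1L)
  tf <- if (is(thirdFreqs, "FrequencyVector")) freqs(thirdFreqs)
        else setNames(as.numeric(thirdFreqs), NUCS)
  tf <- tf[NUCS]
  if (anyNA(tf) || any(tf < 0)) stop("invalid third-position frequencies")
  aaP <- .aaProbs(aaDistribution, code)
  fams <- geneticCodeFamilies(code, "enc")

  # per amino acid: member codons and their target-derived weights
  famCodons <- lapply(fams, function(f) f$codons)
  famWeights <- lapply(fams, function(f) {
    w <- tf[substr(f$codons, 3, 3)]
    if (!is.null(pairBias23)) {
      d23 <- substr(f$codons, 2, 3)
      hit <- match(d23, names(pairBias23))
      w <- w * ifelse(is.na(hit), 1, pairBias23[hit])
    }
    if (sum(w) == 0) {
      message("zero target mass for family ", f$aa,
              "; falling back to uniform codon choice")
      w <- rep(1, length(f$codons))
    }
    unname(w / sum(w))
  })

  aas <- sample(names(aaP), nCodons, replace = TRUE, prob = aaP)
  cod <- character(nCodons)
  for (a in unique(aas)) {
    sel <- which(aas == a)
    cods <- famCodons[[a]]
    cod[sel] <- if (length(cods) == 1L) cods else
      cods[sample.int(length(cods), length(sel), replace = TRUE,
                      prob = famWeights[[a]])]
  }
  .newCds(cod, aas, id)
}

#' Generate the simulated-sequence panel
#'
#' Draws \code{nSequences} coding sequences, each with an independently
#' sampled third-position target frequency vector, reproducibly from the
#' seed. The per-sequence targets are attached as the \code{"targets"}
#' attribute (a 4-column matrix).
#'
#' @param spec a [SimulationSpec-class].
#' @param code a [GeneticCode-class].
#' @return list of [CodingSequence-class] objects with attribute
#'   \code{"targets"}.
#' @examples
#' panel <- generatePanel(simulationSpec(nSequences = 5, nCodons = 100,
#'                                       seed = 1))
#' length(panel) # 5
#' @export
generatePanel <- function(spec = simulationSpec(),
                          code = standardGeneticCode()) {
  stopifnot(is(spec, "SimulationSpec"))
  if (!is.na(spec@seed)) set.seed(spec@seed)
  targets <- matrix(NA_real_, spec@nSequences, 4L,
                    dimnames = list(NULL, NUCS))
  out <- vector("list", spec@nSequences)
  for (i in seq_len(spec@nSequences)) {
    tf <- sampleThirdPositionFrequencies(spec@strategy, spec@alpha,
                                         if (spec@strategy == "fixed")
                                           spec@fixed else NULL)
    targets[i, ] <- freqs(tf)
    out[[i]] <- generateRandomCds(spec@nCodons, tf,
                                  aaDistribution =
                                    if (length(spec@aaDistribution))
                                      spec@aaDistribution else NULL,
                                  id = sprintf("sim_%04d", i), code = code)
  }
  attr(out, "targets") <- targets
  out
}
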