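#' Synonymous third-position sites of a coding sequence
#'
#' One record per codon (stops never occur inside a [CodingSequence-class]),
#' giving the 6-fold-split synonymous family, the set of third-position
#' nucleotides allowed by that family, the current third-position base, and
#' the flanking context used by the dinucleotide-preserving shuffles: the
#' codon's own position-2 base and the next codon's position-1 base (NA for
#' the final codon). Met and Trp sites are non-degenerate and are excluded
#' from every shuffle pool. Because 6-fold amino acids are split into 2- and
#' 4-fold sub-families, positions 1-2 are constant within every family, so
#' only position 3 ever moves.
#'
#' @param cds a [CodingSequence-class].
#' @param code a [GeneticCode-class].
#' @return data.frame with columns \code{codonIndex} (1-based),
#'   \code{familyId}, \code{aa}, \code{n2}, \code{n3}, \code{n1Next},
#'   \code{allowedThird} (collapsed string) and \code{degenerate}.
#' @examples
#' extractSites(codingSequence("TTTAAA")) # Phe {C,T}, Lys {A,G}
#' @export
extractSites <- function(cds, code = standardGeneticCode()) {
  cod <- codons(cds)
  n <- length(cod)
  fam <- unname(code@codonToShuffleFamily[cod])
  fams <- geneticCodeFamilies(code, "shuffle")
  allowed <- vapply(fams, function(f) paste(f$allowedThird, collapse = ""),
                    character(1))
  data.frame(
    codonIndex = seq_len(n),
    familyId = fam,
    aa = strsplit(aaSequence(cds), "")[[1]],
    n2 = substr(cod, 2, 2),
    n3 = substr(cod, 3, 3),
    n1Next = c(substr(cod[-1L], 1, 1), NA_character_),
    allowedThird = unname(allowed[fam]),
    degenerate = nchar(unname(allowed[fam])) > 1L
  )
}

#' Shuffle replicate specification
#'
#' @slot mode one of "GC3", "N3", "DN23", "DN31", "DN231".
#' @slot replicates number of shuffled replicates (default 1000).
#' @slot seed RNG seed (NA = use current RNG state).
#' @slot swapSweeps swap attempts per eligible site per replicate.
#' @slot method "swap" (default), or for N3 also "pool"/"randomize".
#' @slot threshold ENC-difference significance threshold.
#' @slot keepReplicates retain per-replicate ENC values.
#' @export
setClass("ShuffleSpec", representation(
  mode = "character", replicates = "integer", seed = "numeric",
  swapSweeps = "integer", method = "character", threshold = "numeric",
  keepReplicates = "logical"
))

SHUFFLE_MODES <- c("GC3", "N3", "DN23", "DN31", "DN231")

#' @rdname ShuffleSpec-class
#' @param mode,replicates,seed,swapSweeps,method,threshold,keepReplicates
#'   see slots.
#' @export
shuffleSpec <- function(mode, replicates = 1000L, seed = NA_real_,
                        swapSweeps = 10L, method = "swap", threshold = 1.0,
                        keepReplicates = FALSE) {
  mode <- match.arg(toupper(mode), SHUFFLE_MODES)
  stopifnot(replicates >= 1L, swapSweeps >= 1L)
  new("ShuffleSpec", mode = mode, replicates = as.integer(replicates),
      seed = as.numeric(seed), swapSweeps = as.integer(swapSweeps),
      method = method, threshold = threshold,
      keepReplicates = keepReplicates)
}

# ---- internal shuffle context ------------------------------------------

# Precomputes everything reusable across replicates: degenerate-site vectors
# (integer-coded third base, allowed-base matrix, context keys) and the
# codon-count bookkeeping needed to score ENC without rebuilding strings.
.shuffleContext <- function(cds, code = standardGeneticCode()) {
  cod <- codons(cds)
  n <- length(cod)
  fam <- unname(code@codonToShuffleFamily[cod])
  fams <- geneticCodeFamilies(code, "shuffle")
  allowedStr <- vapply(fams, function(f) paste(f$allowedThird, collapse = ""),
                       character(1))[fam]
  deg <- nchar(allowedStr) > 1L
  idx <- which(deg)
  ns <- length(idx)

  third <- match(substr(cod, 3, 3), NUCS)
  n3 <- third[idx]
  allowedM <- matrix(FALSE, ns, 4L)
  for (b in 1:4)
    allowedM[, b] <- grepl(NUCS[b], allowedStr[idx], fixed = TRUE)
  n2 <- match(substr(cod[idx], 2, 2), NUCS)
  nxt <- idx + 1L
  n1next <- ifelse(nxt <= n, match(substr(cod[pmin(nxt, n)], 1, 1), NUCS), 0L)
  n1next[idx == n] <- 0L   # final codon: no 3-1 context

  sense <- senseCodons(code)
  prefix <- substr(cod[idx], 1, 2)
  codonIdMat <- matrix(NA_integer_, ns, 4L)
  for (b in 1:4)
    codonIdMat[, b] <- match(paste0(prefix, NUCS[b]), sense)
  staticCounts <- tabulate(match(if (ns > 0L) cod[-idx] else cod, sense),
                           nbins = length(sense))

  list(cds = cds, code = code, cod = cod, idx = idx, ns = ns, n3 = n3,
       allowedM = allowedM, n2 = n2, n1next = n1next,
       codonIdMat = codonIdMat, staticCounts = staticCounts, sense = sense)
}

# one sweep = one random disjoint pairing of all eligible sites, i.e. one
# swap attempt per site; each pair passes a 1/2 lazy gate (keeps the chain
# aperiodic) and a mode-specific compatibility test
.swapSweeps <- function(n3, allowedM, sweeps, key = NULL) {
  ns <- length(n3)
  if (ns < 2L) return(n3)
  m <- ns %/% 2L
  for (sw in seq_len(sweeps)) {
    perm <- sample.int(ns)
    i <- perm[seq_len(m)]
    j <- perm[m + seq_len(m)]
    ok <- runif(m) < 0.5
    ok <- ok & allowedM[cbind(i, n3[j])] & allowedM[cbind(j, n3[i])]
    if (!is.null(key)) ok <- ok & key[i] == key[j]
    if (any(ok)) {
      ii <- i[ok]; jj <- j[ok]
      tmp <- n3[ii]; n3[ii] <- n3[jj]; n3[jj] <- tmp
    }
  }
  n3
}

# constrained redistribution of a third-position pool: most-constrained sites
# first (random order within a constraint level), random draw from the
# remaining pool, restart on deadlock
.redistributePool <- function(poolCounts, allowedM, maxRestarts = 100L) {
  ns <- nrow(allowedM)
  width <- rowSums(allowedM)
  for (r in seq_len(maxRestarts)) {
    pc <- poolCounts
    ord <- order(width + runif(ns))
    out <- integer(ns)
    ok <- TRUE
    for (s in ord) {
      avail <- which(allowedM[s, ] & pc > 0L)
      if (length(avail) == 0L) { ok <- FALSE; break }
      b <- if (length(avail) == 1L) avail else
        avail[sample.int(length(avail), 1L, prob = pc[avail])]
      out[s] <- b
      pc[b] <- pc[b] - 1L
    }
    if (ok) return(out)
  }
  NULL
}

.gc3Rebalance <- function(counts) {
  gc <- counts[2L] + counts[3L]
  at <- counts[1L] + counts[4L]
  newC <- gc %/% 2L + if (gc %% 2L == 1L) rbinom(1L, 1L, 0.5) else 0L
  newA <- at %/% 2L + if (at %% 2L == 1L) rbinom(1L, 1L, 0.5) else 0L
  c(newA, newC, gc - newC, at - newA)   # A, C, G, T
}

# core: returns the new integer third-base vector for the degenerate sites
.shuffleThirds <- function(ctx, mode, sweeps, method = "swap") {
  n3 <- ctx$n3
  if (ctx$ns == 0L) return(n3)
  if (mode == "DN23")
    return(.swapSweeps(n3, ctx$allowedM, sweeps, key = ctx$n2))
  if (mode == "DN31")
    return(.swapSweeps(n3, ctx$allowedM, sweeps, key = ctx$n1next))
  if (mode == "DN231")
    return(.swapSweeps(n3, ctx$allowedM, sweeps,
                       key = ctx$n2 * 5L + ctx$n1next))
  if (mode == "N3") {
    if (method == "swap")
      return(.swapSweeps(n3, ctx$allowedM, sweeps))
    if (method == "pool") {
      out <- .redistributePool(tabulate(n3, 4L), ctx$allowedM)
      if (is.null(out)) {
        warning("infeasible pool redistribution; returning identity")
        return(n3)
      }
      return(out)
    }
    if (method == "randomize") {
      # generate-to-target-frequencies comparison mode: i.i.d. draws from the
      # pool frequencies restricted to each site's allowed set
      pf <- tabulate(n3, 4L)
      out <- integer(ctx$ns)
      for (s in seq_len(ctx$ns)) {
        w <- pf * ctx$allowedM[s, ]
        if (sum(w) == 0) w <- as.numeric(ctx$allowedM[s, ])
        out[s] <- sample.int(4L, 1L, prob = w)
      }
      return(out)
    }
    stop("unknown method '", method, "' for mode N3")
  }
  if (mode == "GC3") {
    target <- .gc3Rebalance(tabulate(n3, 4L))
    out <- .redistributePool(target, ctx$allowedM)
    if (is.null(out)) {
      warning("infeasible pool redistribution under GC3 rebalancing; ",
              "returning identity arrangement")
      return(n3)
    }
    # extra swap mixing on top of the greedy redistribution
    return(.swapSweeps(out, ctx$allowedM, sweeps))
  }
  stop("unknown shuffle mode '", mode, "'")
}

.rebuildCds <- function(ctx, n3new) {
  cod <- ctx$cod
  if (ctx$ns > 0L)
    cod[ctx$idx] <- paste0(substr(cod[ctx$idx], 1, 2), NUCS[n3new])
  .newCds(cod, strsplit(aaSequence(ctx$cds), "")[[1]], seqId(ctx$cds))
}

#' Constraint-preserving synonymous shuffling
#'
#' Rearranges third-position nucleotides among synonymous sites without ever
#' changing the encoded protein or codon positions 1-2. The mode determines
#' which composition table is preserved exactly:
#' \describe{
#'   \item{N3}{the multiset of third-position nucleotides (genomic
#'     mononucleotide frequencies at position 3).}
#'   \item{GC3}{the third-position pool is first rebalanced so that G = C and
#'     A = T (combined GC3 preserved, individual bases not; an odd count is
#'     resolved by a fair coin), then redistributed like N3.}
#'   \item{DN23}{the joint counts of (position-2, position-3) dinucleotides.}
#'   \item{DN31}{the joint counts of (position-3, next codon's position-1)
#'     dinucleotides; the final codon, which has no 3-1 context, stays put so
#'     that every existing junction count is conserved exactly.}
#'   \item{DN231}{both the 2-3 and the 3-1 tables simultaneously.}
#' }
#' All modes run as seeded random pairwise swaps between compatible sites
#' (disjoint random pairings with a lazy acceptance gate), which guarantees
#' every conservation contract exactly. For N3 a pool-and-redistribute
#' variant (\code{method = "pool"}) and a generate-to-target-frequencies
#' comparison mode (\code{method = "randomize"}, which preserves frequencies
#' only in expectation) are also available. GC3 necessarily goes through the
#' pool: if the rebalanced pool cannot be redistributed (after 100 restarts)
#' the identity arrangement is returned with a warning, never an invalid
#' sequence.
#'
#' @param cds a [CodingSequence-class].
#' @param mode one of \code{"GC3"}, \code{"N3"}, \code{"DN23"},
#'   \code{"DN31"}, \code{"DN231"}.
#' @param swapSweeps swap attempts per eligible site (default 10).
#' @param method \code{"swap"}, \code{"pool"} or \code{"randomize"}
#'   (the latter two for N3 only).
#' @param code a [GeneticCode-class].
#' @return a shuffled [CodingSequence-class] translating to the same protein.
#' @examples
#' set.seed(1)
#' x <- codingSequence("TTTTTCAAAAAG")
#' y <- shuffleSynonymous(x, "N3")
#' aaSequence(y) == aaSequence(x)              # always TRUE
#' sort(positionalNucleotideCounts(y, 3)) ==
#'   sort(positionalNucleotideCounts(x, 3))   # N3 conservation
#' @export
shuffleSynonymous <- function(cds, mode = SHUFFLE_MODES, swapSweeps = 10L,
                              method = c("swap", "pool", "randomize"),
                              code = standardGeneticCode()) {
  mode <- match.arg(toupper(mode[1L]), SHUFFLE_MODES)
  method <- match.arg(method)
  if (method != "swap" && !(mode %in% c("N3", "GC3")))
    stop("method '", method, "' is only available for mode N3")
  ctx <- .shuffleContext(cds, code)
  .rebuildCds(ctx, .shuffleThirds(ctx, mode, swapSweeps, method))
}

#' Replicate summary of shuffled-null ENC
#'
#' @slot mode shuffle mode.
#' @slot encOriginal ENC of the input sequence.
#' @slot encMean,encSd mean and sample standard deviation (n - 1 denominator)
#'   of ENC over the shuffled replicates.
#' @slot call the [SignificanceCall-class] on shuffled mean vs original.
#' @slot encValues per-replicate ENC values (empty unless requested).
#' @slot replicates number of replicates.
#' @export
setClass("ReplicateSummary", representation(
  mode = "character", encOriginal = "numeric", encMean = "numeric",
  encSd = "numeric", call = "SignificanceCall", encValues = "numeric",
  replicates = "integer"
))

#' @rdname ReplicateSummary-class
#' @param object a \code{ReplicateSummary}.
#' @export
summaryRow <- function(object) {
  data.frame(mode = object@mode,
             enc_original = object@encOriginal,
             enc_mean = object@encMean,
             enc_sd = object@encSd,
             delta = object@call@delta,
             significant = object@call@significant)
}

setMethod("show", "ReplicateSummary", function(object) {
  cat("ReplicateSummary [", object@mode, "], R = ", object@replicates,
      "\n  ENC original ", format(object@encOriginal, digits = 6),
      ", shuffled mean ", format(object@encMean, digits = 6),
      " (sd ", format(object@encSd, digits = 3), "), delta ",
      format(object@call@delta, digits = 4),
      if (object@call@significant) " *significant*" else "", "\n", sep = "")
})

#' Run shuffled replicates and summarise ENC
#'
#' Generates \code{replicates} independent shuffles of \code{cds} (each
#' starting from the original arrangement), computes the corrected-estimator
#' ENC of each, and summarises mean, sample standard deviation and the
#' ENC-difference significance call. Fully reproducible from the seed in the
#' spec.
#'
#' @param cds a [CodingSequence-class].
#' @param spec a [ShuffleSpec-class].
#' @param code a [GeneticCode-class].
#' @return a [ReplicateSummary-class].
#' @examples
#' x <- codingSequence(paste(rep(c("TTT", "TTC", "AAA", "GGA", "GGC",
#'                                 "ATT", "ATC", "CTG"), 10), collapse = ""))
#' runShuffleReplicates(x, shuffleSpec("N3", replicates = 50, seed = 1))
#' @export
runShuffleReplicates <- function(cds, spec, code = standardGeneticCode()) {
  stopifnot(is(spec, "ShuffleSpec"))
  if (!is.na(spec@seed)) set.seed(spec@seed)
  ctx <- .shuffleContext(cds, code)
  enc0 <- encValue(encFromCounts(
    setNames(ctx$staticCounts +
               tabulate(ctx$codonIdMat[cbind(seq_len(ctx$ns), ctx$n3)],
                        nbins = length(ctx$sense)), ctx$sense),
    estimator = "corrected", code = code))
  encs <- numeric(spec@replicates)
  for (r in seq_len(spec@replicates)) {
    n3new <- .shuffleThirds(ctx, spec@mode, spec@swapSweeps, spec@method)
    counts <- ctx$staticCounts +
      tabulate(ctx$codonIdMat[cbind(seq_len(ctx$ns), n3new)],
               nbins = length(ctx$sense))
    encs[r] <- encValue(encFromCounts(setNames(counts, ctx$sense),
                                      estimator = "corrected", code = code))
  }
  m <- mean(encs)
  s <- if (spec@replicates > 1L) sd(encs) else 0
  new("ReplicateSummary", mode = spec@mode, encOriginal = enc0,
      encMean = m, encSd = s,
      call = classifyEncDifference(enc0, m, spec@threshold),
      encValues = if (spec@keepReplicates) encs else numeric(0),
      replicates = spec@replicates)
}
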