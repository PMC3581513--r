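# Independent oracles, coded directly from first principles (and from
# Biostrings' genetic code table, not from the package's bookkeeping).

NUC4 <- c("A", "C", "G", "T")
DINUC16 <- as.vector(outer(NUC4, NUC4, paste0))

# amino-acid families straight from Biostrings::GENETIC_CODE
.oracleFamilies <- local({
  tab <- Biostrings::GENETIC_CODE
  sense <- names(tab)[tab != "*"]
  split(sense, tab[sense])
})

# brute-force Wright ENC from a named codon-count vector; same conventions
# as the package contract (n<=1 or F<=0 families dropped, missing 3-fold
# class interpolated from classes 2 and 4, cap at 61), but coded
# independently as plain loops
bruteEnc <- function(counts, estimator = "corrected") {
  fs <- list(); cls <- c()
  for (aa in names(.oracleFamilies)) {
    cods <- .oracleFamilies[[aa]]
    if (length(cods) < 2) next
    n <- sum(counts[cods], na.rm = TRUE)
    if (n <= 1) next
    p <- rep(0, length(cods)); names(p) <- cods
    for (cd in cods) if (cd %in% names(counts)) p[cd] <- counts[cd] / n
    sp2 <- sum(p^2)
    f <- if (estimator == "corrected") (n * sp2 - 1) / (n - 1) else sp2
    if (f <= 0) next
    fs <- c(fs, f); cls <- c(cls, length(cods))
  }
  fs <- unlist(fs)
  fbar <- function(k) if (any(cls == k)) mean(fs[cls == k]) else NA_real_
  f2 <- fbar(2); f3 <- fbar(3); f4 <- fbar(4); f6 <- fbar(6)
  if (is.na(f3) && !is.na(f2) && !is.na(f4)) f3 <- (f2 + f4) / 2
  if (any(is.na(c(f2, f3, f4, f6)))) return(NA_real_)
  min(2 + 9 / f2 + 1 / f3 + 5 / f4 + 3 / f6, 61)
}

# brute-force positional dinucleotide frequencies by scanning the raw
# nucleotide string at fixed offsets (1-based): pair 23 reads (3k+2, 3k+3),
# pair 31 reads (3k+3, 3k+4)
bruteDinucFreqs <- function(nt, pair) {
  n <- nchar(nt)
  starts <- if (pair == "23") seq(2, n - 1, by = 3) else {
    s <- seq(3, n - 1, by = 3)
    s[s + 1 <= n]
  }
  d <- vapply(starts, function(i) substr(nt, i, i + 1), character(1))
  tab <- table(factor(d, levels = DINUC16))
  as.numeric(tab) / sum(tab)
}

# random in-frame stop-free CDS with a random (moderately skewed) codon law
randomTestCds <- function(nCodons, id = "rnd") {
  sense <- senseCodons()
  w <- rgamma(length(sense), shape = 1)
  codingSequence(paste(sample(sense, nCodons, replace = TRUE,
                              prob = w / sum(w)), collapse = ""), id = id)
}

# exhaustive distinct feasible third-position arrangements of a toy CDS
# under the family allowed-set constraint (N3-type feasibility)
enumerateArrangements <- function(cds) {
  s <- extractSites(cds)
  s <- s[s$degenerate, ]
  allowed <- strsplit(s$allowedThird, "")
  pool <- s$n3
  out <- new.env(parent = emptyenv())
  recurse <- function(assigned, left) {
    if (length(left) == 0) {
      assign(paste(assigned, collapse = ""), TRUE, envir = out)
      return(invisible())
    }
    i <- length(assigned) + 1L
    for (b in unique(left)) {
      if (b %in% allowed[[i]])
        recurse(c(assigned, b), left[-match(b, left)])
    }
  }
  recurse(character(0), pool)
  ls(out)
}

degenerateThirds <- function(cds) {
  s <- extractSites(cds)
  paste(s$n3[s$degenerate], collapse = "")
}

# count-table conservation checks used across shuffle tests
conservationChecks <- function(x, y) {
  list(
    aa = identical(aaSequence(x), aaSequence(y)),
    p12 = identical(substr(codons(x), 1, 2), substr(codons(y), 1, 2)),
    n3 = identical(positionalNucleotideCounts(x, 3),
                   positionalNucleotideCounts(y, 3)),
    d23 = identical(positionalDinucleotideCounts(x, "23"),
                    positionalDinucleotideCounts(y, "23")),
    d31 = identical(positionalDinucleotideCounts(x, "31"),
                    positionalDinucleotideCounts(y, "31")),
    gc3 = abs(sum(positionalNucleotideCounts(y, 3)[c("C", "G")]) -
              sum(positionalNucleotideCounts(x, 3)[c("C", "G")])) <= 1
  )
}

# fixture CDS: all 20 amino acids, one fixed codon each (maximal bias)
oneCodonPerAaCds <- function(copies = 10) {
  fams <- geneticCodeFamilies(standardGeneticCode(), "enc")
  one <- vapply(fams, function(f) f$codons[1], character(1))
  codingSequence(paste(rep(one, each = copies), collapse = ""), id = "onecod")
}

# fixture CDS: every sense codon used equally often (no bias)
allCodonsEqualCds <- function(copies = 1) {
  codingSequence(paste(rep(senseCodons(), copies), collapse = ""),
                 id = "equal61")
}
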