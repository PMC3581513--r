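---
title: "Dissecting codon usage bias with constraint-preserving shuffles"
author: "codonShuffle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting codon usage bias with constraint-preserving shuffles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codonShuffle)
```

## The question

Synonymous codons are not used evenly. This codon usage bias (CUB) can come
from *mutational pressure* — the genome's mono- and dinucleotide composition,
which constrains what third positions can look like regardless of translation
— or from *translational pressure*, selection on codon choice tied to the
host's tRNA pools. RNA virus genomes are a sharp test case: their composition
is often strongly skewed (CpG suppression is near universal), their hosts'
tRNA statistics are usually unknown, and their coding density leaves little
neutral sequence.

The package's strategy is the null-model one. Take a real coding sequence,
hold the protein fixed, and rearrange synonymous third positions while
*exactly* preserving a chosen composition table. If the effective number of
codons (ENC) of the shuffled sequences matches the original, that table fully
explains the observed bias; if the shuffled ENC is systematically higher, a
residual bias exists that the preserved feature cannot account for.

## The ENC statistic

For each amino-acid family with $n$ codon occurrences and within-family codon
frequencies $p_i$, the homozygosity is estimated either in Wright's corrected
form

$$\hat F = \frac{n\sum_i p_i^2 - 1}{n - 1}$$

(the default; unbiased for small $n$) or as the plain frequency form
$F = \sum_i p_i^2$ (which makes the equal-use limit exact). Class means
$\bar F_k$ over families of degeneracy $k$ combine as

$$\mathrm{ENC} = 2 + \frac{9}{\bar F_2} + \frac{1}{\bar F_3} +
\frac{5}{\bar F_4} + \frac{3}{\bar F_6},$$

ranging from 20 (one codon per amino acid) to 61 (all codons equal). Two
conventions matter and are worth stating:

* **Families with $n \le 1$, or a non-positive $\hat F$, carry no
  information** and are dropped from their class mean. An absent 3-fold class
  (isoleucine) is interpolated as the average of the 2- and 4-fold means;
  any other absent class leaves ENC undefined, which the package reports as
  an error rather than a number.
* **Leu, Ser and Arg are scored as whole 6-fold families for ENC**, but are
  split into independent 2-fold (UUR, AGY, AGR) and 4-fold (CUN, UCN, CGN)
  sub-families for *shuffling*, so that codon positions 1–2 are constant
  within every shuffle family and only position 3 ever moves. The two
  conventions coexist deliberately: the first matches how ENC is classically
  computed, the second is what makes protein-preserving third-position
  rearrangement well defined.

The corrected estimator sits slightly above the frequency form for finite
sequences, so unbiased long sequences can exceed 61 before capping; values
above 61 are reported as 61 with a `capped` flag, and 20 is the floor of the
scale.

Wright's closed-form expectation $\mathrm{ENC}(s) = 2 + s + 29/(s^2 +
(1-s)^2)$, with $s$ the third-position GC fraction, is provided as
`wrightExpectedEnc()`. Note that it is an *approximation*: sequences built
from balanced G=C, A=T compositions can exceed it by up to roughly 1.4 ENC
units around $s \approx 0.3$ even in the infinite-length limit, and it is not
symmetric in $s \mapsto 1-s$ (the linear $+s$ term contributes a one-unit
difference between the AT-rich and GC-rich extremes).

## The five shuffling algorithms

All shuffles operate on the synonymous third-position sites extracted by
`extractSites()` (Met and Trp are excluded; stop codons never occur inside a
validated `CodingSequence`). Each mode preserves, exactly:

| mode | preserved table |
|------|-----------------|
| `N3` | third-position mononucleotide counts |
| `GC3` | combined third-position G+C (G and C individually rebalanced to equality) |
| `DN23` | joint (position-2, position-3) dinucleotide counts |
| `DN31` | joint (position-3, next position-1) dinucleotide counts |
| `DN231` | both dinucleotide tables simultaneously |

The engine is a seeded random-transposition chain: each sweep draws a random
disjoint pairing of eligible sites and swaps the third-position bases of a
pair when (i) a fair-coin lazy gate accepts, (ii) each base is allowed in the
other site's family, and (iii) the mode's context matches (equal position-2
base for `DN23`, equal next-position-1 base for `DN31`, both for `DN231`).
Swaps trivially guarantee every conservation contract, cannot deadlock, and
the lazy gate makes the chain aperiodic; its stationary law is uniform over
the reachable arrangements. The default of 10 sweeps (one swap attempt per
site per sweep) decorrelates the summary statistic well; for small toys where
all feasible arrangements can be enumerated, we verify uniformity by
chi-square after a longer mixing run (60 sweeps), since at 10 sweeps a
residual imprint of the starting arrangement is still statistically
detectable with ten thousand draws.

Two design points deserve a note:

* **GC3 cannot be a pure swap scheme**, because swaps preserve individual
  base counts. It is implemented as pool rebalancing (set #G = #C and
  #A = #T, odd totals resolved by a fair coin) followed by a
  most-constrained-first random redistribution with restart on deadlock (at
  most 100 restarts), then swap mixing. If the rebalanced pool is infeasible
  — e.g. a sequence whose degenerate sites are all purine-only families —
  the identity arrangement is returned with a warning, never an invalid
  sequence.
* **The final codon has no 3-1 context.** Any swap that moved its third base
  into an interior site would alter an existing junction count, so under
  `DN31`/`DN231` the final site stays put. This is the only arrangement
  freedom given up for exact conservation.

For `N3` a pool-and-redistribute variant (`method = "pool"`) and a
generate-to-target-frequencies comparison mode (`method = "randomize"`,
preserving counts only in expectation) are available; shuffling is the
default because it conserves counts exactly and yields tighter replicate
distributions.

`runShuffleReplicates()` repeats a mode `replicates` times (default 1000,
each replicate restarted from the original arrangement), reports the mean
and sample standard deviation (n − 1 denominator) of ENC, and calls the
difference significant when |shuffled mean − original| strictly exceeds 1
ENC unit. That threshold, rather than a formal test, reflects that replicate
standard deviations are a few tenths of an ENC unit, so any formal test
would flag biologically negligible differences at large replicate counts.

## Relative dinucleotide bias and composition variance

`relativeDinucleotideBias()` compares observed dinucleotide frequencies at a
codon-position pair against the product of the positional mononucleotide
frequencies (for CpG at pair 2-3: $f(C_2) \times f(G_3)$). Entries with zero
expectation are reported as undefined (`NA`), never as zero. Pair 3-1 spans
the codon boundary, so the final codon contributes no observation; a
concatemer is treated as one continuous CDS, so pair 3-1 dinucleotides do
span ORF junctions.

Composition vectors are summarised by their variance around uniformity,
$\frac{1}{n}\sum_i (x_i - 1/n)^2$, with $n$ the number of states (2 for GC
content, 4 for mononucleotides, 16 for dinucleotides). The $1/n$
normalisation is a fixed convention; any positive constant would leave every
ordering used in the analyses unchanged. The statistic is zero iff the
vector is uniform, permutation-invariant, and maximal (0.1875 for $n = 4$)
at a vertex of the simplex.

## The simulated panel

`generatePanel()` reproduces the composition-sweep experiment: by default
1000 sequences of 3334 codons (10002 nt), each built from an independently
drawn third-position target frequency vector. Amino acids are uniform over
the 20 by default (`aaDistribution` accepts any probability vector for,
e.g., virus-like compositions). Within a family, codons are weighted by the
target frequency of their third base, restricted and renormalised to the
family's allowed set; conditional on a 4-fold (sub-)family the third base
therefore follows the target exactly, which is what the parameter-recovery
test checks at ±0.02 with ten thousand codons. Families with zero target
mass fall back to uniform codon choice with a message. An optional
`pairBias23` multiplier plants dinucleotide pressure (e.g. `c(CG = 0.05)`)
acting only at codon positions 2-3 — the synthetic analogue of CpG
suppression, used to validate the comparison analyses and the null ordering.

The "extreme" target sampler is a symmetric Dirichlet with $\alpha = 0.3$,
calibrated once so that in a 1000-draw panel at least 5% of draws are
near-vertex (max component > 0.9) and at least 5% near-balanced (max < 0.5).
Two caveats about what the panel does and does not emulate:

* The relation between ENC and composition is tight against the *generating*
  composition (Spearman $\rho \approx -0.96$ against the target-frequency
  variance). Realized per-sequence third-position frequencies are a distorted
  image of the target — a 2-fold purine family can only realize A or G — so
  correlations computed on realized composition are weaker ($\rho \approx
  -0.86$). The package reports the targets alongside the panel for exactly
  this reason.
* Under this sampling law, draws balanced enough to push ENC above ~58 are
  rare (roughly 2 per 1000 at infinite length), so the panel's observed
  maximum hovers near 57–58 and should not be treated as a sharp invariant.
  The minimum reliably falls below 35: strong bias is reachable at *any* GC
  content, which is the point of the exercise — total GC is a poor
  descriptor of composition-driven CUB.

Panel sequences are i.i.d. draws; no substitution process, no secondary
structure, no translational selection. Passing tests on the panel therefore
demonstrate the statistics and the nulls, not any claim about real viral
evolution; real sequences carry correlations (e.g. local RNA structure) that
the shuffles deliberately destroy and the simulator never creates.

## Comparative analyses

`cpgPositionalComparison()` computes per-sequence CpG RDB at pairs 2-3 and
3-1 and compares the two sets with a two-sided two-sample Student's t-test
(the classical equal-variance form by default, Welch by flag). Sequences
with an undefined CpG RDB at either pair are dropped pairwise with a message.
`aminoAcidPreferenceAnalysis()` asks whether composition reaches through the
code into the protein: Ile/Leu against third-position A content, Val/Leu
against G, the poorly interchangeable Arg/Gly pair as a negative control,
and C at positions 1+2 against C at position 3, all by Spearman correlation
with average ranks for ties.

## Input handling and concatemers

FASTA input goes through Biostrings; every record is validated (frame,
alphabet, internal stops) and failures are reported per record rather than
aborting the batch. A single terminal stop is stripped and recorded.
Ambiguity codes are rejected by default; a permissive mode drops affected
codons with a count, since every statistic here is defined over A/C/G/T
only.

Segmented or multi-ORF genomes are analysed as concatemers:
`buildConcatemer()` extracts CDS features from GenBank flat files (honouring
`join()` and strand), strips terminal stops, optionally excises regions
covered by two or more CDS features (overlapping reading frames), re-frames
each piece from its own 5' end, and validates the joined sequence — with an
optional expected-length check, which is the practical guard when
reconstructing published analysis units.

## Problem sizes and numerical choices

The shipped tests run the conservation suite on 500 random sequences of
20–200 codons across all five modes, compare ENC and dinucleotide tables
against independently coded brute-force oracles to 1e-9 on 200 random
inputs, regenerate the full default panel twice to verify byte-identical
seeding, and run the planted-bias null-ordering experiment at 600 codons
with 200 replicates per mode — sizes chosen so the whole suite completes in
a couple of minutes on one CPU while keeping every statistical assertion
comfortably powered under its fixed seed.

## Known limitations

* ENC on sequences missing a whole degeneracy class (other than Ile) is
  undefined by design; very short or compositionally extreme sequences can
  therefore error rather than return a number, and shuffled replicates of
  such sequences propagate that error.
* The greedy GC3 redistribution is not exactly uniform over feasible
  assignments (the subsequent swap mixing narrows the gap); the swap engine
  itself is uniform only over the component reachable by pairwise swaps,
  which coincided with the full feasible set in every enumerable case we
  checked.
* 6-fold degenerate codons are shuffled within their split sub-families;
  exchange *between* UUR and CUN (or AGY/UCN, AGR/CGN) would change
  positions 1–2 and is out of scope, so bias expressed through sub-family
  choice is held fixed by construction.
* No automatic sequence retrieval: GenBank records are user-supplied files.
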