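# codonShuffle

Tools for dissecting the origins of codon usage bias (CUB) in coding
sequences, built for the composition-skewed world of RNA virus genomes.

Synonymous codon choice is shaped by *mutational pressure* (the genome's
mono- and dinucleotide composition) and *translational pressure* (selection
tied to host tRNA pools). Host-independent analysis rests on Wright's
effective number of codons,

    ENC = 2 + 9/F̄₂ + 1/F̄₃ + 5/F̄₄ + 3/F̄₆,   F̂ = (nΣpᵢ² − 1)/(n − 1),

which ranges from 61 (no bias) to 20 (one codon per amino acid). To ask *how
much* of an observed ENC a given compositional feature explains, the package
shuffles synonymous third positions under progressively stronger exact
constraints, always preserving the protein:

| mode | preserved exactly |
|-------|------------------|
| `GC3` | combined third-position G+C (G/C and A/T rebalanced to equality) |
| `N3` | third-position mononucleotide counts |
| `DN23` | joint position 2-3 dinucleotide counts |
| `DN31` | joint position 3-1 (codon-boundary) dinucleotide counts |
| `DN231` | both dinucleotide tables simultaneously |

If shuffled sequences match the original ENC, the preserved table explains
the bias; a shuffled mean more than 1 ENC unit above the original flags
residual, unexplained bias. Around this core the package provides relative
dinucleotide bias (RDB = observed / expected dinucleotide frequency at codon
position pairs 2-3 and 3-1, the classic CpG-suppression readout),
composition-variance descriptors, Wright's theoretical ENC–GC₃ curve, a
simulator of random coding sequences with controlled (including extreme)
third-position composition, FASTA/GenBank input with ORF-concatemer
construction, comparative CpG and amino-acid-preference analyses, and a
command-line interface.

## Worked example

Simulate a 1200-codon sequence with skewed third-position composition
(A=0.42, C=0.18, G=0.30, T=0.10) and a planted CpG depletion acting only at
codon positions 2-3, then ask each null what it explains:

```r
library(codonShuffle)
set.seed(42)
x <- generateRandomCds(1200, c(A = .42, C = .18, G = .30, T = .10),
                       pairBias23 = c(CG = 0.05), id = "demo")
effectiveNumberOfCodons(x)
#> ENC = 47.6663 (corrected estimator)
#>   class means F: 2=0.5127  3=0.4178  4=0.4239  6=0.2155

for (m in c("GC3", "N3", "DN23", "DN231"))
  print(runShuffleReplicates(x, shuffleSpec(m, replicates = 200, seed = 1)))
#> ReplicateSummary [GC3], R = 200
#>   ENC original 47.6663, shuffled mean 55.0223 (sd 0.589), delta 7.356 *significant*
#> ReplicateSummary [N3], R = 200
#>   ENC original 47.6663, shuffled mean 51.3081 (sd 0.606), delta 3.642 *significant*
#> ReplicateSummary [DN23], R = 200
#>   ENC original 47.6663, shuffled mean 47.533 (sd 0.403), delta -0.1333
#> ReplicateSummary [DN231], R = 200
#>   ENC original 47.6663, shuffled mean 47.6929 (sd 0.263), delta 0.02665
```

Read bottom-up: preserving only GC₃ leaves 7.4 ENC units unexplained;
preserving all four mononucleotide counts still leaves 3.6; preserving the
2-3 dinucleotide table reproduces the original ENC (delta −0.13, not
significant), so mononucleotide plus 2-3 dinucleotide composition explains
essentially the entire bias of this sequence — exactly what was planted. The
RDB tables show where the dinucleotide pressure sits:

```r
rdbValues(relativeDinucleotideBias(x, "23"))[["CG"]]   # 0.065  (suppressed)
rdbValues(relativeDinucleotideBias(x, "31"))[["CG"]]   # 0.877  (untouched)
```

The same analyses run from the shell via the bundled CLI
(`exec/codonshuffle`): subcommands `stats`, `enc`, `rdb`, `shuffle`,
`simulate`, `concat`, `report`; exit codes 0 (success), 2 (validation
failure), 3 (infeasible/undefined statistic).

```sh
codonshuffle shuffle input.fasta --mode dn23 --replicates 1000 --seed 1
codonshuffle simulate --n 1000 --codons 3334 --seed 1 --out panel.fasta
```

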