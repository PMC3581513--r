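Package: codonShuffle
Title: Constraint-Preserving Synonymous Codon Shuffling and Codon Usage
    Bias Analysis
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for dissecting the mutational and translational origins
    of codon usage bias in coding sequences, with an emphasis on RNA virus
    genomes. Implements Wright's effective number of codons (ENC) with
    per-degeneracy-class homozygosity estimates, the theoretical ENC-GC3
    curve, positional relative dinucleotide bias at codon position pairs
    2-3 and 3-1, composition-variance descriptors, a family of
    constraint-preserving synonymous shuffling algorithms (GC3, N3, dN23,
    dN31, dN231) with a seeded replicate engine, and a simulator of random
    coding sequences with controlled (including extreme) third-position
    nucleotide composition. Includes FASTA and GenBank CDS input, ORF
    concatemer construction, comparative CpG and amino-acid-preference
    analyses, machine-readable reports, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: Genetics, Software, SequenceMatching, StatisticalMethod
RoxygenNote: 7.3.3
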