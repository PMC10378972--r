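Package: ctxsub
Title: Context-Dependent Substitution Analysis of Plastome Triplet Alignments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Infers tetranucleotide-context-dependent nucleotide substitution
    patterns from aligned sequence triplets (two ingroup taxa plus an
    outgroup), as used to study mutation dynamics in chloroplast genomes.
    Sites at fourfold-degenerate codon third positions and in noncoding
    regions are polarized by outgroup parsimony into ancestral/derived
    states and accumulated into per-context 4x4 count matrices, which are
    folded across complementary strands and summarized as substitution
    rates, transition:transversion ratios, Markov stationary (equilibrium)
    base compositions with bootstrap uncertainties, and CpG-transition odds
    ratios. A Gillespie-style sequence simulator with neighbor-dependent
    rates provides ground truth for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
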