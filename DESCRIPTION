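Package: pirnasv
Title: piRNA Loci, Structural-Variant Hotspots and Transposon Activity
Version: 0.1.0
Authors@R:
    person("pirnasv", "maintainers", email = "pirnasv@example.org",
           role = c("aut", "cre"))
Description: Detection of PIWI-interacting RNA (piRNA) producing loci from
    small-RNA window abundance by iterative dynamic-programming
    segmentation, structural-variant (SV) hotspot calling by Gaussian
    kernel density with permutation significance, same-chromosome
    interval-shuffling enrichment tests, ping-pong 5'-5' overlap Z-scores
    and nucleotide-periodicity spectra, consensus filtering of long-read
    SV call sets, classification and Jukes-Cantor dating of novel
    transposable-element insertions, and small-RNA abundance, diversity,
    strand-bias and expression-variance statistics.  A synthetic-data
    generator emulates avian-style genomes (macro-, intermediate- and
    micro-chromosomes), clustered SV call sets, collapsed piRNA read sets
    and transposon insertion sequences so the whole pipeline is testable
    end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
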