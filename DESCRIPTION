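Package: panrearr
Title: Core-Genome Scaffold Comparison and Repeat-Mediated Rearrangement
    Analysis for Bacterial Pan-Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds per-strain core-genome scaffolds from whole-genome
    alignment block maps, merges blocks that are consecutive in every
    strain, groups identical scaffolds, eliminates independent
    transposition, inverted transposition, block interchange and inverted
    block interchange events, computes exact minimum-inversion distances
    and scenarios between scaffolds (Hannenhalli-Pevzner breakpoint-graph
    theory), and tests whether inversion and transposition breakpoints are
    flanked by inverted or direct repeats such as IS elements.  Ships a
    seeded simulator of multi-strain bacterial genomes with planted
    repeats and repeat-mediated rearrangements so the whole analysis runs
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
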