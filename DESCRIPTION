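Package: taxlines
Title: Integrative Species Delimitation from Independent Lines of Evidence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for integrative taxonomy of allopatric (typically insular)
    populations. From per-marker sequence alignments and a typed morphological
    character matrix, the package computes three independent lines of evidence:
    representation by an independent statistical-parsimony haplotype network of
    a mitochondrial marker (95% connection limit), exclusivity of nuclear
    haplotypes with a minimum number of distinguishing substitutions, and fixed
    morphological diagnosability (qualitative state disjunction, range
    disjunction, or Amadon's 75% rule). Candidate populations are designated as
    unconfirmed/confirmed candidate species or deep conspecific lineages and
    ranked as species or subspecies within a guide clade grouping: one line of
    evidence supports subspecies rank, two or more support species rank.
    Includes uncorrected p-distance summaries with barcoding-threshold
    comparison, MANOVA with pairwise Hotelling tests and canonical variates
    analysis, and a calibrated simulator of multilocus island scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    S4Vectors,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    MASS,
    ape
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
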