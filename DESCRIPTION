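Package: pepclass
Title: Peptide Pattern Recognition for Alignment-Free Protein Family
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Clusters protein sequences into families defined by shared
    conserved hexapeptides (peptide pattern recognition), annotates
    proteins and raw genomes against group-specific peptide lists via a
    fragment/six-frame-translation scan, profiles the positional
    distribution of conserved hexapeptides and their catalytic-serine
    context, and computes global pairwise percent identity between family
    representatives. Includes a synthetic-data generator that plants
    protein families and genes with known ground truth so every stage of
    the pipeline can be benchmarked without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
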