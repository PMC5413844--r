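Package: roucela
Title: Gene-Tree Discordance and Coalescent Network Analysis of Allopolyploid Origins
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for detecting allopolyploid (hybrid) origins from
    target-enrichment phylogenomic data, built around the Mediterranean
    Campanula (Roucela) species complex as the worked system. Implements
    locus-level quality control (paralog flagging by bait-coverage fraction,
    completeness filtering), support-aware binning of gene trees into
    competing topology classes, clade and quartet concordance factors
    estimated as gene-tree frequencies, expected quartet concordance factors
    on a level-1 species network under the multispecies coalescent, and
    estimation of the inheritance probability gamma by multinomial
    pseudolikelihood on a fixed candidate network. A network multispecies
    coalescent simulator (gene trees, bootstrap-like supports, Jukes-Cantor
    alignments, bract morphometrics) makes every stage testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape (>= 5.0),
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
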