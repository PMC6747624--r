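Package: plastedit
Title: Comparative Plastid Genome Structure, Repeats and RNA-Editing Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for comparative analysis of annotated plastid (chloroplast)
    genomes: detection of the quadripartite LSC/IRb/SSC/IRa structure by
    maximal inverted-repeat search, quantification of dispersed and perfect
    tandem repeats after removal of one inverted-repeat copy, calling of
    C-to-U RNA-editing sites from RNA-seq alignments with a read-identity and
    site-support filter cascade, conservation-score prediction of editing
    sites from homolog protein panels, gene-content and intron-loss
    comparison with circular signed breakpoint distances, and detection of
    tandem peptide repeats within open reading frames. A ground-truthed
    simulator generates quadripartite plastomes, RNA-seq read alignments with
    planted edits, and homolog panels so that every stage can be exercised
    end-to-end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    IRanges,
    Rsamtools,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml,
    withr
Config/testthat/edition: 3
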