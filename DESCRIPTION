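Package: thermotrace
Title: Thermal Adaptation Signatures in Prokaryotic Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies molecular signatures of growth-temperature adaptation
    from annotated prokaryotic genomes. Computes proteome composition indices
    (CvP bias, IVYWREL fraction) on membrane-filtered predicted proteins,
    whole-genome and sliding-window G+C content, codon third-position
    composition, ribosomal RNA operon multiplicity and inter-copy identity,
    and neighbor-joining 16S rRNA phylogenies. Relates each metric to optimum
    growth temperature through linear models with residual scoring, so that
    genomes whose composition is out of step with their growth temperature --
    for example thermophile-like proteomes in mesophiles -- can be flagged.
    Includes a seeded synthetic-genome and proteome generator with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
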