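Package: pearprint
Title: SSR Fingerprinting, Ploidy Determination and Diversity Analysis for
    Clonally Propagated Germplasm
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the molecular characterization of clonally propagated
    fruit-tree germplasm collections genotyped with codominant microsatellite
    (SSR) markers. Computes per-locus and panel informativeness statistics
    (observed and effective allele numbers, observed and expected
    heterozygosity, Shannon index, polymorphism information content) and the
    panel discrimination power; resolves genotype identity via simple-matching
    similarity to detect duplicate accessions, synonymies and homonymies;
    classifies ploidy from triallelic SSR profiles and from flow-cytometry G1
    peak ratios, including propidium-iodide genome-size estimation against
    internal reference standards; and partitions diversity with a
    distance-based AMOVA (permutation test), principal coordinate analysis and
    the Evanno delta-K statistic for external clustering runs. A seeded
    synthetic-germplasm generator with a ground-truth channel makes the whole
    pipeline testable without access to a real collection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    pracma,
    stats,
    utils
Suggests:
    ape,
    jsonlite,
    knitr,
    mclust,
    rmarkdown,
    testthat (>= 3.0.0),
    vegan,
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
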