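Package: haplodiv
Title: Mitochondrial Haplotype Diversity, Population Structure and
    Effective Population Size
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of aligned mitochondrial sequence data (e.g. a
    cytochrome b fragment) sampled from several population groups:
    haplotype collapsing and site classification, Nei haplotype and
    nucleotide diversity with site-bootstrap standard errors,
    distance-based AMOVA and pairwise FST with permutation tests,
    minimum-spanning haplotype networks, neighbor-joining and UPGMA
    trees with bootstrap support, PCA of haplotype SNP matrices, and a
    coalescent effective-population-size estimator. Includes a
    configurable synthetic-data generator emulating a star-like
    haplotype design so the whole pipeline can be exercised without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
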