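Package: germclone
Title: Clone Detection, Admixture and SNP Fingerprinting for Germplasm
    Collections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Characterises clonally propagated germplasm collections from
    genome-wide SNP genotypes. From a VCF of biallelic diploid calls and a
    cultivar-name table, the package filters sites, computes pairwise
    p-distance matrices with site bootstrap, builds neighbour-joining trees
    with bipartition support, estimates two-pool admixture by maximum
    likelihood EM with Evanno delta-K model choice, derives a clone-distance
    cutoff from same-named sister pairs and tight seed groups to call clonal
    (synonymous) and homonymous cultivars, and selects a minimal SNP
    fingerprinting panel with per-marker minor allele frequency and
    polymorphic information content. A synthetic-cohort generator with known
    ground truth (gene pools, hybrids, clone groups, genotyping noise) makes
    every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    jsonlite,
    phangorn,
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
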