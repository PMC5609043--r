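Package: pigpopgen
Title: Population-Genetic Analysis of Dense SNP-Array Data in Pigs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: End-to-end toolkit for population-genetic analysis of diploid
    biallelic SNP-array genotypes from domesticated and wild pig populations.
    Implements quality control with relatedness and linkage-disequilibrium
    pruning, identity-by-state distances with classical multidimensional
    scaling and neighbor-joining trees, maximum-likelihood admixture-model
    ancestry estimation by EM, sliding-window runs-of-homozygosity detection
    and the F_ROH inbreeding statistic, windowed haplotype diversity,
    LD-decay effective-population-size estimation via the Sved relation,
    and Weir-Cockerham Fst scans for loci differentiated between domestic
    and wild populations, together with synthetic-data generators (admixed
    Balding-Nichols cohorts, stepping-stone demes, forward Wright-Fisher
    populations, and gene-dropped pedigrees) that provide known truth for
    validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape,
    geosphere,
    vcfR,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
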