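Package: retrophylo
Title: Retroposon Presence-Absence Phylogenomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Phylogenomic analysis of mobile-element-insertion (MEI)
    presence-absence data from whole-genome genotype calls. Parses MEI
    VCFs into genotype call sets, builds binary presence-absence matrices
    with heterozygosity sidecars, reconstructs phylogenies under Dollo
    parsimony (heuristic search with random addition and branch swapping)
    and neighbor-joining with bootstrap support and consistency indices,
    quantifies conflicting phylogenetic signal through exclusive
    synapomorphy intersections and count-based polytomy and
    introgression-asymmetry tests, estimates per-branch insertion rates
    on dated species trees with an incomplete-lineage-sorting mapping
    rule, simulates insertion data under the multispecies coalescent with
    coverage-dependent detection noise, and benchmarks insertion callers
    against spiked truth sets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    phangorn,
    phytools,
    vcfR,
    jsonlite,
    yaml,
    withr,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
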