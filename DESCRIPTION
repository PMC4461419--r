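Package: cryptolin
Title: Detection and Characterisation of Sympatric Cryptic Plant Lineages
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An integrated analysis chain for demonstrating and
    characterising sympatric cryptic lineages from codominant nuclear
    markers, organellar haplotype sequences, flowering-phenology censuses
    and quantitative traits. Provides diversity and differentiation
    statistics (unbiased gene diversity, rarefied allelic richness,
    Weir-Cockerham F-statistics), genotypic distances with principal
    coordinate analysis, a no-admixture Gibbs clustering model with the
    Evanno delta-K heuristic, Bayesian posterior classification of
    individuals into genotype frequency classes (pure, F1, F2 and
    backcrosses), fixed-limit statistical parsimony haplotype networks,
    flowering synchrony and probability-of-hybrid-formation statistics
    with stratified bootstrap intervals, and quantitative-trait
    divergence (PST) against neutral expectations. A synthetic-data
    generator emulating a three-lineage selfing study system provides
    ground-truth-labelled inputs for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    Biostrings,
    MASS,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
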