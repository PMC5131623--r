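Package: plastrank
Title: Comparative Plastome Structure Analysis and Phylogenetic Marker Ranking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative analysis of annotated chloroplast genomes:
    de novo delineation of the quadripartite structure (LSC, SSC and the two
    inverted repeats), region- and sequence-class length and GC accounting,
    extraction of introns and intergenic spacers as candidate phylogenetic
    markers, alignment summary statistics (variable sites, parsimony-informative
    sites, Kimura two-parameter distances), distance-based tree inference with
    nonparametric bootstrap, Robinson-Foulds comparison to a reference topology,
    and a weighted composite score that ranks markers by phylogenetic
    informativeness. A synthetic-plastome generator with known phylogeny and
    per-marker rates makes the whole pipeline testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    Biostrings,
    Rcpp,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
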