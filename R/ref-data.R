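# Bundled reference tables: per-species values reported for the 16 sequenced
# Melastomataceae plastomes (GenBank KX826819-KX826834) and the eight
# comparison Myrtales plastomes. They allow cohort-level summaries and the
# ranking normalisation to be exercised without downloading the deposits.

ref_path <- function(file)
  system.file("extdata", file, package = "plastrank", mustWork = TRUE)

read_ref <- function(file)
  utils::read.delim(ref_path(file), stringsAsFactors = FALSE,
                    check.names = FALSE)

#' Bundled reference tables for the Melastomataceae plastome cohort
#'
#' * `ref_region_table()`: per-species region lengths (bp) and GC fractions
#'   (LSC, SSC, IR, full genome) with mean sequencing coverage, for the 16
#'   Melastomataceae plastomes KX826819--KX826834.
#' * `ref_class_table()`: per-species sequence-class lengths and GC
#'   (protein-coding, tRNA, rRNA, intron, intergenic) for the same cohort.
#' * `ref_myrtales_table()`: gene counts and region lengths of one
#'   Melastomataceae plastome alongside eight published Myrtales plastomes.
#' * `ref_marker_table()`: the ten top-ranked intron/spacer markers of the
#'   family-wide survey with their summary metrics (sequence lengths,
#'   aligned length, variable and parsimony-informative sites, mean K80
#'   distance, RF distance to the whole-plastome tree, mean bootstrap).
#' * `ref_marker_ranges()`: the survey-wide observed ranges of the three
#'   ranking metrics (variable sites, mean bootstrap, RF distance) across
#'   all 41 surveyed markers, needed to normalise scores for the top-10
#'   subset.
#'
#' @return a data frame (see above).
#' @name ref_tables
NULL

#' @rdname ref_tables
#' @export
ref_region_table <- function() read_ref("melastomataceae_regions.tsv")

#' @rdname ref_tables
#' @export
ref_class_table <- function() read_ref("melastomataceae_classes.tsv")

#' @rdname ref_tables
#' @export
ref_myrtales_table <- function() read_ref("myrtales_genomes.tsv")

#' @rdname ref_tables
#' @export
ref_marker_table <- function() read_ref("marker_survey_top10.tsv")

#' @rdname ref_tables
#' @export
ref_marker_ranges <- function() read_ref("marker_survey_ranges.tsv")
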