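# Composite marker-informativeness score and the survey report.

#' Composite informativeness score
#'
#' Weighted mean of relative values: variable sites (weight 1), mean
#' bootstrap support (weight 2) and topological closeness to the reference
#' tree (weight 3):
#' `score = (1 * v_rel + 2 * b_rel + 3 * d_rel) / 6`.
#'
#' @param v_rel,b_rel,d_rel relative values in `[0, 1]` (vectorised).
#' @return score(s) in `[0, 1]`.
#' @export
composite_score <- function(v_rel, b_rel, d_rel) {
  stopifnot(all(v_rel >= 0 & v_rel <= 1, na.rm = TRUE),
            all(b_rel >= 0 & b_rel <= 1, na.rm = TRUE),
            all(d_rel >= 0 & d_rel <= 1, na.rm = TRUE))
  (v_rel + 2 * b_rel + 3 * d_rel) / 6
}

#' Rank markers by composite informativeness
#'
#' Relative values are computed by dividing each raw metric by its column
#' maximum, with the RF distance inverted (`d_rel = 1 - d / max(d)`:
#' topologies closer to the reference are more informative). When the
#' reports are a subset of a larger survey (e.g. a printed top-10 list),
#' pass the survey-wide maxima explicitly so the normalisation matches the
#' full survey. Markers are sorted by score (descending), ties broken by
#' marker name; markers with missing metrics are reported unranked at the
#' bottom.
#'
#' @param reports data frame with columns `marker`, `variable_n`,
#'   `bootstrap_mean`, `rf_to_reference` (as produced by [survey()]).
#' @param v_max,b_max,d_max optional survey-wide maxima for the three
#'   metrics; default is the column maximum of `reports`.
#' @return `reports` with added columns `score` and `rank`, sorted by rank.
#' @export
rank_markers <- function(reports, v_max = NULL, b_max = NULL, d_max = NULL) {
  stopifnot(is.data.frame(reports), nrow(reports) >= 2L,
            all(c("marker", "variable_n", "bootstrap_mean",
                  "rf_to_reference") %in% names(reports)))
  ok <- stats::complete.cases(reports[, c("variable_n", "bootstrap_mean",
                                          "rf_to_reference")])
  r <- reports[ok, , drop = FALSE]
  if (is.null(v_max)) v_max <- max(r$variable_n)
  if (is.null(b_max)) b_max <- max(r$bootstrap_mean)
  if (is.null(d_max)) d_max <- max(r$rf_to_reference)
  if (v_max == 0)
    stop("degenerate survey: no variable sites in any marker")
  v_rel <- r$variable_n / v_max
  b_rel <- if (b_max > 0) r$bootstrap_mean / b_max else rep(0, nrow(r))
  d_rel <- if (d_max > 0) 1 - r$rf_to_reference / d_max else rep(1, nrow(r))
  r$score <- composite_score(v_rel, b_rel, d_rel)
  ord <- order(-r$score, r$marker)
  r <- r[ord, , drop = FALSE]
  r$rank <- seq_len(nrow(r))
  if (any(!ok)) {
    u <- reports[!ok, , drop = FALSE]
    u$score <- NA_real_
    u$rank <- NA_integer_
    r <- rbind(r, u)
  }
  rownames(r) <- NULL
  r
}

#' Survey marker alignments against a reference tree
#'
#' The per-marker pipeline behind the ranking report: summary statistics,
#' K80 + NJ tree with bootstrap supports, RF distance to the reference, and
#' the composite ranking. Markers whose tree cannot be built (saturation,
#' too few taxa) are reported unranked with a reason code.
#'
#' @param alignments named list of [marker_alignment()] objects.
#' @param reference reference `phylo` tree; must carry all taxa of each
#'   marker.
#' @param bootstrap bootstrap replicates per marker (default 100).
#' @param seed integer seed.
#' @return ranked report data frame (one row per marker, all summary
#'   columns plus `rf_to_reference`, `bootstrap_mean`, `score`, `rank`,
#'   `note`).
#' @export
survey_alignments <- function(alignments, reference, bootstrap = 100L,
                              seed = 1L) {
  stopifnot(length(alignments) >= 2L, inherits(reference, "phylo"))
  rows <- lapply(seq_along(alignments), function(i) {
    a <- alignments[[i]]
    base <- suppressWarnings(summarize_alignment(a))
    res <- tryCatch({
      tr <- suppressMessages(suppressWarnings(
        bootstrap_support(a, replicates = bootstrap,
                          seed = (seed + i) %% 2147483647L)))
      ref <- reference
      if (!setequal(ref$tip.label, tr$tip.label)) {
        if (!all(tr$tip.label %in% ref$tip.label))
          stop("marker taxa not in reference tree")
        ref <- ape::keep.tip(ref, tr$tip.label)
      }
      data.frame(rf_to_reference = rf_distance(tr, ref),
                 bootstrap_mean = mean_support(tr), note = "")
    }, error = function(e)
      data.frame(rf_to_reference = NA_real_, bootstrap_mean = NA_real_,
                 note = conditionMessage(e)))
    cbind(base, res)
  })
  rank_markers(do.call(rbind, rows))
}

#' Survey a cohort of annotated genomes
#'
#' End-to-end marker survey: extraction and collation of introns and
#' spacers ([collate_all_markers()]), per-marker statistics and trees, and
#' the composite ranking against `reference` (by default the tree of the
#' `full` concatenation scheme built from the same genomes). Collated
#' markers must already be equal-length within each marker (true for
#' simulator output, which is gap-free; for real genomes supply externally
#' aligned FASTA via [survey_alignments()]).
#'
#' @param genomes list of at least 4 annotated [circular_genome()] objects.
#' @param reference optional reference `phylo`; defaults to the
#'   full-scheme tree of the cohort.
#' @param min_len,max_len spacer PCR-suitability window (bp).
#' @param bootstrap,seed bootstrap replicates and seed.
#' @return ranked report data frame; attribute `reference` carries the
#'   reference tree used.
#' @export
survey <- function(genomes, reference = NULL, min_len = 400, max_len = 1600,
                   bootstrap = 100L, seed = 1L) {
  stopifnot(length(genomes) >= 4L)
  sets <- collate_all_markers(genomes, classes = c("intron", "spacer"),
                              min_len = min_len, max_len = max_len)
  if (!length(sets)) stop("no markers survived collation/filtering")
  alignments <- list()
  for (nm in names(sets)) {
    seqs <- unlist(sets[[nm]])
    if (length(unique(nchar(seqs))) != 1L)
      stop(sprintf(
        "marker '%s': unequal sequence lengths; align externally and use survey_alignments()",
        nm))
    alignments[[nm]] <- marker_alignment(seqs, nm, attr(sets[[nm]], "mclass"))
  }
  if (is.null(reference)) {
    schemes <- cohort_schemes(genomes, min_len = min_len, max_len = max_len)
    reference <- nj_tree(k80_matrix(schemes$full$alignment))
  }
  rep <- survey_alignments(alignments, reference, bootstrap = bootstrap,
                           seed = seed)
  attr(rep, "reference") <- reference
  rep
}

# build the six schemes from a cohort of genomes (cds + non-coding markers)
cohort_schemes <- function(genomes, min_len = 400, max_len = 1600,
                           window = 5L, max_gap_frac = 0.5) {
  ncs_sets <- collate_all_markers(genomes, classes = c("intron", "spacer"),
                                  min_len = min_len, max_len = max_len)
  cds_sets <- collate_all_markers(genomes, classes = "cds",
                                  min_len = min_len, max_len = max_len)
  to_aln <- function(sets) {
    out <- list()
    for (nm in names(sets)) {
      seqs <- unlist(sets[[nm]])
      if (length(unique(nchar(seqs))) != 1L)
        stop(sprintf("marker '%s': unequal sequence lengths; schemes need aligned input", nm))
      out[[nm]] <- marker_alignment(seqs, nm, attr(sets[[nm]], "mclass"))
    }
    out
  }
  build_schemes(to_aln(cds_sets), to_aln(ncs_sets),
                window = window, max_gap_frac = max_gap_frac)
}
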