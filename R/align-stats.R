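# Alignment summary statistics, K80 distances, codon recoding, translation,
# gap-window masking, and the six concatenation schemes.

# integer matrix view of an alignment: A=1 C=2 G=3 T=4, everything else
# (gaps, Ns, IUPAC ambiguity) NA -- ambiguity is treated as missing in all
# site counts and distances
aln_int_matrix <- function(a) {
  m <- do.call(rbind, lapply(a$rows, seq_to_int))
  rownames(m) <- aln_taxa(a)
  m
}

#' Count variable sites
#'
#' Columns with at least two distinct unambiguous bases; gaps and ambiguity
#' codes are ignored.
#'
#' @param a a [marker_alignment()] with at least 2 rows.
#' @return integer count.
#' @export
count_variable_sites <- function(a) {
  stopifnot(length(a$rows) >= 2L)
  m <- aln_int_matrix(a)
  sum(apply(m, 2L, function(col) length(unique(col[!is.na(col)])) >= 2L))
}

#' Count parsimony-informative sites
#'
#' Columns with at least two distinct unambiguous bases each present in at
#' least two taxa.
#'
#' @param a a [marker_alignment()] with at least 4 rows.
#' @return integer count.
#' @export
count_parsimony_informative <- function(a) {
  stopifnot(length(a$rows) >= 4L)
  m <- aln_int_matrix(a)
  sum(apply(m, 2L, function(col) {
    tab <- tabulate(col[!is.na(col)], nbins = 4L)
    sum(tab >= 2L) >= 2L
  }))
}

# K80 distance from transition/transversion proportions
k80_from_pq <- function(P, Q) {
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) return(NA_real_)  # saturation
  -0.5 * log(w1 * sqrt(w2))
}

# purine/pyrimidine class for the 1..4 coding (A,G purines; C,T pyrimidines)
PURINE <- c(TRUE, FALSE, TRUE, FALSE)

#' Kimura two-parameter distance between two aligned sequences
#'
#' `d = -1/2 ln((1 - 2P - Q) sqrt(1 - 2Q))` with `P` and `Q` the transition
#' and transversion proportions over the compared columns. Comparison uses
#' pairwise deletion: only columns where both sequences carry an unambiguous
#' A/C/G/T base are counted. Saturated pairs (non-positive log argument)
#' return `NA` with a warning so callers can exclude them from means.
#'
#' @param x,y equal-length aligned sequences (strings, or the integer coding
#'   used internally).
#' @return the distance, or `NA` on saturation.
#' @export
k80_distance <- function(x, y) {
  if (is.character(x)) x <- seq_to_int(x)
  if (is.character(y)) y <- seq_to_int(y)
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  if (n == 0L)
    stop("undefined K80 distance: no columns with unambiguous bases in both sequences")
  xs <- x[ok]; ys <- y[ok]
  diff <- xs != ys
  ti <- diff & (PURINE[xs] == PURINE[ys])
  d <- k80_from_pq(sum(ti) / n, sum(diff & !ti) / n)
  if (is.na(d))
    warning("K80 saturation: distance undefined for this pair (excluded from means)")
  d
}

#' Pairwise K80 distance matrix for an alignment
#'
#' @param a a [marker_alignment()].
#' @return symmetric matrix of K80 distances with taxa as dimnames;
#'   saturated pairs are `NA`.
#' @export
k80_matrix <- function(a) {
  m <- aln_int_matrix(a)
  nt <- nrow(m)
  d <- matrix(0, nt, nt, dimnames = list(rownames(m), rownames(m)))
  sat <- 0L
  for (i in seq_len(nt - 1L)) {
    for (j in (i + 1L):nt) {
      dij <- suppressWarnings(k80_distance(m[i, ], m[j, ]))
      if (is.na(dij)) sat <- sat + 1L
      d[i, j] <- d[j, i] <- dij
    }
  }
  if (sat > 0L)
    warning(sprintf("alignment '%s': %d saturated pair(s) set to NA",
                    a$name, sat))
  d
}

#' Summarise an alignment
#'
#' The per-marker summary row: aligned length, ungapped sequence-length mean
#' and range, variable and parsimony-informative site counts (with
#' fractions), and mean pairwise K80 distance (saturated pairs excluded).
#'
#' @param a a [marker_alignment()] with at least 4 rows.
#' @return one-row data frame.
#' @export
summarize_alignment <- function(a) {
  stopifnot(length(a$rows) >= 4L)
  w <- aln_width(a)
  ungapped <- nchar(gsub("-", "", a$rows, fixed = TRUE))
  nv <- count_variable_sites(a)
  np <- count_parsimony_informative(a)
  d <- k80_matrix(a)
  pairs <- d[upper.tri(d)]
  data.frame(
    marker = a$name, mclass = a$mclass,
    n_taxa = length(a$rows),
    bases_mean = mean(ungapped), bases_min = min(ungapped),
    bases_max = max(ungapped),
    aligned_bp = w,
    variable_n = nv, variable_pct = 100 * nv / w,
    pis_n = np, pis_pct = 100 * np / w,
    k80_mean = mean(pairs, na.rm = TRUE))
}

# genetic code table 11 (bacterial/plastid); standard-code assignments are
# identical for all 64 codons, table 11 differs only in start-codon policy
GENETIC_CODE_11 <- local({
  gc <- Biostrings::getGeneticCode("11")
  gc
})

translate_codon <- function(codon) {
  if (codon == "---") return("-")
  if (grepl("[^ACGT]", codon)) return("X")
  unname(GENETIC_CODE_11[[codon]])
}

#' Ambiguate arginine, leucine and serine codons
#'
#' Family-wise IUPAC degeneracy recoding that removes synonymous signal
#' within the three six-fold degenerate amino acids while preserving
#' alignment columns: every codon translating to leucine becomes `YTN`,
#' arginine `MGN`, serine of the `TCN` family `TCN` and of the `AGY` family
#' `AGY`. All other codons, and codons containing gaps or ambiguity codes,
#' are unchanged. The operation is idempotent.
#'
#' @param a a codon-aligned [marker_alignment()] (width divisible by 3,
#'   reading frame starting at column 1).
#' @return recoded [marker_alignment()].
#' @export
ambiguate_rls_codons <- function(a) {
  w <- aln_width(a)
  if (w %% 3L != 0L)
    stop(sprintf("alignment '%s': length %d not divisible by 3", a$name, w))
  starts <- seq(1L, w, by = 3L)
  rows <- vapply(a$rows, function(s) {
    codons <- substring(s, starts, starts + 2L)
    clean <- !grepl("[^ACGT]", codons)
    aa <- character(length(codons))
    aa[clean] <- unname(GENETIC_CODE_11[codons[clean]])
    codons[clean & aa == "L"] <- "YTN"
    codons[clean & aa == "R"] <- "MGN"
    ser <- clean & aa == "S"
    codons[ser & substr(codons, 1L, 2L) == "AG"] <- "AGY"
    codons[ser & substr(codons, 1L, 1L) == "T"] <- "TCN"
    paste(codons, collapse = "")
  }, character(1))
  names(rows) <- aln_taxa(a)
  marker_alignment(rows, a$name, a$mclass)
}

#' Translate a codon alignment to protein
#'
#' Translation under the bacterial/plastid genetic code (table 11). Gap
#' codons (`---`) become `-`; codons containing `N`, other ambiguity or
#' partial gaps become `X`. A terminal stop column (all rows `*` or gap) is
#' dropped; internal stops are replaced with `X` with a warning.
#'
#' @param a a codon-aligned [marker_alignment()].
#' @return a protein [marker_alignment()].
#' @export
translate_cds <- function(a) {
  w <- aln_width(a)
  if (w %% 3L != 0L)
    stop(sprintf("alignment '%s': length %d not divisible by 3", a$name, w))
  starts <- seq(1L, w, by = 3L)
  prot <- vapply(a$rows, function(s) {
    codons <- substring(s, starts, starts + 2L)
    paste(vapply(codons, translate_codon, character(1)), collapse = "")
  }, character(1))
  names(prot) <- aln_taxa(a)
  m <- do.call(rbind, strsplit(prot, "", fixed = TRUE))
  # drop a terminal stop column
  if (ncol(m) > 0L && all(m[, ncol(m)] %in% c("*", "-", "X")) &&
      any(m[, ncol(m)] == "*"))
    m <- m[, -ncol(m), drop = FALSE]
  n_internal <- sum(m == "*")
  if (n_internal > 0L) {
    warning(sprintf("alignment '%s': %d internal stop codon(s) translated as X",
                    a$name, n_internal))
    m[m == "*"] <- "X"
  }
  rows <- apply(m, 1L, paste, collapse = "")
  names(rows) <- aln_taxa(a)
  marker_alignment(rows, a$name, a$mclass)
}

#' Remove poorly aligned columns by gap-window masking
#'
#' A deterministic filter for dubiously aligned stretches: every sliding
#' window of `window` consecutive columns is scored by its fraction of gap
#' and ambiguity characters across all rows, and all columns belonging to
#' any window whose fraction exceeds `max_gap_frac` are removed.
#'
#' @param a a [marker_alignment()].
#' @param window window width in columns (default 5).
#' @param max_gap_frac maximum tolerated gap+ambiguity fraction per window
#'   (default 0.5).
#' @return filtered [marker_alignment()] (never longer than the input).
#' @export
mask_poorly_aligned <- function(a, window = 5L, max_gap_frac = 0.5) {
  stopifnot(window >= 1L)
  w <- aln_width(a)
  if (w == 0L) return(a)
  m <- aln_matrix(a)
  colfrac <- colMeans(matrix(!(m %in% c("A", "C", "G", "T")), nrow = nrow(m)))
  win <- min(window, w)
  drop <- rep(FALSE, w)
  # running mean over windows of length `win`
  cs <- cumsum(c(0, colfrac))
  for (s in seq_len(w - win + 1L)) {
    if ((cs[s + win] - cs[s]) / win > max_gap_frac)
      drop[s:(s + win - 1L)] <- TRUE
  }
  keep <- which(!drop)
  rows <- vapply(a$rows, function(s)
    paste(strsplit(s, "", fixed = TRUE)[[1L]][keep], collapse = ""),
    character(1))
  names(rows) <- aln_taxa(a)
  marker_alignment(rows, a$name, a$mclass)
}

#' Build the six analysis schemes
#'
#' From per-marker coding and non-coding alignments, builds the six
#' concatenated datasets used for whole-plastome phylogenetic inference:
#' \enumerate{
#'   \item `ncs` -- all non-coding markers (introns + spacers);
#'   \item `ncs_filtered` -- the same after [mask_poorly_aligned()];
#'   \item `cds` -- all protein-coding genes;
#'   \item `cds_ambiguated` -- `cds` after [ambiguate_rls_codons()];
#'   \item `protein` -- `cds` translated;
#'   \item `full` -- `ncs_filtered` plus the non-ambiguated `cds`.
#' }
#' Upstream marker collation keeps a single IR copy of every duplicated
#' marker, so duplicated sequence is not over-represented. Taxa missing a
#' marker are gap-filled.
#'
#' @param cds_alignments list of codon-aligned [marker_alignment()] objects.
#' @param ncs_alignments list of non-coding [marker_alignment()] objects.
#' @param window,max_gap_frac parameters of [mask_poorly_aligned()].
#' @return named list of six schemes, each a list with `alignment` and
#'   `partition` (the marker-to-column map; cds partitions carry
#'   `frame = 1`).
#' @export
build_schemes <- function(cds_alignments, ncs_alignments,
                          window = 5L, max_gap_frac = 0.5) {
  stopifnot(length(cds_alignments) >= 1L, length(ncs_alignments) >= 1L)
  ncs_f <- lapply(ncs_alignments, mask_poorly_aligned,
                  window = window, max_gap_frac = max_gap_frac)
  cds_a <- lapply(cds_alignments, ambiguate_rls_codons)
  prot <- lapply(cds_alignments, function(a) suppressWarnings(translate_cds(a)))
  mark_frame <- function(sch) {
    sch$partition$frame <- ifelse(sch$partition$mclass == "cds", 1L, NA_integer_)
    sch
  }
  list(
    ncs = mark_frame(concat_alignments(ncs_alignments, "ncs")),
    ncs_filtered = mark_frame(concat_alignments(ncs_f, "ncs_filtered")),
    cds = mark_frame(concat_alignments(cds_alignments, "cds", mclass = "cds")),
    cds_ambiguated = mark_frame(concat_alignments(cds_a, "cds_ambiguated",
                                                  mclass = "cds")),
    protein = mark_frame(concat_alignments(prot, "protein", mclass = "cds")),
    full = mark_frame(concat_alignments(c(ncs_f, cds_alignments), "full")))
}
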