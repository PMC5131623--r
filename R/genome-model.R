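#' Annotated circular genome
#'
#' The central data structure: a circular nucleotide sequence plus typed,
#' stranded features in 0-based half-open coordinates. A feature part whose
#' `end` exceeds the genome length encodes an origin-spanning interval
#' (stored "unwrapped"; positions are taken modulo the length).
#'
#' @param id accession or sample name.
#' @param seq circular DNA sequence as a single string (upper-cased; residues
#'   outside the IUPAC alphabet are replaced with `N` with a warning).
#' @param features list of features built with [feature()].
#' @return an object of class `circular_genome` with fields `id`, `seq`,
#'   `length` and `features`.
#' @export
circular_genome <- function(id, seq, features = list()) {
  stopifnot(is.character(id), length(id) == 1L,
            is.character(seq), length(seq) == 1L, nzchar(seq))
  seq <- sanitize_dna(seq, what = id)
  g <- structure(list(id = id, seq = seq, length = nchar(seq),
                      features = features),
                 class = "circular_genome")
  validate_genome(g)
  g
}

#' Genome feature
#'
#' @param name gene or marker label.
#' @param ftype one of `gene`, `CDS`, `tRNA`, `rRNA`, `intron`, `spacer`,
#'   `other`.
#' @param parts data frame with columns `start`, `end` (0-based half-open;
#'   `end` may exceed the genome length for origin-spanning parts) and
#'   `strand` (`"+"` or `"-"`).
#' @param pseudo logical, pseudogene flag copied from the annotation.
#' @return an object of class `genome_feature`.
#' @export
feature <- function(name, ftype, parts, pseudo = FALSE) {
  ftype <- match.arg(ftype, c("gene", "CDS", "tRNA", "rRNA", "intron",
                              "spacer", "other"))
  if (is.numeric(parts) && length(parts) >= 2L)
    parts <- data.frame(start = parts[1L], end = parts[2L],
                        strand = if (length(parts) >= 3L && parts[3L] < 0) "-" else "+")
  stopifnot(is.data.frame(parts), nrow(parts) >= 1L,
            all(c("start", "end", "strand") %in% names(parts)))
  parts$start <- as.integer(parts$start)
  parts$end <- as.integer(parts$end)
  if (any(parts$end <= parts$start))
    stop(sprintf("feature '%s': degenerate part (end <= start)", name))
  if (!all(parts$strand %in% c("+", "-")))
    stop(sprintf("feature '%s': strand must be '+' or '-'", name))
  structure(list(name = name, ftype = ftype,
                 parts = parts[, c("start", "end", "strand")],
                 pseudo = isTRUE(pseudo)),
            class = "genome_feature")
}

validate_genome <- function(g) {
  n <- g$length
  stopifnot(n == nchar(g$seq), n > 0L)
  for (f in g$features) {
    if (any(f$parts$start %% n < 0) || any(f$parts$end - f$parts$start > n) ||
        any(f$parts$start >= 2L * n) || any(f$parts$end > 2L * n))
      stop(sprintf("feature '%s' lies outside the sequence (length %d)",
                   f$name, n))
    if (nrow(f$parts) > 1L) {
      p <- f$parts[order(f$parts$start), ]
      if (any(p$start[-1L] < p$end[-nrow(p)]))
        stop(sprintf("feature '%s': overlapping parts", f$name))
    }
  }
  invisible(g)
}

#' @export
print.circular_genome <- function(x, ...) {
  cat(sprintf("<circular_genome> %s: %s bp, %d features\n",
              x$id, format(x$length, big.mark = ","), length(x$features)))
  invisible(x)
}

#' Extract the sequence of a feature
#'
#' Parts are concatenated in genome order, then reverse-complemented if the
#' feature lies on the minus strand, so the returned string always reads in
#' the feature's own 5'→3' direction.
#'
#' @param g a [circular_genome()].
#' @param f a [feature()] (or an element of `g$features`).
#' @return a DNA string.
#' @export
feature_seq <- function(g, f) {
  p <- f$parts[order(f$parts$start), , drop = FALSE]
  s <- paste(vapply(seq_len(nrow(p)), function(i)
    circ_substr(g$seq, p$start[i], p$end[i], g$length), character(1)),
    collapse = "")
  if (all(p$strand == "-")) revcomp(s) else s
}

# total span length of a feature (sum of part lengths)
feature_length <- function(f) sum(f$parts$end - f$parts$start)

# features of given type(s), in genome order of their first part
features_of_type <- function(g, types) {
  fs <- Filter(function(f) f$ftype %in% types, g$features)
  if (!length(fs)) return(fs)
  fs[order(vapply(fs, function(f) min(f$parts$start), numeric(1)))]
}
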