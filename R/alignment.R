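#' Named multiple sequence alignment for one marker
#'
#' A light container: equal-length (gapped) rows keyed by taxon label, plus
#' the marker name and class (`intron`, `spacer` or `cds`).
#'
#' @param rows named character vector of equal-length sequences (gaps as `-`).
#' @param name marker name.
#' @param mclass marker class: `"intron"`, `"spacer"`, `"cds"`, or `"other"`.
#' @return an object of class `marker_alignment`.
#' @export
marker_alignment <- function(rows, name = "marker", mclass = "other") {
  stopifnot(is.character(rows), length(rows) >= 1L)
  if (is.null(names(rows)) || any(!nzchar(names(rows))))
    stop("alignment rows must be named by taxon")
  if (anyDuplicated(names(rows)))
    stop(sprintf("alignment '%s': duplicate taxon labels", name))
  widths <- nchar(rows)
  if (length(unique(widths)) != 1L)
    stop(sprintf("alignment '%s': ragged rows (lengths %s)", name,
                 paste(sort(unique(widths)), collapse = ", ")))
  rows <- toupper(rows)
  structure(list(name = name, mclass = mclass, rows = rows),
            class = "marker_alignment")
}

#' @export
print.marker_alignment <- function(x, ...) {
  cat(sprintf("<marker_alignment> %s (%s): %d taxa x %d columns\n",
              x$name, x$mclass, length(x$rows), aln_width(x)))
  invisible(x)
}

#' @rdname marker_alignment
#' @param a a `marker_alignment`.
#' @export
aln_width <- function(a) if (length(a$rows)) nchar(a$rows[[1L]]) else 0L

#' @rdname marker_alignment
#' @export
aln_taxa <- function(a) names(a$rows)

# character matrix view (taxa x columns)
aln_matrix <- function(a) {
  do.call(rbind, strsplit(a$rows, "", fixed = TRUE))
}

# rebuild rows from a character matrix, preserving taxa/name/class
aln_from_matrix <- function(m, template) {
  rows <- apply(m, 1L, paste, collapse = "")
  names(rows) <- names(template$rows)
  marker_alignment(rows, template$name, template$mclass)
}

#' Read / write a FASTA alignment
#'
#' Thin wrappers over `Biostrings` with validation: rows must be equal
#' length, labels unique; residues are stored upper-case.
#'
#' @param path FASTA file.
#' @param name marker name (defaults to the file stem).
#' @param mclass marker class.
#' @return [read_fasta_alignment()] returns a [marker_alignment()];
#'   [write_fasta_alignment()] returns `path` invisibly.
#' @export
read_fasta_alignment <- function(path, name = NULL, mclass = "other") {
  ss <- Biostrings::readBStringSet(path)
  if (anyDuplicated(names(ss)))
    stop(sprintf("%s: duplicate labels", path))
  rows <- toupper(as.character(ss))
  names(rows) <- names(ss)
  marker_alignment(rows,
                   name = if (is.null(name))
                     tools::file_path_sans_ext(basename(path)) else name,
                   mclass = mclass)
}

#' @rdname read_fasta_alignment
#' @param a a [marker_alignment()].
#' @export
write_fasta_alignment <- function(a, path) {
  ss <- Biostrings::BStringSet(a$rows)
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

#' Concatenate marker alignments into one supermatrix
#'
#' Taxa are the union across markers; a taxon missing from a marker is
#' gap-filled for that marker's columns. Returns the concatenated alignment
#' plus a partition map giving each marker's 1-based column range.
#'
#' @param alignments list of [marker_alignment()] objects.
#' @param name name for the concatenated alignment.
#' @param mclass class label for the concatenated alignment.
#' @return list with elements `alignment` and `partition` (data frame with
#'   columns `marker`, `mclass`, `start`, `end`).
#' @export
concat_alignments <- function(alignments, name = "concatenated",
                              mclass = "other") {
  stopifnot(length(alignments) >= 1L)
  taxa <- sort(unique(unlist(lapply(alignments, aln_taxa))))
  pieces <- matrix("", nrow = length(taxa), ncol = length(alignments),
                   dimnames = list(taxa, NULL))
  part <- data.frame(marker = character(0), mclass = character(0),
                     start = integer(0), end = integer(0))
  at <- 1L
  for (i in seq_along(alignments)) {
    a <- alignments[[i]]
    w <- aln_width(a)
    blank <- strrep("-", w)
    pieces[, i] <- ifelse(taxa %in% aln_taxa(a), a$rows[taxa], blank)
    part <- rbind(part, data.frame(marker = a$name, mclass = a$mclass,
                                   start = at, end = at + w - 1L))
    at <- at + w
  }
  rows <- apply(pieces, 1L, paste, collapse = "")
  names(rows) <- taxa
  list(alignment = marker_alignment(rows, name, mclass), partition = part)
}
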