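IUPAC_CHARS <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "N")

#' Reverse complement of a DNA string
#'
#' Handles the full IUPAC alphabet and keeps gap characters (`-`) in place,
#' so it is safe on gapped alignment rows as well as plain sequences.
#'
#' @param x character vector of DNA strings.
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x))
  vapply(x, function(s) {
    s <- chartr("ACGTRYSWKMBDHVNacgtryswkmbdhvn",
                "TGCAYRSWMKVHDBNtgcayrswmkvhdbn", s)
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' GC content of a DNA sequence
#'
#' Fraction (G+C)/(A+C+G+T). Ambiguity codes, Ns and gaps are excluded from
#' both numerator and denominator, which is the conventional way deposited
#' genomes with stretches of Ns are summarised.
#'
#' @param seq a single DNA string (any case).
#' @return a fraction in `[0, 1]`.
#' @export
gc_content <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L, nzchar(seq))
  counts <- base_counts(seq)
  denom <- sum(counts)
  if (denom == 0L)
    stop("undefined GC content: sequence has no unambiguous A/C/G/T bases")
  (counts[["C"]] + counts[["G"]]) / denom
}

# counts of A, C, G, T in a string (case-insensitive)
base_counts <- function(seq) {
  v <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  c(A = sum(v == "A"), C = sum(v == "C"),
    G = sum(v == "G"), T = sum(v == "T"))
}

# encode A/C/G/T as 1..4, anything else NA (used by distance/site counters)
seq_to_int <- function(x) {
  m <- match(strsplit(toupper(x), "", fixed = TRUE)[[1]],
             c("A", "C", "G", "T"))
  m
}

int_to_seq <- function(v) {
  paste(c("A", "C", "G", "T")[v], collapse = "")
}

# uppercase and replace residues outside the IUPAC set (and '-') with N
sanitize_dna <- function(seq, what = "sequence") {
  seq <- toupper(as.vector(seq))
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  bad <- !(v %in% c(IUPAC_CHARS, "-"))
  if (any(bad)) {
    warning(sprintf("%s: %d residue(s) outside the IUPAC alphabet replaced with N",
                    what, sum(bad)))
    v[bad] <- "N"
    seq <- paste(v, collapse = "")
  }
  seq
}

# substring of a circular sequence, 0-based half-open; end may exceed n
circ_substr <- function(seq, start, end, n = nchar(seq)) {
  stopifnot(end > start)
  start <- start %% n
  len <- end - start
  if (start + len <= n) {
    substr(seq, start + 1L, start + len)
  } else {
    paste0(substr(seq, start + 1L, n), substr(seq, 1L, start + len - n))
  }
}
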