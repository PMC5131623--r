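# Quadripartite structure: IR detection, region/class accounting, junctions.

#' Detect the inverted repeats and partition the plastome
#'
#' Finds the longest exact inverted-repeat pair of length `>= min_ir` whose
#' two copies split the circle into four non-empty regions, and labels the
#' regions so that, traversing the circle forward, they read LSC, IRa, SSC,
#' IRb with LSC the longer single-copy region. The result is
#' rotation-invariant (region lengths do not depend on where the circular
#' sequence was linearised) and orientation-canonical.
#'
#' Matching is exact (plastome IR copies are typically identical); the search
#' runs a binary search on repeat length over rolling hashes of the circular
#' sequence against its reverse complement, with character-level verification
#' of every candidate.
#'
#' @param g a [circular_genome()].
#' @param min_ir minimum IR length in bases (default 10000, the scale of real
#'   plastome IRs; use smaller values for toy genomes).
#' @return an object of class `quadripartite_partition`: intervals `lsc`,
#'   `ira`, `ssc`, `irb` (0-based half-open, `end` may exceed the genome
#'   length for the wrap-around region), plus `ir_length` and
#'   `genome_length`.
#' @export
detect_inverted_repeats <- function(g, min_ir = 10000L) {
  stopifnot(inherits(g, "circular_genome"), min_ir >= 100L)
  n <- g$length
  hits <- .ir_scan_cpp(g$seq, as.integer(min_ir))
  if (nrow(hits) == 0L)
    stop(sprintf("no-IR: %s has no exact inverted repeat of length >= %d",
                 g$id, min_ir), call. = FALSE)
  if (nrow(hits) > 1L)
    stop(sprintf(
      "IR tie: %s has %d distinct maximal inverted-repeat pairs of length %d (starts: %s)",
      g$id, nrow(hits), hits[1L, 3L],
      paste(sprintf("(%d,%d)", hits[, 1L], hits[, 2L]), collapse = " ")),
      call. = FALSE)
  a <- hits[1L, 1L]; b <- hits[1L, 2L]; L <- hits[1L, 3L]
  gap1 <- (b - (a + L)) %% n      # arc from end of copy A to start of copy B
  gap2 <- (a - (b + L)) %% n      # arc from end of copy B to start of copy A
  iv <- function(s, len) c(start = s %% n, end = s %% n + len)
  if (gap2 >= gap1) {
    lsc <- iv(b + L, gap2); ira <- iv(a, L); ssc <- iv(a + L, gap1); irb <- iv(b, L)
  } else {
    lsc <- iv(a + L, gap1); ira <- iv(b, L); ssc <- iv(b + L, gap2); irb <- iv(a, L)
  }
  structure(list(lsc = lsc, ira = ira, ssc = ssc, irb = irb,
                 ir_length = L, genome_length = n),
            class = "quadripartite_partition")
}

#' @export
print.quadripartite_partition <- function(x, ...) {
  cat(sprintf(
    "<quadripartite_partition> %s bp: LSC %s | IR %s | SSC %s\n",
    format(x$genome_length, big.mark = ","),
    format(x$lsc["end"] - x$lsc["start"], big.mark = ","),
    format(x$ir_length, big.mark = ","),
    format(x$ssc["end"] - x$ssc["start"], big.mark = ",")))
  invisible(x)
}

region_length <- function(iv) unname(iv["end"] - iv["start"])

#' Region lengths and GC content
#'
#' One row per region (LSC, SSC, IR -- a single IR copy is reported -- and
#' the full genome) with length in bp and GC fraction.
#'
#' @param g a [circular_genome()].
#' @param p the [detect_inverted_repeats()] partition of `g`.
#' @return data frame with columns `region`, `length_bp`, `gc`.
#' @export
region_stats <- function(g, p) {
  stopifnot(inherits(p, "quadripartite_partition"),
            p$genome_length == g$length)
  seq_of <- function(iv) circ_substr(g$seq, iv["start"], iv["end"], g$length)
  data.frame(
    region = c("LSC", "SSC", "IR", "full"),
    length_bp = c(region_length(p$lsc), region_length(p$ssc),
                  p$ir_length, g$length),
    gc = c(gc_content(seq_of(p$lsc)), gc_content(seq_of(p$ssc)),
           gc_content(seq_of(p$ira)), gc_content(g$seq)))
}

# position-class painting of the whole circle under the precedence rule
# CDS > tRNA > rRNA > intron > intergenic; returns an integer vector of
# length n with levels 1..5 in that order (5 = intergenic)
paint_classes <- function(g) {
  n <- g$length
  cls <- rep.int(5L, n)
  paint <- function(parts, value) {
    for (i in seq_len(nrow(parts))) {
      pos <- (parts$start[i]:(parts$end[i] - 1L)) %% n + 1L
      cls[pos] <<- value
    }
  }
  # lowest precedence first so higher classes overwrite
  for (f in features_of_type(g, "intron")) paint(f$parts, 4L)
  # introns implied by gaps between exon parts of multi-part genes
  for (f in features_of_type(g, "gene")) {
    p <- f$parts[order(f$parts$start), , drop = FALSE]
    if (nrow(p) >= 2L && length(unique(p$strand)) == 1L) {
      for (k in seq_len(nrow(p) - 1L)) {
        if (p$start[k + 1L] > p$end[k])
          paint(data.frame(start = p$end[k], end = p$start[k + 1L],
                           strand = p$strand[1L]), 4L)
      }
    }
  }
  for (f in features_of_type(g, "rRNA")) paint(f$parts, 3L)
  for (f in features_of_type(g, "tRNA")) paint(f$parts, 2L)
  for (f in features_of_type(g, "CDS")) paint(f$parts, 1L)
  cls
}

#' Sequence-class lengths, GC and gene counts
#'
#' Assigns every position of the circle to exactly one class with precedence
#' CDS > tRNA > rRNA > intron > intergenic (annotations may overlap; a
#' deterministic rule is required), then reports summed length and GC per
#' class plus gene counts per class. IR-duplicated genes are counted
#' separately, matching how plastome gene tallies are conventionally printed.
#'
#' @param g an annotated [circular_genome()].
#' @return list with `classes` (data frame: `class`, `length_bp`, `gc`) and
#'   `gene_counts` (named vector: `protein_coding`, `trna`, `rrna`).
#' @export
class_stats <- function(g) {
  cls <- paint_classes(g)
  v <- strsplit(g$seq, "", fixed = TRUE)[[1L]]
  lab <- c("protein_coding", "trna", "rrna", "intron", "intergenic")
  tab <- lapply(1:5, function(k) {
    s <- v[cls == k]
    gc <- if (length(s) && any(s %in% c("A", "C", "G", "T")))
      sum(s %in% c("G", "C")) / sum(s %in% c("A", "C", "G", "T")) else NA_real_
    data.frame(class = lab[k], length_bp = length(s), gc = gc)
  })
  counts <- c(protein_coding = length(features_of_type(g, "CDS")),
              trna = length(features_of_type(g, "tRNA")),
              rrna = length(features_of_type(g, "rRNA")))
  list(classes = do.call(rbind, tab), gene_counts = counts)
}

#' Report the features at the four quadripartite junctions
#'
#' For each junction (LSC-IRa, IRa-SSC, SSC-IRb, IRb-LSC) reports the
#' gene-level feature containing the boundary position, or the two flanking
#' features when the boundary falls in an intergenic spacer.
#'
#' @param g a [circular_genome()].
#' @param p its [detect_inverted_repeats()] partition.
#' @return data frame with columns `junction`, `position` (0-based position
#'   of the first base of the downstream region), `in_feature` (`NA` when
#'   the boundary is intergenic), `flank_left`, `flank_right`.
#' @export
report_junctions <- function(g, p) {
  n <- g$length
  fs <- features_of_type(g, c("gene"))
  if (!length(fs)) fs <- features_of_type(g, c("CDS", "tRNA", "rRNA"))
  starts <- vapply(fs, function(f) min(f$parts$start) %% n, numeric(1))
  contains <- function(f, pos) {
    any(vapply(seq_len(nrow(f$parts)), function(i) {
      s <- f$parts$start[i]; e <- f$parts$end[i]
      ((pos - s) %% n) < (e - s)
    }, logical(1)))
  }
  junctions <- data.frame(
    junction = c("LSC-IRa", "IRa-SSC", "SSC-IRb", "IRb-LSC"),
    position = c(p$ira["start"], p$ssc["start"], p$irb["start"],
                 p$lsc["start"]) %% n)
  res <- lapply(junctions$position, function(pos) {
    hit <- Filter(function(f) contains(f, pos), fs)
    if (length(hit))
      return(c(in_feature = hit[[1L]]$name, flank_left = NA, flank_right = NA))
    # flanking features on the circle
    d_ahead <- (starts - pos) %% n                 # next feature start
    ends <- vapply(fs, function(f) max(f$parts$end) %% n, numeric(1))
    d_behind <- (pos - ends) %% n                  # previous feature end
    c(in_feature = NA,
      flank_left = fs[[which.min(d_behind)]]$name,
      flank_right = fs[[which.min(d_ahead)]]$name)
  })
  cbind(junctions, do.call(rbind, lapply(res, function(r)
    data.frame(in_feature = r[["in_feature"]], flank_left = r[["flank_left"]],
               flank_right = r[["flank_right"]]))))
}

#' Cohort summary of region (and class) lengths
#'
#' Accepts either a list of annotated genomes (structure is detected and
#' summarised per genome) or a data frame of per-genome length columns, e.g.
#' published region tables, so that printed per-species values can be fed in
#' directly. Reports the per-genome table plus mean and sample (n-1)
#' standard deviation of every numeric length column.
#'
#' @param x list of [circular_genome()] objects, or a data frame whose
#'   numeric columns are per-genome lengths (and optionally GC values;
#'   columns whose name contains `gc` are averaged but their s.d. is
#'   reported too).
#' @param min_ir passed to [detect_inverted_repeats()] when `x` is a list of
#'   genomes.
#' @return list with `table` (per-genome values) and `summary` (data frame
#'   with columns `column`, `mean`, `sd`).
#' @export
summarize_cohort <- function(x, min_ir = 10000L) {
  if (is.data.frame(x)) {
    tab <- x
  } else {
    stopifnot(is.list(x), length(x) >= 2L)
    rows <- lapply(x, function(g) {
      p <- detect_inverted_repeats(g, min_ir = min_ir)
      rs <- region_stats(g, p)
      cs <- class_stats(g)
      vals <- c(setNames(rs$length_bp, paste0(tolower(rs$region), "_bp")),
                setNames(rs$gc, paste0(tolower(rs$region), "_gc")),
                setNames(cs$classes$length_bp,
                         paste0(cs$classes$class, "_bp")),
                cs$gene_counts)
      data.frame(id = g$id, t(vals), check.names = FALSE)
    })
    tab <- do.call(rbind, rows)
  }
  num <- vapply(tab, is.numeric, logical(1))
  if (!any(num)) stop("no numeric columns to summarise")
  summary <- data.frame(
    column = names(tab)[num],
    mean = vapply(tab[num], mean, numeric(1)),
    sd = vapply(tab[num], stats::sd, numeric(1)),
    row.names = NULL)
  list(table = tab, summary = summary)
}
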