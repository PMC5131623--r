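# GenBank flat-file I/O for circular plastomes.
#
# No installed R package parses GenBank flat files from disk (ape's GenBank
# reader is a network fetcher), so a minimal reader/writer for the subset of
# the format plastome deposits use is implemented here: LOCUS, a FEATURES
# table with gene/CDS/tRNA/rRNA/intron/misc_feature keys, location strings
# with join()/complement() and origin-spanning joins, /gene, /note and
# /pseudo qualifiers, and the ORIGIN sequence block. Coordinates are 1-based
# inclusive on disk and 0-based half-open in memory.

GB_KEY_FOR_FTYPE <- c(gene = "gene", CDS = "CDS", tRNA = "tRNA", rRNA = "rRNA",
                      intron = "intron", spacer = "misc_feature",
                      other = "misc_feature")

#' Read a GenBank flat file
#'
#' @param path path to a GenBank flat file with an ORIGIN sequence block.
#' @return a [circular_genome()].
#' @export
read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  locus <- grep("^LOCUS", lines)
  id <- if (length(locus)) strsplit(trimws(sub("^LOCUS", "", lines[locus[1L]])),
                                    "[ \t]+")[[1L]][1L] else basename(path)

  ori <- grep("^ORIGIN", lines)
  if (!length(ori))
    stop(sprintf("%s: no ORIGIN sequence block", path))
  endrec <- grep("^//", lines)
  endrec <- if (length(endrec)) endrec[endrec > ori[1L]][1L] else length(lines) + 1L
  seq_lines <- lines[(ori[1L] + 1L):(endrec - 1L)]
  seq <- toupper(gsub("[0-9 \t]", "", paste(seq_lines, collapse = "")))
  if (!nzchar(seq))
    stop(sprintf("%s: empty ORIGIN sequence block", path))

  feats <- list()
  fstart <- grep("^FEATURES", lines)
  if (length(fstart)) {
    block <- lines[(fstart[1L] + 1L):(ori[1L] - 1L)]
    # a new feature starts with a key in columns 6-20
    is_key <- grepl("^ {5}\\S", block)
    idx <- which(is_key)
    for (k in seq_along(idx)) {
      from <- idx[k]
      to <- if (k < length(idx)) idx[k + 1L] - 1L else length(block)
      chunk <- block[from:to]
      key <- sub("^ {5}(\\S+).*$", "\\1", chunk[1L])
      if (key == "source") next
      # location may continue over lines until the first qualifier
      qual_at <- grep("^ {21}/", chunk)
      loc_end <- if (length(qual_at)) qual_at[1L] - 1L else length(chunk)
      loc <- paste0(sub("^ {5}\\S+\\s*", "", chunk[1L]),
                    if (loc_end >= 2L)
                      paste(trimws(chunk[2L:loc_end]), collapse = "") else "")
      loc <- gsub("[ \t]", "", loc)
      quals <- if (length(qual_at)) trimws(chunk[qual_at]) else character(0)
      gene <- qual_value(quals, "gene")
      note <- qual_value(quals, "note")
      pseudo <- any(grepl("^/pseudo\\b", quals))
      ftype <- switch(key,
        gene = "gene", CDS = "CDS", tRNA = "tRNA", rRNA = "rRNA",
        intron = "intron",
        misc_feature = if (!is.na(note) && grepl("spacer", note)) "spacer" else "other",
        "other")
      parts <- parse_gb_location(loc, nchar(seq), paste0(key, "@", loc))
      name <- if (!is.na(gene)) gene
              else if (!is.na(note)) note
              else sprintf("%s_%d", key, parts$start[1L] + 1L)
      feats[[length(feats) + 1L]] <- feature(name, ftype, parts, pseudo = pseudo)
    }
  }
  g <- circular_genome(id, seq, feats)
  for (f in g$features)
    if (any(f$parts$end > 2L * g$length) || any(f$parts$start >= g$length))
      stop(sprintf("%s: feature '%s' outside sequence", path, f$name))
  g
}

qual_value <- function(quals, what) {
  hit <- grep(sprintf("^/%s=", what), quals, value = TRUE)
  if (!length(hit)) return(NA_character_)
  gsub("^\"|\"$", "", sub(sprintf("^/%s=", what), "", hit[1L]))
}

# parse a GenBank location string into a parts data frame
# (0-based half-open, origin-spanning joins unwrapped to end > n)
parse_gb_location <- function(loc, n, name) {
  parse_one <- function(s, strand) {
    if (grepl("^complement\\(", s)) {
      inner <- sub("^complement\\((.*)\\)$", "\\1", s)
      return(parse_one(inner, if (strand == "+") "-" else "+"))
    }
    if (grepl("^(join|order)\\(", s)) {
      inner <- sub("^(join|order)\\((.*)\\)$", "\\2", s)
      pieces <- split_top_commas(inner)
      return(do.call(rbind, lapply(pieces, parse_one, strand = strand)))
    }
    m <- regmatches(s, regexec("^[<>]?(\\d+)\\.\\.[<>]?(\\d+)$", s))[[1L]]
    if (length(m) == 3L) {
      a <- as.integer(m[2L]); b <- as.integer(m[3L])
    } else if (grepl("^\\d+$", s)) {
      a <- b <- as.integer(s)
    } else {
      stop(sprintf("feature '%s': cannot parse location '%s'", name, s))
    }
    data.frame(start = a - 1L, end = b, strand = strand,
               stringsAsFactors = FALSE)
  }
  parts <- parse_one(loc, "+")
  # merge an origin-spanning join: ... a..n followed by 1..b on the same strand
  if (nrow(parts) >= 2L) {
    i <- 1L
    while (i < nrow(parts)) {
      if (parts$end[i] == n && parts$start[i + 1L] == 0L &&
          parts$strand[i] == parts$strand[i + 1L]) {
        parts$end[i] <- n + parts$end[i + 1L]
        parts <- parts[-(i + 1L), , drop = FALSE]
      } else i <- i + 1L
    }
  }
  parts
}

# split on commas not nested inside parentheses
split_top_commas <- function(s) {
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  depth <- cumsum((chars == "(") - (chars == ")"))
  cut <- which(chars == "," & depth == 0L)
  starts <- c(1L, cut + 1L)
  ends <- c(cut - 1L, length(chars))
  vapply(seq_along(starts), function(i)
    paste(chars[starts[i]:ends[i]], collapse = ""), character(1))
}

#' Write a GenBank flat file
#'
#' Inverse of [read_genbank()]: re-reading the written file reproduces the
#' genome's sequence and feature intervals/strands exactly. Origin-spanning
#' parts (stored with `end > length`) are rendered as a `join` across the
#' origin.
#'
#' @param g a [circular_genome()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(g, path) {
  n <- g$length
  out <- c(
    sprintf("LOCUS       %-16s %d bp    DNA     circular PLN 01-JAN-2026",
            g$id, n),
    sprintf("DEFINITION  %s.", g$id),
    "FEATURES             Location/Qualifiers",
    sprintf("     source          1..%d", n)
  )
  for (f in g$features) {
    key <- GB_KEY_FOR_FTYPE[[f$ftype]]
    loc <- render_gb_location(f$parts, n)
    out <- c(out, sprintf("     %-16s%s", key, loc),
             sprintf("                     /gene=\"%s\"", f$name))
    if (f$ftype %in% c("spacer", "other"))
      out <- c(out, sprintf("                     /note=\"%s\"",
                            if (f$ftype == "spacer") "intergenic spacer" else "feature"))
    if (f$pseudo) out <- c(out, "                     /pseudo")
  }
  out <- c(out, "ORIGIN")
  s <- tolower(g$seq)
  pos <- seq(1L, n, by = 60L)
  for (p in pos) {
    chunk <- substr(s, p, min(p + 59L, n))
    groups <- substring(chunk, seq(1L, nchar(chunk), 10L),
                        pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
    out <- c(out, sprintf("%9d %s", p, paste(groups, collapse = " ")))
  }
  out <- c(out, "//")
  writeLines(out, path)
  invisible(path)
}

render_gb_location <- function(parts, n) {
  ranges <- lapply(seq_len(nrow(parts)), function(i) {
    s <- parts$start[i]; e <- parts$end[i]
    if (e > n) c(sprintf("%d..%d", s + 1L, n), sprintf("%d..%d", 1L, e - n))
    else sprintf("%d..%d", s + 1L, e)
  })
  strands <- parts$strand
  if (all(strands == "-")) {
    inner <- paste(unlist(ranges), collapse = ",")
    if (length(unlist(ranges)) > 1L) inner <- sprintf("join(%s)", inner)
    sprintf("complement(%s)", inner)
  } else if (all(strands == "+")) {
    flat <- unlist(ranges)
    if (length(flat) > 1L) sprintf("join(%s)", paste(flat, collapse = ","))
    else flat
  } else {
    pieces <- unlist(lapply(seq_len(nrow(parts)), function(i) {
      r <- ranges[[i]]
      if (strands[i] == "-")
        sprintf("complement(%s)",
                if (length(r) > 1L) sprintf("join(%s)", paste(r, collapse = ",")) else r)
      else r
    }))
    sprintf("join(%s)", paste(pieces, collapse = ","))
  }
}
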