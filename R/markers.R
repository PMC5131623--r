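# Intron and intergenic-spacer extraction and cross-taxon marker collation.

#' Extract introns from an annotated genome
#'
#' One intron per gap between consecutive exon parts of a multi-part gene,
#' strand-normalised to the gene's strand and numbered in transcription
#' order (`"<gene> intron"` for single-intron genes, `"<gene> intron 1"`,
#' `"... 2"` for two-intron genes). Genes whose parts lie on opposite
#' strands (trans-spliced, rps12-style) are skipped with a warning: their
#' "intron" is discontiguous across the genome and not a PCR-amplifiable
#' fragment.
#'
#' @param g a [circular_genome()].
#' @return named list of intron sequences; names follow the rule above.
#'   Duplicate names from IR copies are kept (deduplicated at collation).
#' @export
extract_introns <- function(g) {
  out <- list()
  for (f in features_of_type(g, "gene")) {
    p <- f$parts[order(f$parts$start), , drop = FALSE]
    if (nrow(p) < 2L) next
    if (length(unique(p$strand)) > 1L) {
      warning(sprintf("gene '%s': parts on opposite strands (trans-spliced); introns skipped",
                      f$name))
      next
    }
    if (any(p$start[-1L] < p$end[-nrow(p)]))
      stop(sprintf("gene '%s': overlapping parts", f$name))
    m <- nrow(p) - 1L
    for (k in seq_len(m)) {
      s <- circ_substr(g$seq, p$end[k], p$start[k + 1L], g$length)
      if (p$strand[1L] == "-") s <- revcomp(s)
      # transcription-order index: genome order for '+', reversed for '-'
      idx <- if (p$strand[1L] == "+") k else m - k + 1L
      nm <- if (m == 1L) paste(f$name, "intron") else paste(f$name, "intron", idx)
      out[[length(out) + 1L]] <- s
      names(out)[length(out)] <- nm
    }
  }
  out
}

#' Extract intergenic spacers from an annotated genome
#'
#' For each pair of adjacent gene-level features on the circle, the
#' inter-feature sequence, named `"<left>-<right> spacer"` in genome order.
#' Zero-length spacers (adjacent or overlapping genes) are omitted. Size
#' filtering happens at survey level on the cohort mean length, not here.
#'
#' @param g a [circular_genome()].
#' @return named list of spacer sequences.
#' @export
extract_spacers <- function(g) {
  fs <- features_of_type(g, "gene")
  if (!length(fs)) fs <- features_of_type(g, c("CDS", "tRNA", "rRNA"))
  if (length(fs) < 2L) return(list())
  n <- g$length
  starts <- vapply(fs, function(f) min(f$parts$start), numeric(1))
  ends <- vapply(fs, function(f) max(f$parts$end), numeric(1))
  ord <- order(starts)
  fs <- fs[ord]; starts <- starts[ord]; ends <- ends[ord]
  out <- list()
  for (i in seq_along(fs)) {
    j <- if (i == length(fs)) 1L else i + 1L
    gap_start <- ends[i]
    gap_end <- if (i == length(fs)) starts[j] + n else starts[j]
    if (gap_end <= gap_start) next   # adjacent or overlapping genes
    s <- circ_substr(g$seq, gap_start, gap_end, n)
    nm <- paste0(fs[[i]]$name, "-", fs[[j]]$name, " spacer")
    out[[length(out) + 1L]] <- s
    names(out)[length(out)] <- nm
  }
  out
}

# all marker sequences of one genome: introns + spacers + coding genes
# (cds class uses the spliced, strand-normalised coding sequence)
genome_markers <- function(g, classes = c("intron", "spacer")) {
  out <- list()
  if ("intron" %in% classes) {
    v <- suppressWarnings(extract_introns(g))
    out <- c(out, lapply(seq_along(v), function(i)
      list(name = names(v)[i], mclass = "intron", seq = v[[i]])))
  }
  if ("spacer" %in% classes) {
    v <- extract_spacers(g)
    out <- c(out, lapply(seq_along(v), function(i)
      list(name = names(v)[i], mclass = "spacer", seq = v[[i]])))
  }
  if ("cds" %in% classes) {
    for (f in features_of_type(g, "CDS"))
      out <- c(out, list(list(name = f$name, mclass = "cds",
                              seq = feature_seq(g, f))))
  }
  out
}

#' Collate one marker across genomes
#'
#' One sequence per genome possessing the marker; genomes with IR-duplicated
#' copies contribute the first copy on the canonical orientation. A spacer
#' recorded under the reversed name (both anchors on the minus strand in
#' that genome) is reverse-complemented to the common orientation.
#'
#' @param genomes list of [circular_genome()] objects.
#' @param name marker name (e.g. `"trnG intron"`, `"trnS-trnG spacer"`).
#' @param classes marker classes to search.
#' @return a named list of sequences (one per genome possessing the
#'   marker); attribute `missing` lists absent taxa.
#' @export
collate_marker <- function(genomes, name, classes = c("intron", "spacer", "cds")) {
  revname <- if (grepl(" spacer$", name)) {
    anchors <- strsplit(sub(" spacer$", "", name), "-", fixed = TRUE)[[1L]]
    if (length(anchors) == 2L)
      paste0(anchors[2L], "-", anchors[1L], " spacer") else NA_character_
  } else NA_character_
  seqs <- list()
  missing <- character(0)
  for (g in genomes) {
    mk <- genome_markers(g, classes)
    nm <- vapply(mk, `[[`, character(1), "name")
    hit <- which(nm == name)
    if (length(hit)) {
      seqs[[g$id]] <- mk[[hit[1L]]]$seq
    } else if (!is.na(revname) && any(nm == revname)) {
      seqs[[g$id]] <- revcomp(mk[[which(nm == revname)[1L]]]$seq)
    } else {
      missing <- c(missing, g$id)
    }
  }
  if (length(seqs) < 4L)
    stop(sprintf("marker '%s': present in only %d genome(s); at least 4 needed for a tree",
                 name, length(seqs)))
  structure(seqs, missing = missing)
}

#' Collate all markers of a cohort
#'
#' Extracts introns and intergenic spacers from every genome, deduplicates
#' IR copies, applies the PCR-suitability filter to spacers (cohort mean
#' length within `[min_len, max_len]`), and drops markers present in fewer
#' than `min_taxa` genomes.
#'
#' @param genomes list of [circular_genome()] objects.
#' @param classes marker classes to survey (default introns + spacers, the
#'   classes a marker survey targets; add `"cds"` for coding genes).
#' @param min_len,max_len PCR-suitable cohort-mean length window applied to
#'   spacers (defaults 400 and 1600 bp).
#' @param min_taxa minimum genomes per marker (default 4).
#' @return named list of per-marker named sequence lists; attribute
#'   `dropped` is a data frame of excluded markers with reasons.
#' @export
collate_all_markers <- function(genomes, classes = c("intron", "spacer"),
                                min_len = 400, max_len = 1600,
                                min_taxa = 4L) {
  per_genome <- lapply(genomes, genome_markers, classes = classes)
  names(per_genome) <- vapply(genomes, `[[`, character(1), "id")
  # union of marker names with class, deduplicating IR copies within genome
  all_names <- unique(do.call(rbind, lapply(per_genome, function(mk)
    data.frame(name = vapply(mk, `[[`, character(1), "name"),
               mclass = vapply(mk, `[[`, character(1), "mclass")))))
  all_names <- all_names[!duplicated(all_names$name), ]
  sets <- list()
  dropped <- data.frame(marker = character(0), reason = character(0))
  for (r in seq_len(nrow(all_names))) {
    nm <- all_names$name[r]
    seqs <- list()
    for (gid in names(per_genome)) {
      mk <- per_genome[[gid]]
      hit <- which(vapply(mk, `[[`, character(1), "name") == nm)
      if (length(hit)) seqs[[gid]] <- mk[[hit[1L]]]$seq
    }
    if (length(seqs) < min_taxa) {
      dropped <- rbind(dropped, data.frame(marker = nm, reason = "too_few_taxa"))
      next
    }
    if (all_names$mclass[r] == "spacer") {
      mlen <- mean(nchar(unlist(seqs)))
      if (mlen < min_len || mlen > max_len) {
        dropped <- rbind(dropped,
                         data.frame(marker = nm, reason = "size_filter"))
        next
      }
    }
    attr(seqs, "mclass") <- all_names$mclass[r]
    sets[[nm]] <- seqs
  }
  attr(sets, "dropped") <- dropped
  sets
}
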