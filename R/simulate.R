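# Synthetic annotated plastomes with known phylogeny and per-marker rates.
#
# The generator emulates the statistical structure the downstream survey
# assumes: a set of markers (coding genes, introns, intergenic spacers)
# evolving at heterogeneous rates along one underlying tree under K80, laid
# out on a circular genome with an exact inverted-repeat duplication.

#' Toy plastome architecture
#'
#' A structurally faithful but desk-scale plastome blueprint: ~35 genes with
#' plastid-style names, four intron-bearing single-copy loci (one of them
#' two-intron, clpP-style), one intron-bearing tRNA duplicated in the IR, a
#' dozen intergenic spacers in the PCR-suitable 400-1600 bp range, an ~8.4 kb
#' IR block, and an rps19-style gene straddling the LSC-IRa junction --
#' on a genome of roughly 62 kb.
#'
#' Columns: `name`, `ftype` (`cds`/`tRNA`/`rRNA`), `region`
#' (`lsc`/`ir`/`ssc`), `strand`, `exon_bp` (comma-separated exon lengths),
#' `intron_bp` (comma-separated intron lengths, `""` for none),
#' `gap_after` (intergenic gap to the next feature, bp).
#'
#' @return data frame, one row per gene in genome order.
#' @export
default_architecture <- function() {
  g <- function(name, ftype, region, strand, exon_bp, intron_bp, gap_after)
    data.frame(name = name, ftype = ftype, region = region, strand = strand,
               exon_bp = exon_bp, intron_bp = intron_bp,
               gap_after = gap_after)
  rbind(
    # --- LSC ---
    g("psbA",  "cds",  "lsc", "-", "1062", "", 450),
    g("matK",  "cds",  "lsc", "-", "1530", "", 120),
    g("rps16", "cds",  "lsc", "-", "261",  "", 600),
    g("trnQ",  "tRNA", "lsc", "-", "72",   "", 300),
    g("atpA",  "cds",  "lsc", "-", "1524", "", 80),
    g("atpF",  "cds",  "lsc", "-", "555",  "", 500),
    g("atpH",  "cds",  "lsc", "-", "246",  "", 700),
    g("atpI",  "cds",  "lsc", "-", "744",  "", 150),
    g("rpoC2", "cds",  "lsc", "-", "4140", "", 90),
    g("rpoB",  "cds",  "lsc", "-", "3213", "", 550),
    g("trnC",  "tRNA", "lsc", "+", "71",   "", 250),
    g("psbD",  "cds",  "lsc", "+", "1062", "", 60),
    g("psbC",  "cds",  "lsc", "+", "1386", "", 420),
    g("trnS",  "tRNA", "lsc", "-", "88",   "", 800),
    g("trnG",  "tRNA", "lsc", "+", "23,48", "690", 350),
    g("rbcL",  "cds",  "lsc", "+", "1428", "", 900),
    g("accD",  "cds",  "lsc", "+", "1488", "", 250),
    g("clpP",  "cds",  "lsc", "-", "71,292,228", "620,540", 200),
    g("psbB",  "cds",  "lsc", "+", "1527", "", 100),
    g("petB",  "cds",  "lsc", "+", "648",  "", 300),
    g("rpoA",  "cds",  "lsc", "-", "1014", "", 180),
    g("rps19", "cds",  "lsc", "-", "279",  "", 0),     # straddles LSC-IRa
    # --- IR block (annotated once, duplicated reverse-complemented) ---
    g("rrn16", "rRNA", "ir",  "+", "1491", "", 150),
    g("trnI",  "tRNA", "ir",  "+", "72",   "", 350),
    g("trnA",  "tRNA", "ir",  "+", "38,35", "800", 250),
    g("rrn23", "rRNA", "ir",  "+", "2810", "", 100),
    g("rrn5",  "rRNA", "ir",  "+", "121",  "", 200),
    g("ndhB",  "cds",  "ir",  "-", "1536", "", 150),
    # --- SSC ---
    g("ndhF",  "cds",  "ssc", "-", "2241", "", 1100),
    g("rpl32", "cds",  "ssc", "+", "174",  "", 450),
    g("trnL",  "tRNA", "ssc", "+", "80",   "", 750),
    g("ccsA",  "cds",  "ssc", "+", "966",  "", 220),
    g("ndhD",  "cds",  "ssc", "-", "1503", "", 90),
    g("psaC",  "cds",  "ssc", "-", "246",  "", 380),
    g("ndhA",  "cds",  "ssc", "-", "553,539", "1070", 140),
    g("ycf1",  "cds",  "ssc", "+", "1800", "", 300))
}

#' Simulation configuration
#'
#' @param n_taxa number of tips (>= 4).
#' @param seed integer master seed; every stochastic step derives its stream
#'   from it.
#' @param birth Yule birth rate for the tree shape.
#' @param base_rate expected substitutions per site from root to tip for a
#'   rate-multiplier of 1 (default 0.05, giving tip-to-tip K80 divergences
#'   around 0.05-0.1, the range plastome spacers show between confamilial
#'   species).
#' @param kappa transition/transversion rate ratio of the K80 process
#'   (default 2).
#' @param architecture genome blueprint, see [default_architecture()].
#' @param rate_multipliers named numeric vector of per-marker rate
#'   multipliers overriding the class defaults (`cds` 0.7, `tRNA` 0.5,
#'   `rRNA` 0.3, intron 1.3, spacer 1.8 -- non-coding markers evolve faster
#'   than coding ones, as in real plastomes).
#' @param lsc_leading_gap,ir_leading_gap,ssc_leading_gap intergenic gaps
#'   opening each region (bp). The IR leading gap hosts the 100 bp 3' end of
#'   the straddling rps19-style gene.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_taxa = 16L, seed = 1L, birth = 1,
                       base_rate = 0.05, kappa = 2,
                       architecture = default_architecture(),
                       rate_multipliers = NULL,
                       lsc_leading_gap = 200L, ir_leading_gap = 300L,
                       ssc_leading_gap = 250L) {
  stopifnot(n_taxa >= 4L, base_rate >= 0, kappa > 0,
            is.null(rate_multipliers) || all(rate_multipliers > 0))
  structure(list(n_taxa = as.integer(n_taxa), seed = as.integer(seed),
                 birth = birth, base_rate = base_rate, kappa = kappa,
                 architecture = architecture,
                 rate_multipliers = rate_multipliers,
                 lsc_leading_gap = as.integer(lsc_leading_gap),
                 ir_leading_gap = as.integer(ir_leading_gap),
                 ssc_leading_gap = as.integer(ssc_leading_gap),
                 straddle_bp = 100L),
            class = "sim_config")
}

#' Simulate a Yule tree
#'
#' Pure-birth tree with `n_taxa` tips, rescaled so the root-to-tip height is
#' 1; branch lengths are then converted to expected substitutions per site
#' by the per-marker rate at evolution time. Reproducible by seed.
#'
#' @param n_taxa number of tips.
#' @param birth Yule birth rate.
#' @param seed integer seed.
#' @return an ultrametric `phylo` with tips `t01`, `t02`, ...
#' @export
simulate_tree <- function(n_taxa = 16L, birth = 1, seed = 1L) {
  set.seed(seed)
  tr <- ape::rphylo(n_taxa, birth = birth, death = 0)
  depth <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- tr$edge.length / depth
  tr$tip.label <- sprintf("t%02d", seq_len(n_taxa))
  tr
}

# K80 transition-probability matrix for branch length t (subs/site) and
# kappa; state order A, C, G, T
k80_pmat <- function(t, kappa) {
  b <- t / (kappa + 2)
  e1 <- exp(-4 * b)
  e2 <- exp(-2 * b * (kappa + 1))
  same <- 0.25 + 0.25 * e1 + 0.5 * e2
  ts <- 0.25 + 0.25 * e1 - 0.5 * e2     # transition (A<->G, C<->T)
  tv <- 0.25 - 0.25 * e1                # each transversion target
  P <- matrix(tv, 4, 4)
  diag(P) <- same
  P[1, 3] <- P[3, 1] <- ts
  P[2, 4] <- P[4, 2] <- ts
  P
}

#' Evolve one marker along a tree under K80
#'
#' The root sequence is i.i.d. uniform over A/C/G/T; each branch applies the
#' closed-form K80 transition probabilities for its length (scaled by
#' `rate`), independently per column. Gap-free by construction, so the
#' simulated matrix is its own alignment.
#'
#' @param tree a `phylo` with branch lengths.
#' @param length marker length in bp (>= 1).
#' @param rate expected substitutions/site per unit branch length (the
#'   product of the cohort base rate and the marker's rate multiplier).
#' @param kappa transition/transversion rate ratio.
#' @param seed integer seed.
#' @param name,mclass passed to [marker_alignment()].
#' @return a gap-free [marker_alignment()] with one row per tip.
#' @export
evolve_marker <- function(tree, length, rate, kappa = 2, seed = 1L,
                          name = "marker", mclass = "other") {
  stopifnot(length >= 1L, rate >= 0)
  set.seed(seed)
  n <- base::length(tree$tip.label)
  nnode <- tree$Nnode
  states <- matrix(NA_integer_, n + nnode, length)
  root <- n + 1L
  states[root, ] <- sample.int(4L, length, replace = TRUE)
  ord <- ape::reorder.phylo(tree, "postorder")
  edges <- ord$edge[rev(seq_len(nrow(ord$edge))), , drop = FALSE]  # preorder
  elens <- ord$edge.length[rev(seq_len(nrow(ord$edge)))]
  for (e in seq_len(nrow(edges))) {
    par <- edges[e, 1L]; child <- edges[e, 2L]
    P <- k80_pmat(elens[e] * rate, kappa)
    parent_state <- states[par, ]
    child_state <- integer(length)
    for (s in 1:4) {
      idx <- which(parent_state == s)
      if (base::length(idx))
        child_state[idx] <- sample.int(4L, base::length(idx),
                                       replace = TRUE, prob = P[s, ])
    }
    states[child, ] <- child_state
  }
  rows <- vapply(seq_len(n), function(i) int_to_seq(states[i, ]), character(1))
  names(rows) <- tree$tip.label
  marker_alignment(rows, name, mclass)
}

# default per-class rate multipliers
CLASS_RATE <- c(cds = 0.7, tRNA = 0.5, rRNA = 0.3,
                intron = 1.3, spacer = 1.8)

# enumerate every marker implied by an architecture: coding/tRNA/rRNA gene
# sequences, introns, named spacers, and region-leading gaps
architecture_markers <- function(config) {
  arch <- config$architecture
  mk <- list()
  add <- function(name, mclass, length, region) {
    mk[[length(mk) + 1L]] <<- data.frame(marker = name, mclass = mclass,
                                         length = length, region = region)
  }
  for (r in seq_len(nrow(arch))) {
    a <- arch[r, ]
    exons <- as.integer(strsplit(a$exon_bp, ",")[[1L]])
    introns <- if (nzchar(a$intron_bp))
      as.integer(strsplit(a$intron_bp, ",")[[1L]]) else integer(0)
    add(a$name, if (a$ftype == "cds") "cds" else a$ftype, sum(exons), a$region)
    if (length(introns) == 1L) add(paste(a$name, "intron"), "intron",
                                   introns, a$region)
    else for (k in seq_along(introns))
      add(paste(a$name, "intron", k), "intron", introns[k], a$region)
    # spacer to the next gene in the same region (last gene's gap_after
    # runs into the next region boundary and is named at assembly time)
    nxt <- if (r < nrow(arch) && arch$region[r + 1L] == a$region)
      arch$name[r + 1L] else NULL
    if (a$gap_after > 0L) {
      nm <- if (is.null(nxt)) paste0(a$name, "-tail")
            else paste(paste0(a$name, "-", nxt), "spacer")
      add(nm, "spacer", a$gap_after, a$region)
    }
  }
  add("lsc-lead", "spacer", config$lsc_leading_gap, "lsc")
  add("ir-lead", "spacer",
      config$ir_leading_gap - config$straddle_bp, "ir")
  add("ssc-lead", "spacer", config$ssc_leading_gap, "ssc")
  do.call(rbind, mk)
}

# per-marker rate multiplier: class default unless overridden by name
marker_multipliers <- function(config, markers) {
  cls <- markers$mclass
  mult <- unname(CLASS_RATE[ifelse(cls %in% names(CLASS_RATE), cls, "spacer")])
  names(mult) <- markers$marker
  if (!is.null(config$rate_multipliers)) {
    ov <- config$rate_multipliers
    hit <- intersect(names(ov), names(mult))
    mult[hit] <- ov[hit]
  }
  mult
}

#' Simulate a cohort of annotated plastomes
#'
#' Runs the full generator: Yule tree, per-marker K80 evolution at
#' heterogeneous rates, and per-taxon assembly into annotated circular
#' genomes with an exact inverted-repeat duplication. Identical
#' configuration and seed give byte-identical output.
#'
#' @param config a [sim_config()].
#' @return list with elements `genomes` (list of [circular_genome()]),
#'   `tree` (the true `phylo`), `alignments` (named list of the gap-free
#'   per-marker [marker_alignment()]s), and `truth` (data frame: `marker`,
#'   `mclass`, `length`, `region`, `rate_multiplier`, plus per-taxon
#'   realised IR/region lengths in `attr(truth, "structure")`).
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  tree <- simulate_tree(config$n_taxa, config$birth, config$seed)
  markers <- architecture_markers(config)
  mult <- marker_multipliers(config, markers)
  alignments <- vector("list", nrow(markers))
  names(alignments) <- markers$marker
  for (i in seq_len(nrow(markers))) {
    alignments[[i]] <- evolve_marker(
      tree, markers$length[i],
      rate = config$base_rate * mult[[markers$marker[i]]],
      kappa = config$kappa,
      seed = (config$seed * 10007L + i) %% 2147483647L,
      name = markers$marker[i], mclass = markers$mclass[i])
  }
  genomes <- lapply(tree$tip.label, function(tx)
    assemble_genome_taxon(tx, config, markers, alignments))
  names(genomes) <- tree$tip.label
  truth <- cbind(markers, rate_multiplier = unname(mult[markers$marker]))
  attr(truth, "structure") <- do.call(rbind, lapply(genomes, function(g)
    attr(g, "planted_structure")))
  list(genomes = genomes, tree = tree, alignments = alignments,
       truth = truth)
}

# lay out one taxon's genome: LSC | IRa | SSC | IRb = revcomp(IRa)
assemble_genome_taxon <- function(taxon, config, markers, alignments) {
  arch <- config$architecture
  seq_of <- function(marker) alignments[[marker]]$rows[[taxon]]
  feats <- list()
  pieces <- character(0)
  pos <- 0L
  emit <- function(s) { pieces <<- c(pieces, s); pos <<- pos + nchar(s); invisible(NULL) }
  add_feat <- function(name, ftype, parts, pseudo = FALSE)
    feats[[length(feats) + 1L]] <<- feature(name, ftype, parts, pseudo)

  # lay one gene down at the current position; returns its annotation parts
  lay_gene <- function(a) {
    exons <- as.integer(strsplit(a$exon_bp, ",")[[1L]])
    introns <- if (nzchar(a$intron_bp))
      as.integer(strsplit(a$intron_bp, ",")[[1L]]) else integer(0)
    stopifnot(length(introns) == length(exons) - 1L || length(introns) == 0L)
    gene_seq <- seq_of(a$name)                       # concatenated exons, 5'->3'
    intron_names <- if (length(introns) == 0L) character(0)
                    else if (length(introns) == 1L) paste(a$name, "intron")
                    else paste(a$name, "intron", seq_along(introns))
    # genome-order layout: on '-' strand the stored sequence is the revcomp
    # and exon/intron genome order is reversed
    if (a$strand == "+") {
      ex_seqs <- split_lengths(gene_seq, exons)
      in_seqs <- lapply(intron_names, seq_of)
    } else {
      ex_seqs <- rev(lapply(split_lengths(gene_seq, exons), revcomp))
      in_seqs <- rev(lapply(intron_names, function(nm) revcomp(seq_of(nm))))
    }
    parts <- NULL
    for (k in seq_along(ex_seqs)) {
      s0 <- pos
      emit(ex_seqs[[k]])
      parts <- rbind(parts, data.frame(start = s0, end = pos,
                                       strand = a$strand))
      if (k < length(ex_seqs)) emit(in_seqs[[k]])
    }
    parts
  }

  annotate <- function(a, parts) {
    add_feat(a$name, "gene", parts)
    add_feat(a$name, if (a$ftype == "cds") "CDS" else a$ftype, parts)
  }

  # --- LSC ---
  emit(seq_of("lsc-lead"))
  lsc_rows <- which(arch$region == "lsc")
  rps19_parts <- NULL
  for (r in lsc_rows) {
    a <- arch[r, ]
    parts <- lay_gene(a)
    if (r == lsc_rows[length(lsc_rows)] && a$gap_after == 0L) {
      rps19_parts <- list(a = a, parts = parts)   # annotated after straddle
    } else {
      annotate(a, parts)
      if (a$gap_after > 0L) {
        nxt <- if (r < nrow(arch) && arch$region[r + 1L] == "lsc")
          arch$name[r + 1L] else NULL
        nm <- if (is.null(nxt)) paste0(a$name, "-tail")
              else paste(paste0(a$name, "-", nxt), "spacer")
        emit(seq_of(nm))
      }
    }
  }
  lsc_end <- pos

  # --- IRa block ---
  ir_start <- pos
  ir_pieces_start <- length(pieces) + 1L
  # straddle: the last `straddle_bp` bases of the straddling gene open the IR
  if (!is.null(rps19_parts)) {
    a <- rps19_parts$a
    parts <- rps19_parts$parts
    sb <- config$straddle_bp
    # the gene was laid entirely in the LSC; move its genome-order leading
    # `sb` bases (its 3' end on the '-' strand) into the IR by splitting the
    # annotation at the region boundary
    # simpler layout rule: the gene's final `sb` genome bases fall after the
    # boundary, i.e. the boundary cuts the last exon `sb` bases before its end
    last <- nrow(parts)
    stopifnot(parts$end[last] - parts$start[last] > sb)
    ir_start <- parts$end[last] - sb
    annotate(a, parts)
  }
  emit(seq_of("ir-lead"))
  ir_rows <- which(arch$region == "ir")
  for (r in ir_rows) {
    a <- arch[r, ]
    parts <- lay_gene(a)
    annotate(a, parts)
    if (a$gap_after > 0L) {
      nxt <- if (r < nrow(arch) && arch$region[r + 1L] == "ir")
        arch$name[r + 1L] else NULL
      nm <- if (is.null(nxt)) paste0(a$name, "-tail")
            else paste(paste0(a$name, "-", nxt), "spacer")
      emit(seq_of(nm))
    }
  }
  ir_end <- pos
  ir_block_seq <- substr(paste(pieces, collapse = ""), ir_start + 1L, ir_end)
  # features fully inside the IR block, to be mirrored into IRb
  ir_feats <- Filter(function(f) min(f$parts$start) >= ir_start &&
                       max(f$parts$end) <= ir_end, feats)

  # --- SSC ---
  emit(seq_of("ssc-lead"))
  ssc_rows <- which(arch$region == "ssc")
  for (r in ssc_rows) {
    a <- arch[r, ]
    parts <- lay_gene(a)
    annotate(a, parts)
    if (a$gap_after > 0L) {
      nxt <- if (r < nrow(arch) && arch$region[r + 1L] == "ssc")
        arch$name[r + 1L] else NULL
      nm <- if (is.null(nxt)) paste0(a$name, "-tail")
            else paste(paste0(a$name, "-", nxt), "spacer")
      emit(seq_of(nm))
    }
  }
  ssc_end <- pos

  # --- IRb: exact reverse complement of the IRa block ---
  irb_start <- pos
  emit(revcomp(ir_block_seq))
  n <- pos
  B <- ir_end - ir_start
  mirror <- function(parts) {
    p <- parts
    for (k in seq_len(nrow(p))) {
      s <- parts$start[k] - ir_start; e <- parts$end[k] - ir_start
      p$start[k] <- irb_start + (B - e)
      p$end[k] <- irb_start + (B - s)
      p$strand[k] <- if (parts$strand[k] == "+") "-" else "+"
    }
    p[order(p$start), , drop = FALSE]
  }
  for (f in ir_feats)
    add_feat(f$name, f$ftype, mirror(f$parts), f$pseudo)

  seq <- paste(pieces, collapse = "")
  g <- circular_genome(taxon, seq, feats)
  # realised maximal IR: the planted block plus any chance outward extension
  ext <- ir_extension(seq, ir_start, ir_end, irb_start, n)
  attr(g, "planted_structure") <- data.frame(
    taxon = taxon, genome_bp = n,
    lsc_bp = ir_start, ir_bp = B, ssc_bp = irb_start - ir_end,
    planted_ir_start = ir_start, planted_irb_start = irb_start,
    realised_ir_bp = B + ext,
    stringsAsFactors = FALSE)
  g
}

# chance outward extension of the planted IR pair (both directions)
ir_extension <- function(seq, ir_start, ir_end, irb_start, n) {
  v <- strsplit(seq, "", fixed = TRUE)[[1L]]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  ext <- 0L
  # grow left of IRa / right of IRb
  i <- ir_start - 1L; j <- irb_start + (ir_end - ir_start)  # 0-based
  while (ext < n) {
    ii <- i %% n; jj <- j %% n
    if (ii == jj) break
    a <- v[ii + 1L]; b <- v[jj + 1L]
    if (is.na(comp[a]) || comp[[a]] != b) break
    ext <- ext + 1L; i <- i - 1L; j <- j + 1L
  }
  # grow right of IRa / left of IRb
  i <- ir_end; j <- irb_start - 1L
  while (ext < n) {
    ii <- i %% n; jj <- j %% n
    if (ii == jj) break
    a <- v[ii + 1L]; b <- v[jj + 1L]
    if (is.na(comp[a]) || comp[[a]] != b) break
    ext <- ext + 1L; i <- i + 1L; j <- j - 1L
  }
  ext
}

# split a string into consecutive chunks of the given lengths
split_lengths <- function(s, lens) {
  stopifnot(nchar(s) == sum(lens))
  ends <- cumsum(lens)
  starts <- c(1L, ends[-length(ends)] + 1L)
  lapply(seq_along(lens), function(i) substr(s, starts[i], ends[i]))
}

#' Punch gap blocks into an alignment (optional indel mode)
#'
#' Introduces geometric-length gap runs into random rows. The generator does
#' not simulate indels by default (so distance and site-count truths stay
#' exact); this utility exists to exercise gap handling and
#' [mask_poorly_aligned()].
#'
#' @param a a [marker_alignment()].
#' @param n_blocks number of gap blocks to place.
#' @param mean_len geometric mean block length.
#' @param seed integer seed.
#' @return a gappier [marker_alignment()].
#' @export
add_indel_gaps <- function(a, n_blocks = 3L, mean_len = 20L, seed = 1L) {
  set.seed(seed)
  m <- aln_matrix(a)
  w <- ncol(m)
  for (b in seq_len(n_blocks)) {
    len <- min(w, stats::rgeom(1L, 1 / mean_len) + 1L)
    at <- sample.int(w - len + 1L, 1L)
    row <- sample.int(nrow(m), 1L)
    m[row, at:(at + len - 1L)] <- "-"
  }
  aln_from_matrix(m, a)
}

#' Write a simulated cohort to disk
#'
#' GenBank flat files (one per taxon), the true tree as Newick, and the
#' marker truth table as TSV.
#'
#' @param cohort result of [simulate_cohort()].
#' @param outdir output directory (created if missing).
#' @return named character vector of written paths, invisibly.
#' @export
write_cohort <- function(cohort, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (g in cohort$genomes) {
    p <- file.path(outdir, paste0(g$id, ".gb"))
    write_genbank(g, p)
    paths[g$id] <- p
  }
  tp <- file.path(outdir, "true_tree.nwk")
  write_newick(cohort$tree, tp)
  paths["tree"] <- tp
  tt <- file.path(outdir, "marker_truth.tsv")
  utils::write.table(cohort$truth, tt, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths["truth"] <- tt
  invisible(paths)
}
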