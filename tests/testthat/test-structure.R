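# Quadripartite partitioning and region/class accounting.

test_that("planted inverted repeats are recovered exactly", {
  set.seed(11)
  seq <- planted_ir_sequence(500, 200, 180)
  g <- circular_genome("planted", seq)
  p <- detect_inverted_repeats(g, min_ir = 100)
  expect_equal(p$ir_length, 200L)
  expect_equal(unname(p$lsc["end"] - p$lsc["start"]), 500)
  expect_equal(unname(p$ssc["end"] - p$ssc["start"]), 180)
  # IRa is the exact reverse complement of IRb
  ira <- plastrank:::circ_substr(g$seq, p$ira["start"], p$ira["end"], g$length)
  irb <- plastrank:::circ_substr(g$seq, p$irb["start"], p$irb["end"], g$length)
  expect_identical(ira, revcomp(irb))
})

test_that("IR detection is invariant under rotation and reverse complement", {
  set.seed(12)
  seq <- planted_ir_sequence(420, 150, 160)
  lens <- function(p) sort(c(p$ir_length,
                             unname(p$lsc["end"] - p$lsc["start"]),
                             unname(p$ssc["end"] - p$ssc["start"])))
  p0 <- detect_inverted_repeats(circular_genome("a", seq), min_ir = 100)
  for (rot in c(137, 411, 799)) {
    r <- paste0(substr(seq, rot + 1, nchar(seq)), substr(seq, 1, rot))
    pr <- detect_inverted_repeats(circular_genome("r", r), min_ir = 100)
    expect_equal(lens(pr), lens(p0))
  }
  prc <- detect_inverted_repeats(circular_genome("rc", revcomp(seq)),
                                 min_ir = 100)
  expect_equal(lens(prc), lens(p0))
})

test_that("detection agrees with the brute-force all-pairs oracle on small circles", {
  set.seed(13)
  for (case in 1:3) {
    seq <- planted_ir_sequence(sample(160:240, 1), sample(100:150, 1),
                               sample(120:180, 1))
    g <- circular_genome(paste0("c", case), seq)
    p <- detect_inverted_repeats(g, min_ir = 100)
    expect_equal(p$ir_length, brute_max_ir(seq, 100L))
  }
})

test_that("absence of a qualifying repeat raises a structured no-IR error", {
  set.seed(14)
  seq <- random_dna(5000)
  # brute confirmation that no >= 1000 bp inverted repeat exists is implicit:
  # chance maxima on 5 kb are ~10 bp
  expect_error(detect_inverted_repeats(circular_genome("r", seq),
                                       min_ir = 1000),
               "no-IR")
})

test_that("gc_content follows the ACGT-only convention", {
  expect_equal(gc_content("ATGC"), 0.5)
  expect_equal(gc_content("GGCC"), 1.0)
  expect_equal(gc_content("GCNNNN--AT"), 0.5)   # ambiguity and gaps excluded
  expect_equal(gc_content("acgt"), 0.5)
  expect_error(gc_content("NNNN"), "undefined")
  set.seed(15)
  s <- random_dna(500)
  expect_equal(gc_content(revcomp(s)), gc_content(s))
})

test_that("region stats tile the genome and match planted lengths", {
  set.seed(16)
  g <- circular_genome("planted", planted_ir_sequence(700, 260, 240))
  p <- detect_inverted_repeats(g, min_ir = 100)
  rs <- region_stats(g, p)
  expect_equal(rs$length_bp[rs$region == "LSC"], 700)
  expect_equal(rs$length_bp[rs$region == "SSC"], 240)
  expect_equal(rs$length_bp[rs$region == "IR"], 260)
  expect_equal(sum(rs$length_bp[rs$region %in% c("LSC", "SSC")]) +
                 2 * rs$length_bp[rs$region == "IR"],
               rs$length_bp[rs$region == "full"])
  expect_true(all(rs$gc >= 0 & rs$gc <= 1))
})

test_that("class painting respects the CDS > tRNA > rRNA > intron precedence", {
  set.seed(17)
  seq <- random_dna(1000)
  g <- circular_genome("cls", seq, list(
    feature("big", "gene", data.frame(start = 100, end = 400, strand = "+")),
    feature("big", "CDS", data.frame(start = 100, end = 400, strand = "+")),
    feature("t1", "tRNA", data.frame(start = 500, end = 570, strand = "+")),
    # intron annotation fully inside the CDS: CDS wins
    feature("big", "intron", data.frame(start = 150, end = 250, strand = "+"))))
  cs <- class_stats(g)
  cl <- cs$classes
  expect_equal(cl$length_bp[cl$class == "protein_coding"], 300)
  expect_equal(cl$length_bp[cl$class == "trna"], 70)
  expect_equal(cl$length_bp[cl$class == "intron"], 0)
  expect_equal(cl$length_bp[cl$class == "intergenic"], 1000 - 300 - 70)
  expect_equal(sum(cl$length_bp), g$length)
  expect_equal(unname(cs$gene_counts),
               c(1L, 1L, 0L))
})

test_that("junction report names straddling genes or flanking pairs", {
  set.seed(18)
  seq <- planted_ir_sequence(600, 220, 200)
  # gene straddling the LSC-IRa boundary at position 600
  g <- circular_genome("jx", seq, list(
    feature("strad", "gene", data.frame(start = 550, end = 650, strand = "+")),
    feature("left", "gene", data.frame(start = 100, end = 200, strand = "+")),
    feature("right", "gene", data.frame(start = 300, end = 400, strand = "+"))))
  p <- detect_inverted_repeats(g, min_ir = 100)
  jx <- report_junctions(g, p)
  expect_equal(jx$in_feature[jx$junction == "LSC-IRa"], "strad")
  # IRb-LSC boundary (position 0) falls between genes: flanked by strad/left
  row <- jx[jx$junction == "IRb-LSC", ]
  expect_true(is.na(row$in_feature))
  expect_equal(row$flank_left, "strad")
  expect_equal(row$flank_right, "left")
})

test_that("cohort summaries use the sample (n-1) standard deviation", {
  tab <- data.frame(lsc_bp = c(100, 104, 108), full_bp = c(500, 500, 500))
  s <- summarize_cohort(tab)
  expect_equal(s$summary$sd[s$summary$column == "lsc_bp"], 4)   # sd with n-1
  expect_equal(s$summary$sd[s$summary$column == "full_bp"], 0)
  expect_equal(s$summary$mean[s$summary$column == "lsc_bp"], 104)
})

test_that("cohort summary over simulated genomes matches planted structure", {
  co <- simulate_cohort(sim_config(n_taxa = 4, seed = 21))
  s <- summarize_cohort(co$genomes, min_ir = 1000)
  truth <- attr(co$truth, "structure")
  expect_equal(sort(s$table$full_bp), sort(truth$genome_bp))
  expect_equal(sort(s$table$ir_bp), sort(truth$realised_ir_bp))
})
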