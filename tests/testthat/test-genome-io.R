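# Genome model and GenBank/FASTA I/O.

test_that("coordinate conversion and feature validation behave", {
  # 1-based inclusive (a, b) <-> 0-based half-open (a-1, b), length preserved
  p <- plastrank:::parse_gb_location("10..20", 100, "x")
  expect_equal(p$start, 9L)
  expect_equal(p$end, 20L)
  expect_equal(p$end - p$start, 20L - 10L + 1L)

  p2 <- plastrank:::parse_gb_location("join(10..20,30..40)", 100, "x")
  expect_equal(p2$start, c(9L, 29L))
  expect_equal(p2$end, c(20L, 40L))
  expect_equal(p2$strand, c("+", "+"))

  pc <- plastrank:::parse_gb_location("complement(join(10..20,30..40))", 100, "x")
  expect_true(all(pc$strand == "-"))

  # origin-spanning join unwraps to end > length
  pw <- plastrank:::parse_gb_location("join(95..100,1..7)", 100, "x")
  expect_equal(nrow(pw), 1L)
  expect_equal(pw$start, 94L)
  expect_equal(pw$end, 107L)

  expect_error(feature("bad", "gene",
                       data.frame(start = 10, end = 10, strand = "+")),
               "degenerate")
  expect_error(circular_genome("g", "ACGT", list(
    feature("far", "gene", data.frame(start = 9, end = 12, strand = "+")))),
    "outside")
})

test_that("GenBank write/read round-trips sequence and features exactly", {
  set.seed(101)
  g <- toy_genome()
  tf <- withr::local_tempfile(fileext = ".gb")
  write_genbank(g, tf)
  g2 <- read_genbank(tf)
  expect_identical(g2$seq, g$seq)
  expect_equal(length(g2$features), length(g$features))
  for (i in seq_along(g$features)) {
    expect_identical(g2$features[[i]]$name, g$features[[i]]$name)
    expect_identical(g2$features[[i]]$ftype, g$features[[i]]$ftype)
    expect_equal(g2$features[[i]]$parts$start, g$features[[i]]$parts$start)
    expect_equal(g2$features[[i]]$parts$end, g$features[[i]]$parts$end)
    expect_identical(g2$features[[i]]$parts$strand, g$features[[i]]$parts$strand)
  }

  # simulator output round-trips too (includes minus-strand multi-part genes)
  co <- simulate_cohort(sim_config(n_taxa = 4, seed = 3))
  gs <- co$genomes[[2]]
  tf2 <- withr::local_tempfile(fileext = ".gb")
  write_genbank(gs, tf2)
  gs2 <- read_genbank(tf2)
  expect_identical(gs2$seq, gs$seq)
  expect_equal(length(gs2$features), length(gs$features))
  starts2 <- lapply(gs2$features, function(f) f$parts$start)
  starts1 <- lapply(gs$features, function(f) f$parts$start)
  expect_equal(starts2, starts1)
})

test_that("origin-spanning features render as a join across the origin", {
  set.seed(7)
  g <- circular_genome("x", random_dna(200), list(
    feature("wrap", "gene", data.frame(start = 190, end = 210, strand = "+"))))
  tf <- withr::local_tempfile(fileext = ".gb")
  write_genbank(g, tf)
  expect_true(any(grepl("join(191..200,1..10)", readLines(tf), fixed = TRUE)))
  g2 <- read_genbank(tf)
  expect_equal(g2$features[[1]]$parts$start, 190L)
  expect_equal(g2$features[[1]]$parts$end, 210L)
})

test_that("GenBank reader rejects records without sequence; writer handles empty feature lists", {
  tf <- withr::local_tempfile(fileext = ".gb")
  writeLines(c("LOCUS       x 10 bp", "FEATURES", "//"), tf)
  expect_error(read_genbank(tf), "ORIGIN")

  set.seed(8)
  g <- circular_genome("bare", random_dna(90))
  tf2 <- withr::local_tempfile(fileext = ".gb")
  write_genbank(g, tf2)
  g2 <- read_genbank(tf2)
  expect_identical(g2$seq, g$seq)
  expect_length(g2$features, 0L)
})

test_that("non-IUPAC residues are replaced with N with a warning", {
  expect_warning(g <- circular_genome("odd", "ACGTXZACGT"), "IUPAC")
  expect_identical(g$seq, "ACGTNNACGT")
})

test_that("FASTA alignment round-trips; ragged and duplicate inputs error", {
  set.seed(9)
  a <- random_alignment(3, 40)
  tf <- withr::local_tempfile(fileext = ".fasta")
  write_fasta_alignment(a, tf)
  a2 <- read_fasta_alignment(tf, name = a$name)
  expect_identical(a2$rows, a$rows)

  tf2 <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACGT", ">b", "ACG"), tf2)
  expect_error(read_fasta_alignment(tf2), "ragged")
  tf3 <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACGT", ">a", "ACGT"), tf3)
  expect_error(read_fasta_alignment(tf3), "duplicate")
  tf4 <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "acgt", ">b", "tgca"), tf4)
  expect_identical(unname(read_fasta_alignment(tf4)$rows), c("ACGT", "TGCA"))
})
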