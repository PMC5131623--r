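# Site counts, K80 distances, recoding, translation, masking, schemes.

test_that("variable and parsimony-informative site counts match definitions", {
  a <- marker_alignment(c(a = "ACGT", b = "ACGT", c = "ACGT", d = "ACGT"))
  expect_equal(count_variable_sites(a), 0L)
  expect_equal(count_parsimony_informative(a), 0L)

  b <- marker_alignment(c(a = "ACGT", b = "ACGA", c = "ACGT", d = "ACGT"))
  expect_equal(count_variable_sites(b), 1L)     # singleton column
  expect_equal(count_parsimony_informative(b), 0L)

  cc <- marker_alignment(c(a = "AA", b = "AA", c = "CA", d = "CA"))
  expect_equal(count_parsimony_informative(cc), 1L)

  # gaps and ambiguity are ignored
  d <- marker_alignment(c(a = "A-N", b = "AWN", c = "A-N", d = "A-N"))
  expect_equal(count_variable_sites(d), 0L)
})

test_that("site counts equal the brute-force per-column oracle on random alignments", {
  set.seed(31)
  for (i in 1:25) {
    a <- random_alignment(sample(4:10, 1), sample(20:120, 1),
                          gap_frac = sample(c(0, 0.1), 1))
    expect_equal(count_variable_sites(a), brute_variable_sites(a))
    expect_equal(count_parsimony_informative(a), brute_pis(a))
  }
})

test_that("removing a taxon never increases the variable-site count", {
  set.seed(32)
  for (i in 1:10) {
    a <- random_alignment(6, 80)
    sub <- marker_alignment(a$rows[-1], a$name, a$mclass)
    expect_lte(count_variable_sites(sub), count_variable_sites(a))
    expect_lte(count_parsimony_informative(marker_alignment(a$rows[-(1:2)])),
               count_variable_sites(a))
  }
})

test_that("K80 distance evaluates its closed form and handles saturation", {
  expect_equal(k80_distance("ACGTACGT", "ACGTACGT"), 0)
  # 100 sites: 10 transitions (A<->G), 5 transversions (A<->C)
  x <- strrep("A", 100)
  y <- paste0(strrep("G", 10), strrep("C", 5), strrep("A", 85))
  expect_equal(round(k80_distance(x, y), 4), 0.1702)
  # P = 0.5, Q = 0: log of a non-positive number -> saturation
  x2 <- strrep("A", 10)
  y2 <- paste0(strrep("G", 5), strrep("A", 5))
  expect_warning(d <- k80_distance(x2, y2), "saturation")
  expect_true(is.na(d))
  # pairwise deletion: distance unchanged by adding gap columns
  expect_equal(k80_distance(paste0(x, "----"), paste0(y, "ACGT")),
               k80_distance(x, y))
  expect_error(k80_distance("NNN", "ACG"), "undefined")
  # symmetry (moderately diverged pair, below saturation)
  set.seed(33)
  s1 <- strsplit(random_dna(200), "")[[1]]
  s2 <- s1
  flip <- sample.int(200, 25)
  s2[flip] <- vapply(s1[flip], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
  s1 <- paste(s1, collapse = ""); s2 <- paste(s2, collapse = "")
  expect_equal(k80_distance(s1, s2), k80_distance(s2, s1))
  expect_gt(k80_distance(s1, s2), 0)
})

test_that("K80 estimates agree with ape::dist.dna on simulated alignments", {
  co <- simulate_cohort(sim_config(n_taxa = 5, seed = 35))
  a <- co$alignments[["ndhF-rpl32 spacer"]]
  d1 <- k80_matrix(a)
  bin <- ape::as.DNAbin(do.call(rbind, strsplit(tolower(a$rows), "")))
  d2 <- as.matrix(ape::dist.dna(bin, model = "K80"))
  expect_equal(unname(d1), unname(d2[rownames(d1), colnames(d1)]),
               tolerance = 1e-12)
})

test_that("alignment summary fields are consistent", {
  set.seed(36)
  tr6 <- simulate_tree(6, seed = 36)
  a <- evolve_marker(tr6, 150, rate = 0.3, kappa = 2, seed = 36)
  s <- summarize_alignment(a)
  expect_lte(s$pis_n, s$variable_n)
  expect_lte(s$variable_n, s$aligned_bp)
  expect_gte(s$k80_mean, 0)
  expect_equal(s$aligned_bp, 150L)
  expect_equal(s$bases_mean, 150)

  ident <- marker_alignment(setNames(rep(strrep("ACGT", 10), 4),
                                     paste0("t", 1:4)))
  si <- summarize_alignment(ident)
  expect_equal(si$variable_n, 0L)
  expect_equal(si$k80_mean, 0)
})

test_that("RLS codon ambiguation recodes families and is idempotent", {
  rows <- c(t1 = "ATGCTTAGATCAAGTGGG",   # ATG CTT AGA TCA AGT GGG
            t2 = "ATGTTAAGGAGCTCCGGG",
            t3 = "ATG---CGANNNAGTGGG",
            t4 = "ATGCTGCGGTCGAGCGGG")
  a <- marker_alignment(rows, "cdsx", "cds")
  r <- ambiguate_rls_codons(a)
  expect_identical(substr(r$rows[["t1"]], 1, 3), "ATG")    # Met untouched
  expect_identical(substr(r$rows[["t1"]], 4, 6), "YTN")    # Leu CTT
  expect_identical(substr(r$rows[["t1"]], 7, 9), "MGN")    # Arg AGA
  expect_identical(substr(r$rows[["t1"]], 10, 12), "TCN")  # Ser TCA
  expect_identical(substr(r$rows[["t1"]], 13, 15), "AGY")  # Ser AGT
  expect_identical(substr(r$rows[["t2"]], 4, 6), "YTN")    # Leu TTA
  expect_identical(substr(r$rows[["t2"]], 7, 9), "MGN")    # Arg AGG
  expect_identical(substr(r$rows[["t2"]], 10, 12), "AGY")  # Ser AGC
  # gap/ambiguity codons unchanged
  expect_identical(substr(r$rows[["t3"]], 4, 6), "---")
  expect_identical(substr(r$rows[["t3"]], 10, 12), "NNN")
  # idempotence and width preservation
  expect_identical(ambiguate_rls_codons(r)$rows, r$rows)
  expect_equal(aln_width(r), aln_width(a))
  expect_error(ambiguate_rls_codons(marker_alignment(c(a = "ACGTA",
                                                       b = "ACGTA"))),
               "divisible")
})

test_that("translation uses the plastid code, drops terminal stops, flags internal ones", {
  a <- marker_alignment(c(x = "ATGGCTTAA", y = "ATGGCTTAA",
                          z = "ATG---TAA", w = "ATGGCNTAA"))
  p <- translate_cds(a)
  expect_identical(unname(p$rows), c("MA", "MA", "M-", "MX"))
  b <- marker_alignment(c(x = "ATGTAAGCT", y = "ATGTAAGCT"))
  expect_warning(pb <- translate_cds(b), "internal stop")
  expect_identical(unname(pb$rows[1]), "MXA")
})

test_that("gap-window masking removes planted gap blocks and nothing else", {
  set.seed(37)
  a <- random_alignment(6, 200)
  expect_identical(mask_poorly_aligned(a)$rows, a$rows)   # gap-free unchanged
  m <- plastrank:::aln_matrix(a)
  m[1:4, 101:150] <- "-"                                  # 50-col gappy block
  gappy <- plastrank:::aln_from_matrix(m, a)
  f <- mask_poorly_aligned(gappy, window = 5, max_gap_frac = 0.5)
  expect_lte(aln_width(f), aln_width(gappy))
  # the 50 planted columns plus the two flanking windows that tip over 0.5
  expect_equal(aln_width(f), 148L)
  expect_false(any(grepl("-", f$rows, fixed = TRUE)))
})

test_that("the six schemes satisfy their construction identities", {
  co <- simulate_cohort(sim_config(n_taxa = 5, seed = 38))
  sch <- plastrank:::cohort_schemes(co$genomes)
  expect_named(sch, c("ncs", "ncs_filtered", "cds", "cds_ambiguated",
                      "protein", "full"))
  expect_equal(aln_width(sch$full$alignment),
               aln_width(sch$ncs_filtered$alignment) +
                 aln_width(sch$cds$alignment))
  # scheme 4 equals scheme 3 after ambiguation
  amb <- ambiguate_rls_codons(sch$cds$alignment)
  expect_identical(sch$cds_ambiguated$alignment$rows, amb$rows)
  # partition map covers every column once
  part <- sch$full$partition
  expect_equal(sum(part$end - part$start + 1L),
               aln_width(sch$full$alignment))
  expect_true(all(part$frame[part$mclass == "cds"] == 1L))
})
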