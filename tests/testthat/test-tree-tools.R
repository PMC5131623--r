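# NJ inference, RF distance, bootstrap, Newick I/O.

test_that("NJ recovers the generating topology from additive distances", {
  set.seed(41)
  for (i in 1:5) {
    tr <- ape::rtree(sample(5:9, 1))
    tr$edge.length <- tr$edge.length + 0.05
    d <- stats::cophenetic(tr)
    d <- d[sort(rownames(d)), sort(rownames(d))]
    t2 <- nj_tree(d)
    expect_equal(rf_distance(t2, ape::unroot(tr)), 0)
  }
})

test_that("NJ resolves the four-point-condition split and validates input", {
  # distances favouring AB|CD
  d <- matrix(c(0, 2, 7, 7,
                2, 0, 7, 7,
                7, 7, 0, 2,
                7, 7, 2, 0), 4, 4,
              dimnames = list(c("A", "B", "C", "D"), c("A", "B", "C", "D")))
  tr <- nj_tree(d)
  bip <- plastrank:::tree_bipartitions(tr)
  expect_length(bip, 1L)
  expect_identical(bip, paste(c("C", "D"), collapse = "\r"))
  expect_error(nj_tree(d[1:3, 1:3]), "at least 4")
  d2 <- d; d2[1, 2] <- 5
  expect_error(nj_tree(d2), "symmetric")
})

test_that("NJ matches the reference implementation on random matrices", {
  set.seed(42)
  for (i in 1:5) {
    n <- sample(6:12, 1)
    x <- matrix(rnorm(n * 8), n)
    d <- as.matrix(stats::dist(x))
    dimnames(d) <- list(letters[1:n], letters[1:n])
    expect_equal(rf_distance(nj_tree(d), ape::nj(d)), 0)
  }
})

test_that("RF distance counts symmetric bipartition differences", {
  t1 <- ape::read.tree(text = "((A,B),(C,D));")
  t2 <- ape::read.tree(text = "((A,C),(B,D));")
  expect_equal(rf_distance(t1, t1), 0)
  expect_equal(rf_distance(t1, t2), 2)
  t3 <- ape::read.tree(text = "((A,B),(C,E));")
  expect_error(rf_distance(t1, t3), "taxon sets")
})

test_that("RF satisfies metric axioms and agrees with phangorn on random trees", {
  skip_if_not_installed("phangorn")
  set.seed(43)
  tips <- paste0("t", 1:12)
  rand_tree <- function() {
    tr <- ape::rtree(12)
    tr$tip.label <- sample(tips)
    tr
  }
  for (i in 1:10) {
    a <- rand_tree(); b <- rand_tree(); cc <- rand_tree()
    dab <- rf_distance(a, b)
    expect_equal(dab, rf_distance(b, a))
    expect_equal(rf_distance(a, a), 0)
    expect_lte(rf_distance(a, cc), dab + rf_distance(b, cc))
    expect_equal(dab, as.integer(phangorn::RF.dist(a, b)))
    expect_lte(dab, 2 * (12 - 3))
  }
})

test_that("bootstrap gives high support for strong signal, is seed-reproducible", {
  set.seed(44)
  # two deep clades, long internal edge: every internal split well supported
  tr <- ape::read.tree(text = paste0(
    "(((a1:0.02,a2:0.02):0.02,(a3:0.02,a4:0.02):0.02):0.3,",
    "((b1:0.02,b2:0.02):0.02,(b3:0.02,b4:0.02):0.02):0.3);"))
  a <- evolve_marker(tr, 5000, rate = 1, kappa = 2, seed = 99)
  bt <- bootstrap_support(a, replicates = 100, seed = 5)
  sup <- suppressWarnings(as.numeric(bt$node.label))
  sup <- sup[!is.na(sup)]
  expect_true(all(sup >= 95))
  expect_true(all(sup >= 0 & sup <= 100))
  # noise alignment: i.i.d. columns, sparse random minor alleles carrying no
  # tree signal (kept below K80 saturation); mean support collapses
  noise_m <- matrix("A", 8, 400)
  for (j in seq_len(400)) {
    base <- sample(c("A", "C", "G", "T"), 1)
    noise_m[, j] <- base
    if (runif(1) < 0.3) {
      k <- sample.int(3, 1)
      noise_m[sample.int(8, k), j] <- sample(setdiff(c("A", "C", "G", "T"),
                                                     base), 1)
    }
  }
  rownames(noise_m) <- tr$tip.label
  noise <- plastrank:::aln_from_matrix(
    noise_m, marker_alignment(setNames(rep("A", 8), tr$tip.label), "noise"))
  bt2 <- bootstrap_support(noise, replicates = 50, seed = 5)
  expect_lt(mean_support(bt2), mean_support(bt))
  # determinism
  bt3 <- bootstrap_support(a, replicates = 100, seed = 5)
  expect_identical(bt3$node.label, bt$node.label)
})

test_that("mean_support averages internal-edge supports", {
  tr <- ape::read.tree(text = "((A:1,B:1)50:1,(C:1,D:1)100:1,E:1);")
  expect_equal(mean_support(tr), 75)
  tr2 <- ape::read.tree(text = "((A:1,B:1)100:1,(C:1,D:1)100:1,E:1);")
  expect_equal(mean_support(tr2), 100)
})

test_that("Newick round trip preserves topology, lengths and supports", {
  set.seed(45)
  for (i in 1:5) {
    tr <- ape::rtree(8)
    tr$node.label <- c("", sample(50:100, tr$Nnode - 1, replace = TRUE))
    tf <- withr::local_tempfile(fileext = ".nwk")
    write_newick(tr, tf)
    tr2 <- read_newick(tf)
    expect_equal(rf_distance(tr, tr2), 0)
    expect_equal(tr2$edge.length, tr$edge.length, tolerance = 1e-9)
    expect_identical(tr2$node.label, as.character(tr$node.label))
  }
  # trifurcating (unrooted-style) root accepted
  tf3 <- withr::local_tempfile(fileext = ".nwk")
  writeLines("(A:1,B:1,(C:1,D:1):1);", tf3)
  t3 <- read_newick(tf3)
  expect_equal(length(t3$tip.label), 4L)
  tf <- withr::local_tempfile()
  writeLines("((A,B,(C", tf)
  expect_error(read_newick(tf))
})
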