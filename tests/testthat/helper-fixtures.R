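# Shared fixtures and independent oracles, built in code.

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

# random gap-free alignment as a marker_alignment
random_alignment <- function(n_taxa, width, gap_frac = 0) {
  alphabet <- c("A", "C", "G", "T")
  rows <- vapply(seq_len(n_taxa), function(i) {
    v <- sample(alphabet, width, replace = TRUE)
    if (gap_frac > 0) {
      k <- rbinom(1L, width, gap_frac)
      if (k > 0) v[sample.int(width, k)] <- "-"
    }
    paste(v, collapse = "")
  }, character(1))
  names(rows) <- sprintf("s%02d", seq_len(n_taxa))
  marker_alignment(rows, "random", "other")
}

# --- independent per-column site-count oracles (brute force) ---
brute_variable_sites <- function(a) {
  m <- do.call(rbind, strsplit(a$rows, "", fixed = TRUE))
  count <- 0L
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    col <- col[col %in% c("A", "C", "G", "T")]
    if (length(unique(col)) >= 2L) count <- count + 1L
  }
  count
}

brute_pis <- function(a) {
  m <- do.call(rbind, strsplit(a$rows, "", fixed = TRUE))
  count <- 0L
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    col <- col[col %in% c("A", "C", "G", "T")]
    tab <- table(col)
    if (sum(tab >= 2L) >= 2L) count <- count + 1L
  }
  count
}

# --- brute-force maximal inverted repeat on a small circular sequence ---
# O(n^2 log n): for every ordered pair of start positions, extend the exact
# inverted-repeat match; returns the maximal disjoint pair length
brute_max_ir <- function(seq, min_ir) {
  v <- strsplit(seq, "", fixed = TRUE)[[1L]]
  n <- length(v)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  best <- 0L
  for (i in 0:(n - 1L)) {
    for (j in 0:(n - 1L)) {
      if (i == j) next
      # grow the match S[i+k] == comp(S[j-1-k]); partner interval is [j-L, j)
      L <- 0L
      repeat {
        k <- L
        p1 <- (i + k) %% n
        p2 <- (j - 1L - k) %% n   # growing match ending at j-1 going left
        if (p1 == p2) break
        if (comp[[v[p1 + 1L]]] != v[p2 + 1L]) break
        L <- L + 1L
        if (L >= n %/% 2L) break
      }
      if (L >= min_ir) {
        # disjointness: intervals [i, i+L) and [j-L, j) mod n, both gaps >= 1
        s2 <- (j - L) %% n
        g1 <- (s2 - (i + L)) %% n
        g2 <- (i - ((s2 + L))) %% n
        if (g1 + g2 == n - 2L * L && g1 >= 1L && g2 >= 1L && L > best)
          best <- L
      }
    }
  }
  best
}

# planted-IR circular genome: LSC + IRa + SSC + revcomp(IRa), with boundary
# bases fixed so no chance outward extension exists (detection is then exact)
planted_ir_sequence <- function(lsc_len, ir_len, ssc_len) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  lsc <- strsplit(random_dna(lsc_len), "")[[1L]]
  ira <- random_dna(ir_len)
  ssc <- strsplit(random_dna(ssc_len), "")[[1L]]
  # block left extension: last LSC base must not pair with first LSC base
  if (comp[[lsc[lsc_len]]] == lsc[1L])
    lsc[lsc_len] <- setdiff(c("A", "C", "G", "T"), comp[[lsc[1L]]])[1L]
  # block right extension: first SSC base must not pair with last SSC base
  if (comp[[ssc[1L]]] == ssc[ssc_len])
    ssc[1L] <- setdiff(c("A", "C", "G", "T"), comp[[ssc[ssc_len]]])[1L]
  out <- paste0(paste(lsc, collapse = ""), ira,
                paste(ssc, collapse = ""), revcomp(ira))
  attr(out, "planted_ir") <- ir_len
  out
}

# small synthetic annotated genome used across module tests
toy_genome <- function() {
  seq <- random_dna(1200)
  feats <- list(
    feature("geneA", "gene", data.frame(start = 100, end = 200, strand = "+")),
    feature("geneA", "CDS", data.frame(start = 100, end = 200, strand = "+")),
    feature("geneB", "gene", data.frame(start = c(300, 500),
                                        end = c(400, 620),
                                        strand = c("+", "+"))),
    feature("geneB", "CDS", data.frame(start = c(300, 500),
                                       end = c(400, 620),
                                       strand = c("+", "+"))),
    feature("trnX", "gene", data.frame(start = 700, end = 770, strand = "-")),
    feature("trnX", "tRNA", data.frame(start = 700, end = 770, strand = "-")))
  circular_genome("toy", seq, feats)
}
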