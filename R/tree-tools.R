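# Unrooted trees: neighbor-joining, nonparametric bootstrap, Robinson-Foulds.
# Trees are held as ape "phylo" objects (the field's standard container);
# the inference and comparison algorithms themselves are implemented here.

#' Neighbor-joining tree from a distance matrix
#'
#' Classic Saitou-Nei neighbor joining with deterministic tie-breaking:
#' when several pairs minimise the Q criterion, the pair whose cluster
#' names (the lexicographically smallest taxon in each cluster) come first
#' in lexicographic order is joined. Negative branch lengths are clamped to
#' zero. The returned tree is unrooted (trifurcation at the last join).
#'
#' @param d symmetric numeric matrix with zero diagonal and taxon dimnames
#'   (or a `dist` object), at least 4 taxa, no `NA`.
#' @return an unrooted `phylo` tree.
#' @export
nj_tree <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  if (nrow(d) < 4L)
    stop("neighbor joining needs at least 4 taxa (no internal edge otherwise)")
  if (is.null(rownames(d))) stop("distance matrix must have taxon names")
  if (any(is.na(d))) stop("distance matrix contains NA (saturated pairs?)")
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix is not symmetric")
  if (any(abs(diag(d)) > 1e-12)) stop("distance matrix diagonal is not zero")

  labels <- rownames(d)
  frag <- labels                       # newick fragment per active cluster
  rep_name <- labels                   # lexicographic representative
  D <- d
  while (length(frag) > 3L) {
    m <- nrow(D)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    # deterministic tie-break on (min name, max name) of each candidate pair
    keys <- apply(cand, 1L, function(ij) {
      nm <- sort(c(rep_name[ij[1L]], rep_name[ij[2L]]))
      paste(nm, collapse = "\r")
    })
    pick <- cand[order(keys)[1L], ]
    i <- pick[[1L]]; j <- pick[[2L]]
    vi <- 0.5 * D[i, j] + (r[i] - r[j]) / (2 * (m - 2))
    vj <- D[i, j] - vi
    vi <- max(vi, 0); vj <- max(vj, 0)
    newfrag <- sprintf("(%s:%.10g,%s:%.10g)", frag[i], vi, frag[j], vj)
    newrep <- min(rep_name[i], rep_name[j])
    dk <- 0.5 * (D[i, ] + D[j, ] - D[i, j])
    keep <- setdiff(seq_len(m), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dk[keep]),
                c(dk[keep], 0))
    frag <- c(frag[keep], newfrag)
    rep_name <- c(rep_name[keep], newrep)
    D <- D2
  }
  v1 <- max(0, (D[1, 2] + D[1, 3] - D[2, 3]) / 2)
  v2 <- max(0, (D[1, 2] + D[2, 3] - D[1, 3]) / 2)
  v3 <- max(0, (D[1, 3] + D[2, 3] - D[1, 2]) / 2)
  nwk <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
                 frag[1L], v1, frag[2L], v2, frag[3L], v3)
  ape::read.tree(text = nwk)
}

# nontrivial bipartition keys of an unrooted tree: for each internal edge,
# the tip set on one side, canonicalised to the side NOT containing the
# overall lexicographically smallest taxon, sorted and pasted
tree_bipartitions <- function(t) {
  tips <- t$tip.label
  n <- length(tips)
  ref <- sort(tips)[1L]
  nnode <- t$Nnode
  root <- n + 1L
  # tip sets per internal node by accumulating over edges in postorder
  sets <- vector("list", n + nnode)
  for (i in seq_len(n)) sets[[i]] <- tips[i]
  ord <- ape::reorder.phylo(t, "postorder")
  for (e in seq_len(nrow(ord$edge))) {
    par <- ord$edge[e, 1L]; child <- ord$edge[e, 2L]
    sets[[par]] <- c(sets[[par]], sets[[child]])
  }
  keys <- character(0)
  for (e in seq_len(nrow(t$edge))) {
    child <- t$edge[e, 2L]
    if (child <= n) next                    # trivial (single-tip) split
    side <- sets[[child]]
    if (length(side) < 2L || length(side) > n - 2L) next
    if (ref %in% side) side <- setdiff(tips, side)
    keys <- c(keys, paste(sort(side), collapse = "\r"))
  }
  unique(keys)
}

#' Robinson-Foulds distance between two unrooted trees
#'
#' The classic symmetric-difference count of nontrivial bipartitions (not
#' normalised): 0 iff the unrooted topologies agree, at most `2(n-3)` for
#' binary trees. Polytomies are allowed; their missing splits simply count
#' toward the other tree's side.
#'
#' @param t1,t2 `phylo` trees on identical taxon sets.
#' @return integer distance.
#' @export
rf_distance <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label))
    stop("trees have different taxon sets")
  b1 <- tree_bipartitions(t1)
  b2 <- tree_bipartitions(t2)
  length(setdiff(b1, b2)) + length(setdiff(b2, b1))
}

#' Nonparametric bootstrap support for the K80 + NJ tree of an alignment
#'
#' Infers the tree from the alignment's K80 distance matrix by
#' [nj_tree()], then resamples alignment columns with replacement
#' `replicates` times; each replicate's NJ tree is scored against the
#' internal edges of the original tree, and support is the percentage of
#' successful replicates containing each bipartition. Replicates whose
#' distance matrix has saturated (undefined) entries are dropped with a
#' message. Per-replicate random streams are derived from `seed` by
#' counter, so results are reproducible.
#'
#' @param a a [marker_alignment()] with at least 4 rows.
#' @param replicates number of bootstrap replicates (>= 10).
#' @param seed integer seed.
#' @return the original NJ `phylo` tree with supports in `node.label`
#'   (root label empty) and an attribute `n_replicates_used`.
#' @export
bootstrap_support <- function(a, replicates = 100L, seed = 1L) {
  stopifnot(replicates >= 10L)
  d0 <- k80_matrix(a)
  if (any(is.na(d0)))
    stop(sprintf("alignment '%s': saturated pairs in the original matrix",
                 a$name))
  tr <- nj_tree(d0)
  keys0 <- tree_bipartitions(tr)
  counts <- setNames(numeric(length(keys0)), keys0)
  m <- aln_int_matrix(a)
  w <- ncol(m)
  used <- 0L
  for (r in seq_len(replicates)) {
    set.seed((seed * 1000003L + r) %% 2147483647L)
    idx <- sample.int(w, w, replace = TRUE)
    mb <- m[, idx, drop = FALSE]
    db <- int_k80_matrix(mb)
    if (any(is.na(db))) next                       # saturated replicate
    kb <- tree_bipartitions(nj_tree(db))
    hit <- keys0 %in% kb
    counts[hit] <- counts[hit] + 1
    used <- used + 1L
  }
  if (used < replicates)
    message(sprintf("alignment '%s': %d/%d bootstrap replicates dropped (saturation)",
                    a$name, replicates - used, replicates))
  if (used == 0L)
    stop(sprintf("alignment '%s': all bootstrap replicates saturated", a$name))
  support <- 100 * counts / used
  tr <- attach_supports(tr, support)
  attr(tr, "n_replicates_used") <- used
  tr
}

# K80 matrix straight from an integer matrix (bootstrap inner loop)
int_k80_matrix <- function(m) {
  nt <- nrow(m)
  d <- matrix(0, nt, nt, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(nt - 1L)) {
    xi <- m[i, ]
    for (j in (i + 1L):nt) {
      yj <- m[j, ]
      ok <- !is.na(xi) & !is.na(yj)
      n <- sum(ok)
      if (n == 0L) { d[i, j] <- d[j, i] <- NA_real_; next }
      xs <- xi[ok]; ys <- yj[ok]
      diff <- xs != ys
      ti <- diff & (PURINE[xs] == PURINE[ys])
      d[i, j] <- d[j, i] <- k80_from_pq(sum(ti) / n, sum(diff & !ti) / n)
    }
  }
  d
}

# write per-bipartition supports into node labels of the matching tree
attach_supports <- function(tr, support) {
  n <- length(tr$tip.label)
  tips <- tr$tip.label
  ref <- sort(tips)[1L]
  sets <- vector("list", n + tr$Nnode)
  for (i in seq_len(n)) sets[[i]] <- tips[i]
  ord <- ape::reorder.phylo(tr, "postorder")
  for (e in seq_len(nrow(ord$edge)))
    sets[[ord$edge[e, 1L]]] <- c(sets[[ord$edge[e, 1L]]],
                                 sets[[ord$edge[e, 2L]]])
  labs <- rep("", tr$Nnode)
  for (e in seq_len(nrow(tr$edge))) {
    child <- tr$edge[e, 2L]
    if (child <= n) next
    side <- sets[[child]]
    if (length(side) < 2L || length(side) > n - 2L) next
    if (ref %in% side) side <- setdiff(tips, side)
    key <- paste(sort(side), collapse = "\r")
    if (key %in% names(support))
      labs[child - n] <- format(support[[key]], digits = 4)
  }
  tr$node.label <- labs
  tr
}

#' Mean bootstrap support of a tree
#'
#' Arithmetic mean over internal edges carrying a support value.
#'
#' @param t a `phylo` tree with numeric `node.label` supports.
#' @return mean support.
#' @export
mean_support <- function(t) {
  if (is.null(t$node.label))
    stop("tree has no support values")
  v <- suppressWarnings(as.numeric(t$node.label))
  v <- v[!is.na(v)]
  if (!length(v)) stop("tree has no internal edges with support")
  mean(v)
}

#' Read / write Newick trees
#'
#' Thin validated wrappers over ape: topology, branch lengths and
#' internal-node support labels round-trip losslessly.
#'
#' @param path file path (for [read_newick()]) or a `phylo` tree and path
#'   (for [write_newick()]).
#' @return [read_newick()] returns a `phylo`; [write_newick()] returns
#'   `path` invisibly.
#' @export
read_newick <- function(path) {
  tr <- tryCatch(suppressWarnings(ape::read.tree(path)),
                 error = function(e) stop(sprintf("cannot parse Newick in %s: %s",
                                                  path, conditionMessage(e))))
  if (is.null(tr)) stop(sprintf("cannot parse Newick in %s", path))
  tr
}

#' @rdname read_newick
#' @param t a `phylo` tree.
#' @export
write_newick <- function(t, path) {
  ape::write.tree(t, file = path)
  invisible(path)
}
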