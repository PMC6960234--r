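#' BIONJ tree from a distance matrix
#'
#' Builds an unrooted BIONJ neighbour-joining tree: agglomeration by the
#' neighbour-joining Q-criterion with BIONJ's variance-weighted averaging of
#' the merged rows (Gascuel's scheme, with the reduction weight `lambda`
#' estimated from the variance matrix and clamped to `[0, 1]`).  All
#' arithmetic is double precision, so additive matrices are reproduced to
#' machine accuracy.
#'
#' Determinism: taxa are put in canonical (sorted-label) order before
#' agglomeration and Q-criterion ties are broken by lexicographic taxon-pair
#' order, so the result is invariant to the input row order.  Negative
#' branch lengths arising at a join are clamped to zero with the deficit
#' moved to the sibling branch (the usual neighbour-joining convention);
#' the number of clamped edges is recorded in the `clamped_edges` attribute.
#'
#' @param D symmetric distance matrix with taxon dimnames ([build_matrix]).
#' @return An `ape::phylo` tree (unrooted, with branch lengths).
#' @export
bionj_tree <- function(D) {
  D <- as.matrix(unclass(D))
  if (nrow(D) < 3L) stop("need at least 3 taxa")
  labs <- rownames(D)
  if (is.null(labs) || anyDuplicated(labs))
    stop("duplicate or missing taxon labels")
  ord <- order(labs)
  D <- D[ord, ord]
  labs <- labs[ord]
  n <- length(labs)
  V <- D                                   # BIONJ: initial variances = distances
  # each active node carries its Newick subtree string
  nwk <- labs
  clamped <- 0L
  fmt <- function(x) sprintf("%.17g", x)
  while (n > 3L) {
    R <- rowSums(D)
    Q <- (n - 2) * D - outer(R, R, `+`)
    diag(Q) <- Inf
    # first minimal entry in column-major upper order == lexicographic pair
    # order because rows stay canonically ordered
    best <- which(Q == min(Q[upper.tri(Q)]) & upper.tri(Q),
                  arr.ind = TRUE)
    best <- best[order(best[, 1L], best[, 2L]), , drop = FALSE]
    i <- best[1L, 1L]
    j <- best[1L, 2L]
    d_ij <- D[i, j]
    b_i <- d_ij / 2 + (R[i] - R[j]) / (2 * (n - 2))
    b_j <- d_ij - b_i
    # emitted edges are clamped at zero (deficit to the sibling), but the
    # row reduction keeps the raw estimates so distances stay unbiased
    e_i <- b_i; e_j <- b_j
    if (e_i < 0) { e_j <- e_j + e_i; e_i <- 0; clamped <- clamped + 1L }
    if (e_j < 0) { e_i <- e_i + e_j; e_j <- 0; clamped <- clamped + 1L }
    e_i <- max(e_i, 0)
    e_j <- max(e_j, 0)
    keep <- setdiff(seq_len(n), c(i, j))
    lambda <- if (V[i, j] > 0) {
      0.5 + sum(V[j, keep] - V[i, keep]) / (2 * (n - 2) * V[i, j])
    } else 0.5
    lambda <- min(max(lambda, 0), 1)
    d_new <- lambda * (D[i, keep] - b_i) + (1 - lambda) * (D[j, keep] - b_j)
    v_new <- lambda * V[i, keep] + (1 - lambda) * V[j, keep] -
      lambda * (1 - lambda) * V[i, j]
    merged <- paste0("(", nwk[i], ":", fmt(e_i), ",", nwk[j], ":",
                     fmt(e_j), ")")
    D <- D[keep, keep, drop = FALSE]
    V <- V[keep, keep, drop = FALSE]
    D <- rbind(cbind(D, d_new), c(d_new, 0))
    V <- rbind(cbind(V, v_new), c(v_new, 0))
    nwk <- c(nwk[keep], merged)
    n <- n - 1L
  }
  # final three nodes join at the central (root) node of the unrooted tree
  b1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  b2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  b3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  neg <- c(b1, b2, b3) < 0
  clamped <- clamped + sum(neg)
  b <- pmax(c(b1, b2, b3), 0)
  tree_str <- paste0("(", nwk[1], ":", fmt(b[1]), ",", nwk[2], ":",
                     fmt(b[2]), ",", nwk[3], ":", fmt(b[3]), ");")
  tr <- ape::read.tree(text = tree_str)
  attr(tr, "clamped_edges") <- clamped
  tr
}

#' Nonparametric bootstrap support for a BIONJ tree
#'
#' Felsenstein-style bootstrap: alignment columns are resampled with
#' replacement, the distance matrix and BIONJ tree are rebuilt for each
#' replicate, and the support of each internal edge of the point-estimate
#' tree is the fraction of completed replicates whose tree contains the same
#' bipartition.  Replicates whose resampled alignment yields an incomparable
#' or saturated pair are discarded and counted; the support denominator is
#' the number of completed replicates.
#'
#' @param aln alignment as accepted by [build_matrix].
#' @param model distance model passed to [build_matrix].
#' @param n_reps number of bootstrap replicates (default 100).
#' @param seed integer seed; the replicate stream is fully determined by it.
#' @return A list: `tree` (the point-estimate tree with `node.label` set to
#'   support values), `support` (numeric per internal node; root node `NA`),
#'   `n_completed`, `n_discarded`.
#' @export
bootstrap_support <- function(aln, model = "JC69", n_reps = 100L, seed = 1L) {
  if (n_reps < 1L) stop("n_reps must be >= 1")
  aln <- as_alignment(aln)
  chars <- do.call(rbind, strsplit(aln, "", fixed = TRUE))
  rownames(chars) <- names(aln)
  ref <- bionj_tree(build_matrix(aln, model = model))
  boot_trees <- list()
  n_discarded <- 0L
  with_seed(seed, {
    for (r in seq_len(n_reps)) {
      idx <- sample.int(ncol(chars), replace = TRUE)
      rep_aln <- apply(chars[, idx, drop = FALSE], 1L, paste, collapse = "")
      tr <- tryCatch(bionj_tree(build_matrix(rep_aln, model = model)),
                     error = function(e) NULL)
      if (is.null(tr)) n_discarded <- n_discarded + 1L
      else boot_trees[[length(boot_trees) + 1L]] <- tr
    }
  })
  n_done <- length(boot_trees)
  if (n_done == 0L) stop("all bootstrap replicates failed")
  class(boot_trees) <- "multiPhylo"
  counts <- ape::prop.clades(ref, boot_trees, rooted = FALSE)
  support <- counts / n_done
  # the root "bipartition" of an unrooted tree is trivial; prop.clades may
  # return NA for clades absent from every replicate
  support[is.na(counts)] <- 0
  support[1L] <- NA_real_
  ref$node.label <- formatC(support, format = "f", digits = 2)
  ref$node.label[is.na(support)] <- ""
  list(tree = ref, support = support,
       n_completed = n_done, n_discarded = n_discarded)
}
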