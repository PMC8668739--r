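# Pairwise compositional turnover between occupied cells, UPGMA
# bioregionalization and PCoA colour-composition maps.

#' Pairwise Simpson dissimilarity between cells
#'
#' Turnover-only taxonomic dissimilarity: with `a` species shared and
#' `b`, `c` unique to each cell, `beta = min(b, c) / (min(b, c) + a)`.
#' Nested assemblages score 0; disjoint assemblages score 1. Empty cells
#' must be removed first (see [drop_empty_cells()]).
#'
#' @param pam A [pa_matrix()] with no empty cells.
#' @return Symmetric matrix in `[0,1]` with zero diagonal, labelled by cell
#'   id, with attribute `metric = "simpson"`.
#' @export
simpson_dissimilarity <- function(pam) {
  mat <- pam$mat
  stopifnot(all(rowSums(mat) >= 1))
  a <- mat %*% t(mat)
  td <- rowSums(mat)
  b <- outer(td, rep(1, length(td))) - a      # unique to row cell
  cc <- t(b)
  minbc <- pmin(b, cc)
  d <- minbc / (minbc + a)
  diag(d) <- 0
  dimnames(d) <- list(rownames(mat), rownames(mat))
  attr(d, "metric") <- "simpson"
  d
}

#' Pairwise phylogenetic turnover (PhyloSor, turnover component)
#'
#' Branch-length analogue of Simpson dissimilarity: with `A` the summed
#' length of branches shared by the two cells' spanning paths and `B`, `C`
#' the lengths unique to each, `beta = min(B, C) / (min(B, C) + A)`. On a
#' star tree with equal branch lengths this reduces exactly to
#' [simpson_dissimilarity()].
#'
#' @param tree Rooted `phylo` with branch lengths.
#' @param pam A [pa_matrix()] with no empty cells.
#' @return Symmetric matrix in `[0,1]`, attribute `metric = "phylosor_turn"`.
#' @export
phylosor_turnover <- function(tree, pam) {
  stopifnot(all(rowSums(pam$mat) >= 1))
  ctx <- phylo_context(tree, pam)
  cb <- cell_branch_incidence(pam$mat, ctx$tip_inc) * 1
  shared <- cb %*% (ctx$len * t(cb))
  tot <- as.vector(cb %*% ctx$len)
  b <- outer(tot, rep(1, length(tot))) - shared
  cc <- t(b)
  minbc <- pmin(b, cc)
  d <- minbc / (minbc + shared)
  diag(d) <- 0
  dimnames(d) <- list(rownames(pam$mat), rownames(pam$mat))
  attr(d, "metric") <- "phylosor_turn"
  d
}

#' UPGMA bioregion clustering
#'
#' Average-linkage agglomeration of the cell dissimilarity matrix, cut at
#' the height giving exactly `k` clusters.
#'
#' @param dissim Symmetric dissimilarity matrix (cells x cells).
#' @param k Number of bioregions (default 4).
#' @return List with `cluster` (named integer vector, labels 1..k in order
#'   of first appearance), `dendrogram` (the `hclust` object) and `k`.
#' @export
upgma_cluster <- function(dissim, k = 4) {
  n <- nrow(dissim)
  if (k > n) stop("k = ", k, " exceeds the number of cells (", n, ")")
  hc <- stats::hclust(stats::as.dist(dissim), method = "average")
  cl <- stats::cutree(hc, k = k)
  # relabel clusters by order of first appearance for determinism
  cl <- stats::setNames(match(cl, unique(cl)), names(cl))
  list(cluster = cl, dendrogram = hc, k = k)
}

#' Map a dissimilarity matrix to RGB colours by principal coordinates
#'
#' Classical scaling (PCoA) of the dissimilarity matrix; the first three
#' positive-eigenvalue axes are each rescaled to `[0, 255]` and used as
#' red, green and blue channels, so cells with similar composition receive
#' similar colours. If fewer than three positive axes exist the remaining
#' channels are set to 128 with a warning.
#'
#' @param dissim Symmetric dissimilarity matrix (>= 4 cells).
#' @return Data frame: `cell`, `red`, `green`, `blue` (0-255), plus the raw
#'   axis scores as attribute `scores`.
#' @export
pcoa_rgb <- function(dissim) {
  n <- nrow(dissim)
  stopifnot(n >= 4)
  sc <- suppressWarnings(
    stats::cmdscale(stats::as.dist(dissim), k = min(3, n - 1), eig = TRUE))
  pos <- sc$eig[seq_len(ncol(sc$points))] > max(sc$eig) * 1e-8
  pts <- sc$points[, pos, drop = FALSE]
  n_ax <- ncol(pts)
  if (n_ax < 3)
    warning("only ", n_ax, " positive PCoA axes; remaining channels set to 128")
  chan <- matrix(128, n, 3)
  for (j in seq_len(min(3, n_ax))) {
    v <- pts[, j]
    rng <- range(v)
    chan[, j] <- if (diff(rng) == 0) 128 else
      round(255 * (v - rng[1]) / diff(rng))
  }
  out <- data.frame(cell = rownames(dissim), red = chan[, 1],
                    green = chan[, 2], blue = chan[, 3],
                    stringsAsFactors = FALSE)
  attr(out, "scores") <- pts
  out
}
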