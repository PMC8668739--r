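# Per-cell diversity and endemism indices on a presence-absence matrix and
# a rooted tree: TD, WE, Faith PD and Rosauer PE (both scaled by total tree
# length), their equal-branch-tree relative versions RPD/RPE, and
# margin-preserving curveball null percentiles.

#' Tip-by-branch incidence of a rooted tree
#'
#' @param tree A rooted `phylo` object with branch lengths.
#' @return Binary matrix, tips x edges: 1 where the edge lies on the path
#'   from the tip to the root.
#' @export
branch_incidence <- function(tree) {
  n_tip <- length(tree$tip.label)
  parent <- tree$edge[, 1]; child <- tree$edge[, 2]
  # edge leading to each node (by child node id)
  edge_of <- integer(max(tree$edge))
  edge_of[child] <- seq_len(nrow(tree$edge))
  root <- n_tip + 1L
  inc <- matrix(0L, n_tip, nrow(tree$edge),
                dimnames = list(tree$tip.label, NULL))
  par_of <- integer(max(tree$edge))
  par_of[child] <- parent
  for (i in seq_len(n_tip)) {
    node <- i
    while (node != root) {
      inc[i, edge_of[node]] <- 1L
      node <- par_of[node]
    }
  }
  inc
}

#' Branches on the minimum spanning path of a tip set
#'
#' Union of the branches on the root-ward paths of each tip in the set.
#'
#' @param tree A rooted `phylo` object.
#' @param tip_set Character vector of tip labels (nonempty).
#' @return Integer vector of edge indices into `tree$edge`.
#' @export
spanning_path <- function(tree, tip_set) {
  stopifnot(length(tip_set) >= 1)
  unknown <- setdiff(tip_set, tree$tip.label)
  if (length(unknown))
    stop("unknown tip label(s): ", paste(unknown, collapse = ", "))
  inc <- branch_incidence(tree)
  which(colSums(inc[tip_set, , drop = FALSE]) > 0)
}

# tree/PAM consistency: PAM species must all be tips; tips absent from the
# PAM are pruned (logged via message).
align_tree_pam <- function(tree, pam) {
  spp <- colnames(pam$mat)
  missing <- setdiff(spp, tree$tip.label)
  if (length(missing))
    stop("species not on the tree: ", paste(missing, collapse = ", "))
  extra <- setdiff(tree$tip.label, spp)
  if (length(extra)) {
    message("pruning ", length(extra), " tip(s) absent from the matrix: ",
            paste(extra, collapse = ", "))
    tree <- ape::drop.tip(tree, extra)
  }
  tree
}

#' Taxonomic diversity per cell
#'
#' @param pam A [pa_matrix()].
#' @return Named numeric vector of species counts (row sums).
#' @export
taxonomic_diversity <- function(pam) rowSums(pam$mat)

#' Weighted endemism per cell
#'
#' Sum over the species present in a cell of the inverse of their range
#' size, so a single-cell endemic contributes 1. Summed over all cells this
#' equals the number of species exactly.
#'
#' @param pam A [pa_matrix()].
#' @return Named numeric vector.
#' @export
weighted_endemism <- function(pam) {
  r <- range_sizes(pam)
  stopifnot(all(r >= 1))
  as.vector(pam$mat %*% (1 / r))
}

# cells x branches incidence and common pieces, computed once and shared by
# pd/pe/rpd/rpe and the null loop.
phylo_context <- function(tree, pam) {
  tree <- align_tree_pam(tree, pam)
  inc <- branch_incidence(tree)[colnames(pam$mat), , drop = FALSE]
  list(tree = tree, tip_inc = inc, len = tree$edge.length,
       l_tot = sum(tree$edge.length))
}

cell_branch_incidence <- function(mat, tip_inc) {
  (mat %*% tip_inc) > 0
}

pd_from_ctx <- function(mat, ctx, len = ctx$len, l_tot = ctx$l_tot) {
  cb <- cell_branch_incidence(mat, ctx$tip_inc)
  v <- as.vector(cb %*% len) / l_tot
  v[rowSums(mat) == 0] <- NA_real_
  v
}

pe_from_ctx <- function(mat, ctx, len = ctx$len, l_tot = ctx$l_tot) {
  cb <- cell_branch_incidence(mat, ctx$tip_inc)
  r_b <- colSums(cb)                       # branch range on this matrix
  w <- ifelse(r_b > 0, len / r_b, 0)
  v <- as.vector(cb %*% w) / l_tot
  v[rowSums(mat) == 0] <- NA_real_
  v
}

#' Faith phylogenetic diversity per cell, scaled by total tree length
#'
#' Sum of branch lengths on the minimum spanning path linking the cell's
#' species to the root, divided by the total tree length (range 0-1).
#' Empty cells are `NA`.
#'
#' @param tree Rooted `phylo` with branch lengths.
#' @param pam A [pa_matrix()].
#' @return Named numeric vector.
#' @export
phylo_diversity <- function(tree, pam) {
  ctx <- phylo_context(tree, pam)
  stats::setNames(pd_from_ctx(pam$mat, ctx), rownames(pam$mat))
}

#' Rosauer phylogenetic endemism per cell, scaled by total tree length
#'
#' As [phylo_diversity()], but each branch on the spanning path is first
#' divided by its range size (the number of cells occupied by at least one
#' of its descendant tips, on this same matrix). Summed over cells this
#' equals the PD of the full species pool.
#'
#' @inheritParams phylo_diversity
#' @return Named numeric vector.
#' @export
phylo_endemism <- function(tree, pam) {
  ctx <- phylo_context(tree, pam)
  stats::setNames(pe_from_ctx(pam$mat, ctx), rownames(pam$mat))
}

#' Replace all branch lengths by 1
#'
#' The comparison tree for relative PD/PE: identical topology, equal branch
#' lengths, scaled by its own total length (so any constant length choice
#' gives identical ratios).
#'
#' @param tree A `phylo` object.
#' @return The tree with unit branch lengths.
#' @export
equalize_branches <- function(tree) {
  tree$edge.length <- rep(1, nrow(tree$edge))
  tree
}

#' Relative phylogenetic diversity per cell
#'
#' Ratio of scaled PD on the actual tree over scaled PD on the same
#' topology with equal branch lengths; values above 1 mark assemblages of
#' long-branch (old) lineages.
#'
#' @inheritParams phylo_diversity
#' @return Named numeric vector (`NA` for empty cells).
#' @export
rel_phylo_diversity <- function(tree, pam) {
  phylo_diversity(tree, pam) / phylo_diversity(equalize_branches(tree), pam)
}

#' Relative phylogenetic endemism per cell
#'
#' @inheritParams phylo_diversity
#' @return Named numeric vector (`NA` for empty cells).
#' @export
rel_phylo_endemism <- function(tree, pam) {
  phylo_endemism(tree, pam) / phylo_endemism(equalize_branches(tree), pam)
}

# One curveball trade: pick two cells (rows), exchange a random subset of
# the species unique to each, preserving both margins.
curveball_step <- function(mat) {
  rows <- sample.int(nrow(mat), 2L)
  a <- mat[rows[1], ]; b <- mat[rows[2], ]
  only_a <- which(a == 1 & b == 0)
  only_b <- which(a == 0 & b == 1)
  na <- length(only_a); nb <- length(only_b)
  if (na == 0 || nb == 0) return(mat)
  pool <- c(only_a, only_b)
  pick <- sample(pool, na)
  a[pool] <- 0; b[pool] <- 0
  a[pick] <- 1; b[setdiff(pool, pick)] <- 1
  mat[rows[1], ] <- a; mat[rows[2], ] <- b
  mat
}

#' Margin-preserving randomization of a presence-absence matrix
#'
#' Curveball (trial-swap) randomization: every replicate preserves each
#' cell's species count and each species' range size exactly, randomizing
#' which species identities fall in which cell. Burn-in is `5 x fill` trades
#' and replicates are separated by `fill` trades, where fill is the number
#' of presences.
#'
#' @param pam A [pa_matrix()] with at least 2 cells and 2 species.
#' @param n_iter Number of replicates.
#' @param seed Integer seed.
#' @return List of binary matrices (same dimnames as `pam$mat`).
#' @export
randomize_pam <- function(pam, n_iter = 999, seed = 1L) {
  mat <- pam$mat
  stopifnot(nrow(mat) >= 2, ncol(mat) >= 2)
  set.seed(seed)
  fill <- sum(mat)
  # degenerate matrices (no pair of rows with exchangeable species) admit
  # only themselves
  swappable <- function(m) {
    for (i in seq_len(nrow(m) - 1)) for (j in (i + 1):nrow(m)) {
      if (any(m[i, ] == 1 & m[j, ] == 0) && any(m[i, ] == 0 & m[j, ] == 1))
        return(TRUE)
    }
    FALSE
  }
  if (!swappable(mat)) {
    warning("matrix admits no margin-preserving swap; replicates are identical")
    return(replicate(n_iter, mat, simplify = FALSE))
  }
  for (i in seq_len(5L * fill)) mat <- curveball_step(mat)
  out <- vector("list", n_iter)
  for (r in seq_len(n_iter)) {
    for (i in seq_len(fill)) mat <- curveball_step(mat)
    out[[r]] <- mat
  }
  out
}

#' Null-model percentile ranks of per-cell indices
#'
#' Percentile rank of the observed index within the null distribution from
#' a margin-preserving ensemble, with the midrank tie convention:
#' `100 * (#\{null < obs\} + 0.5 #\{null = obs\}) / n_iter`. Cells above
#' 97.5 / below 2.5 are flagged significantly high/low (two-tailed 5%).
#'
#' @param tree Rooted `phylo` with branch lengths.
#' @param pam A [pa_matrix()].
#' @param ensemble List of null matrices from [randomize_pam()].
#' @param indices Character subset of `c("pd", "pe", "rpd", "rpe")`.
#' @return List with `percentile` (cells x indices matrix) and `signif`
#'   (character matrix: `"high"`, `"low"`, `""`).
#' @export
null_percentiles <- function(tree, pam, ensemble,
                             indices = c("pd", "pe", "rpd", "rpe")) {
  indices <- match.arg(indices, several.ok = TRUE)
  ctx <- phylo_context(tree, pam)
  eq_len <- rep(1, length(ctx$len))
  eq_tot <- sum(eq_len)
  compute <- function(mat) {
    out <- list()
    if (any(c("pd", "rpd") %in% indices)) pd <- pd_from_ctx(mat, ctx)
    if (any(c("pe", "rpe") %in% indices)) pe <- pe_from_ctx(mat, ctx)
    if ("pd" %in% indices) out$pd <- pd
    if ("pe" %in% indices) out$pe <- pe
    if ("rpd" %in% indices)
      out$rpd <- pd / pd_from_ctx(mat, ctx, eq_len, eq_tot)
    if ("rpe" %in% indices)
      out$rpe <- pe / pe_from_ctx(mat, ctx, eq_len, eq_tot)
    do.call(cbind, out)
  }
  obs <- compute(pam$mat)
  n_iter <- length(ensemble)
  lower <- obs * 0; equal <- obs * 0
  for (m in ensemble) {
    nul <- compute(m)
    lower <- lower + (nul < obs)
    equal <- equal + (nul == obs)
  }
  pct <- 100 * (lower + 0.5 * equal) / n_iter
  sig <- matrix("", nrow(pct), ncol(pct), dimnames = dimnames(pct))
  sig[pct > 97.5] <- "high"; sig[pct < 2.5] <- "low"
  sig[is.na(pct)] <- NA
  rownames(pct) <- rownames(pam$mat)
  list(percentile = pct, signif = sig)
}

#' Per-cell index table with null percentiles
#'
#' Computes TD, WE, PD, PE, RPD and RPE for every cell together with
#' curveball null percentile ranks for the phylogenetic indices.
#'
#' @param tree Rooted `phylo` with branch lengths.
#' @param pam A [pa_matrix()].
#' @param n_null Number of null replicates (0 to skip nulls).
#' @param seed Integer seed for the randomization.
#' @return Data frame: `cell`, `lon`, `lat`, `td`, `we`, `pd`, `pe`, `rpd`,
#'   `rpe` and `*_pctl` columns.
#' @export
cell_indices <- function(tree, pam, n_null = 999, seed = 1L) {
  tab <- data.frame(cell = pam$coords$cell, lon = pam$coords$lon,
                    lat = pam$coords$lat,
                    td = taxonomic_diversity(pam),
                    we = weighted_endemism(pam),
                    pd = phylo_diversity(tree, pam),
                    pe = phylo_endemism(tree, pam),
                    rpd = rel_phylo_diversity(tree, pam),
                    rpe = rel_phylo_endemism(tree, pam),
                    row.names = NULL, stringsAsFactors = FALSE)
  if (n_null > 0) {
    ens <- randomize_pam(pam, n_iter = n_null, seed = seed)
    np <- null_percentiles(tree, pam, ens)
    for (ix in colnames(np$percentile))
      tab[[paste0(ix, "_pctl")]] <- np$percentile[, ix]
  }
  tab
}
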