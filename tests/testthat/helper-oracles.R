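# Shared fixtures and independent oracles. The oracles deliberately take a
# different route than the package implementation (edge walking instead of
# incidence matrices, all-pairs enumeration instead of ranks, grid search
# instead of proximal gradient).

micro_tree <- function() ape::read.tree(text = "((A:1,B:1):1,C:2);")

micro_pam <- function() {
  g <- grid_spec(0, 2, 1, 2, 1)
  mat <- matrix(c(1, 0, 1, 0, 0, 1), 2, 3,
                dimnames = list(NULL, c("A", "B", "C")))
  pa_matrix(mat, data.frame(cell = c("c1", "c2"), row = 1:2, col = 1,
                            lon = 0.5, lat = c(1.5, 0.5)), g)
}

# random PAM with no empty cell and no empty species column
random_pam <- function(n_cells, n_species, seed, fill = 0.35) {
  set.seed(seed)
  repeat {
    mat <- matrix(rbinom(n_cells * n_species, 1, fill), n_cells, n_species)
    if (all(rowSums(mat) > 0) && all(colSums(mat) > 0)) break
  }
  colnames(mat) <- sprintf("sp%02d", seq_len(n_species))
  g <- grid_spec(0, n_cells, 1, n_cells, 1)
  pa_matrix(mat, data.frame(cell = sprintf("c%02d", seq_len(n_cells)),
                            row = seq_len(n_cells), col = 1, lon = 0.5,
                            lat = seq_len(n_cells) - 0.5), g)
}

# spanning-path PD by explicit root-ward edge walking per tip
oracle_pd <- function(tree, tips) {
  root <- length(tree$tip.label) + 1L
  edges <- integer(0)
  for (tp in tips) {
    node <- which(tree$tip.label == tp)
    while (node != root) {
      e <- which(tree$edge[, 2] == node)
      edges <- union(edges, e)
      node <- tree$edge[e, 1]
    }
  }
  sum(tree$edge.length[edges]) / sum(tree$edge.length)
}

# PE via per-branch range counts computed by brute force over cells
oracle_pe <- function(tree, pam) {
  root <- length(tree$tip.label) + 1L
  path_edges <- function(tips) {
    edges <- integer(0)
    for (tp in tips) {
      node <- which(tree$tip.label == tp)
      while (node != root) {
        e <- which(tree$edge[, 2] == node)
        edges <- union(edges, e)
        node <- tree$edge[e, 1]
      }
    }
    edges
  }
  cell_tips <- apply(pam$mat, 1, function(r) colnames(pam$mat)[r == 1],
                     simplify = FALSE)
  cell_edges <- lapply(cell_tips, function(tp)
    if (length(tp)) path_edges(tp) else integer(0))
  r_b <- vapply(seq_len(nrow(tree$edge)), function(e)
    sum(vapply(cell_edges, function(es) e %in% es, TRUE)), 0)
  vapply(cell_edges, function(es)
    if (!length(es)) NA_real_ else
      sum(tree$edge.length[es] / r_b[es]) / sum(tree$edge.length), 0)
}

oracle_auc <- function(pos, neg) {
  s <- 0
  for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

# penalized presence-background log-likelihood for a single coefficient
oracle_pb_objective <- function(beta, xp, xb, lambda) {
  mean(xp * beta) - log(mean(exp(xb * beta))) - lambda * abs(beta)
}

rand_index <- function(a, b) {
  n <- length(a)
  s <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    s <- s + as.numeric((a[i] == a[j]) == (b[i] == b[j]))
  unname(s / choose(n, 2))
}

tiny_grid <- function(nr = 4, nc = 3, cs = 1) grid_spec(0, nr * cs, cs, nr, nc)
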