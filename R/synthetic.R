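# Synthetic worlds: landscapes, phylogenies, niches and biased occurrence
# samples with known truth, so the whole pipeline can be exercised without
# any external data. All randomness flows from one integer seed through
# child_seeds(), one child stream per species/layer/stage.

child_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Simulate an ultrametric birth-death phylogeny
#'
#' Constant-rate birth-death tree conditioned on the number of extant tips,
#' with tips relabelled `sp01..spNN`. Depths are in the same time units as
#' the rates (Ma for per-Ma rates).
#'
#' @param n_taxa Number of extant tips (>= 2).
#' @param birth_rate,death_rate Per-lineage per-Ma rates; `birth_rate >
#'   death_rate >= 0`.
#' @param seed Integer seed.
#' @return A rooted ultrametric `phylo` object with `n_taxa` tips.
#' @export
simulate_tree <- function(n_taxa, birth_rate = 0.08, death_rate = 0.02,
                          seed = 1L) {
  stopifnot(n_taxa >= 2, birth_rate > death_rate, death_rate >= 0)
  set.seed(seed)
  tree <- NULL
  for (i in 1:100) {
    tree <- tryCatch(ape::rphylo(n_taxa, birth_rate, death_rate),
                     error = function(e) NULL)
    if (!is.null(tree)) break
  }
  if (is.null(tree))
    stop(sprintf("birth-death simulation failed for rates (%g, %g)",
                 birth_rate, death_rate))
  tree$tip.label <- sprintf("sp%02d", seq_len(n_taxa))
  tree
}

# Separable Gaussian blur with circular boundary (keeps the field
# stationary); range = kernel sd in cells.
gaussian_blur <- function(mat, range) {
  if (range <= 0) return(mat)
  half <- max(1L, ceiling(3 * range))
  k <- stats::dnorm(seq(-half, half), sd = range)
  k <- k / sum(k)
  blur1 <- function(m) {
    n <- nrow(m)
    idx <- outer(seq_len(n), seq(-half, half), function(i, o) ((i + o - 1) %% n) + 1)
    out <- matrix(0, n, ncol(m))
    for (j in seq_along(k)) out <- out + k[j] * m[idx[, j], , drop = FALSE]
    out
  }
  t(blur1(t(blur1(mat))))
}

standardize <- function(m) {
  s <- stats::sd(as.vector(m))
  if (s == 0) return(m - mean(m))
  (m - mean(m)) / s
}

#' Simulate an environmental landscape
#'
#' Each layer is a deterministic spatial gradient (north-south for odd
#' layers, an elevation-like central ridge for even layers) mixed with a
#' Gaussian random field of the stated autocorrelation range, standardized
#' to mean 0, sd 1. The north-south gradient increases southwards.
#'
#' @param n_rows,n_cols Grid dimensions (>= 10).
#' @param n_env Number of layers.
#' @param autocorr_range Gaussian-field correlation range in cells; 0 gives
#'   iid noise.
#' @param seed Integer seed.
#' @param gradient_weight Mixing weight in `[0,1]` of the deterministic
#'   gradient (may be a vector, one per layer).
#' @param grid Optional [grid_spec()]; default places the grid on a Western
#'   Ghats-like extent where `n_rows` fine cells at 0.2075 deg span the
#'   mountain chain's latitudes.
#' @return An [env_stack()].
#' @export
simulate_landscape <- function(n_rows, n_cols, n_env = 3, autocorr_range = 4,
                               seed = 1L, gradient_weight = 0.6,
                               grid = NULL) {
  stopifnot(n_rows >= 10, n_cols >= 10, n_env >= 1)
  if (is.null(grid)) grid <- grid_spec(74, 21, 0.2075, n_rows, n_cols)
  gradient_weight <- rep_len(gradient_weight, n_env)
  seeds <- child_seeds(seed, n_env)
  ns <- matrix(seq(-1, 1, length.out = n_rows), n_rows, n_cols)  # south high
  ridge <- standardize(matrix(
    exp(-((col(ns) - (n_cols + 1) / 2)^2) / (2 * (n_cols / 4)^2)),
    n_rows, n_cols))
  layers <- vector("list", n_env)
  for (j in seq_len(n_env)) {
    set.seed(seeds[j])
    noise <- standardize(gaussian_blur(matrix(stats::rnorm(n_rows * n_cols),
                                              n_rows, n_cols),
                                       autocorr_range))
    g <- if (j %% 2 == 1) standardize(ns) else ridge
    w <- gradient_weight[j]
    layers[[j]] <- standardize(w * g + (1 - w) * noise)
  }
  names(layers) <- paste0("env", seq_len(n_env))
  env_stack(layers, grid)
}

# Gaussian suitability surface around a vector of per-layer optima.
# niche_sd is recycled per layer; very large sds make a layer irrelevant.
suitability_from_optima <- function(env, opt, niche_sd) {
  niche_sd <- rep_len(niche_sd, length(env$layers))
  d2 <- 0
  for (j in seq_along(env$layers))
    d2 <- d2 + (env$layers[[j]] - opt[j])^2 / (2 * niche_sd[j]^2)
  exp(-d2)
}

#' Evolve species niches on a phylogeny
#'
#' Each species' niche optimum (one per environmental layer) is a convex
#' mix of a Brownian-motion trait evolved on the tree (standardized to unit
#' variance across tips) and an iid standard-normal draw; `phylo_signal = 1`
#' gives pure Brownian optima (close relatives share similar niches),
#' `phylo_signal = 0` gives independent optima. Suitability of a cell is
#' `exp(-sum_j (env_j - opt_j)^2 / (2 niche_sd_j^2))`, hence in (0, 1].
#'
#' @param tree A `phylo` object.
#' @param env An [env_stack()].
#' @param niche_sd Niche breadth in environment units (scalar or one per
#'   layer).
#' @param phylo_signal Mixing weight in `[0,1]`.
#' @param seed Integer seed.
#' @return List with `suitability` (env_stack of per-species rasters, layers
#'   named by tip) and `optima` (tips x layers matrix).
#' @export
simulate_niches <- function(tree, env, niche_sd = 1, phylo_signal = 0.8,
                            seed = 1L) {
  stopifnot(phylo_signal >= 0, phylo_signal <= 1)
  n_env <- length(env$layers)
  tips <- tree$tip.label
  seeds <- child_seeds(seed, n_env)
  opt <- matrix(0, length(tips), n_env, dimnames = list(tips, names(env$layers)))
  for (j in seq_len(n_env)) {
    set.seed(seeds[j])
    bm <- ape::rTraitCont(tree, model = "BM", sigma = 1)
    bm <- if (stats::sd(bm) > 0) (bm - mean(bm)) / stats::sd(bm) else bm * 0
    iid <- stats::rnorm(length(tips))
    opt[, j] <- phylo_signal * bm[tips] + (1 - phylo_signal) * iid
  }
  suit <- lapply(tips, function(sp)
    suitability_from_optima(env, opt[sp, ], niche_sd))
  names(suit) <- tips
  list(suitability = env_stack(suit, env$grid), optima = opt)
}

#' Sample spatially biased occurrence points
#'
#' For each species, occupied fine cells are drawn without replacement with
#' probability proportional to `true_suitability x bias`, and one point is
#' placed uniformly at random inside each drawn cell (points are GPS-like
#' coordinates, not cell indices).
#'
#' @param true_suitability [env_stack()] with one layer per species.
#' @param n_per_species Either a single count, a named/unnamed vector (one
#'   per species), or a length-2 range from which per-species counts are
#'   drawn log-uniformly (the default `c(3, 42)` emulates sparse field
#'   sampling).
#' @param bias_truth Nonnegative bias raster (matrix) on the same grid; `NULL`
#'   for unbiased sampling.
#' @param seed Integer seed.
#' @return Data frame with columns `species`, `lon`, `lat`.
#' @export
sample_occurrences <- function(true_suitability, n_per_species = c(3, 42),
                               bias_truth = NULL, seed = 1L) {
  grid <- true_suitability$grid
  spp <- names(true_suitability$layers)
  if (is.null(bias_truth)) bias_truth <- matrix(1, grid$nrow, grid$ncol)
  seeds <- child_seeds(seed, length(spp) + 1L)
  n <- if (length(n_per_species) == 2 && is.null(names(n_per_species)) &&
           n_per_species[2] > n_per_species[1]) {
    set.seed(seeds[length(spp) + 1L])
    round(exp(stats::runif(length(spp), log(n_per_species[1]),
                           log(n_per_species[2]))))
  } else rep_len(n_per_species, length(spp))
  out <- vector("list", length(spp))
  for (i in seq_along(spp)) {
    set.seed(seeds[i])
    w <- as.vector(true_suitability$layers[[spp[i]]] * bias_truth)
    w[is.na(w)] <- 0
    avail <- sum(w > 0)
    if (avail < n[i])
      stop(sprintf("species %s: %d occurrences requested but only %d cells have positive weight",
                   spp[i], n[i], avail))
    cells <- sample.int(length(w), n[i], replace = FALSE, prob = w)
    row <- (cells - 1L) %% grid$nrow + 1L
    col <- (cells - 1L) %/% grid$nrow + 1L
    lon <- grid$xmin + (col - 1 + stats::runif(n[i])) * grid$cellsize
    lat <- grid$ymax - (row - 1 + stats::runif(n[i])) * grid$cellsize
    out[[i]] <- data.frame(species = spp[i], lon = lon, lat = lat,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# Ultrametric caterpillar clade: tips[1] diverges at split_times[1], etc.
# Returns a newick fragment whose root is at depth split_times[1].
caterpillar_newick <- function(tips, split_times) {
  k <- length(tips)
  stopifnot(length(split_times) == k - 1,
            all(diff(split_times) < 0) || k == 2)
  if (k == 1) return(sprintf("%s", tips))
  if (k == 2)
    return(sprintf("(%s:%.10f,%s:%.10f)", tips[1], split_times[1],
                   tips[2], split_times[1]))
  inner <- caterpillar_newick(tips[-1], split_times[-1])
  sprintf("(%s:%.10f,%s:%.10f)", tips[1], split_times[1], inner,
          split_times[1] - split_times[2])
}

refuge_tree <- function() {
  # Old clade: six long-branch southern endemics, crown 85 Ma.
  old <- caterpillar_newick(sprintf("sp%02d", 1:6), c(85, 68, 52, 40, 30))
  # Young clade: 13 species radiating in the last 12 Ma.
  young <- caterpillar_newick(sprintf("sp%02d", 7:19),
                              seq(12, 2.4, length.out = 12))
  txt <- sprintf("(%s:%.10f,%s:%.10f);", old, 100 - 85, young, 100 - 12)
  ape::read.tree(text = txt)
}

#' Build a synthetic world fixture
#'
#' Presets:
#' \describe{
#'   \item{southern_refuge}{Two replacing faunas on a latitudinal gradient:
#'     an old long-branch clade of narrow-ranged southern endemics plus
#'     young southern species versus a young northern fauna, with two
#'     widespread species; emulates a southern-refuge diversity gradient.}
#'   \item{uniform}{No spatial structure: every species suitable everywhere
#'     (all-ones true occupancy), unbiased sampling.}
#'   \item{two_blocks}{Disjoint northern and southern assemblages sharing
#'     no species, for turnover tests.}
#' }
#'
#' @param preset One of `"southern_refuge"`, `"uniform"`, `"two_blocks"`.
#' @param n_taxa Number of species (fixed at 19 for `southern_refuge`).
#' @param n_rows,n_cols Fine-grid dimensions.
#' @param factor Fine-to-coarse aggregation factor.
#' @param seed Integer seed.
#' @param n_per_species Occurrence counts, as in [sample_occurrences()].
#' @return A `synthetic_world` list: `env`, `tree`, `true_suitability`,
#'   `true_occupancy` (a [pa_matrix()]), `occurrences`, `bias_truth`,
#'   `grid`, `coarse_grid`, `factor`, `seed`, and `truth` (per-cell block
#'   labels and per-species fauna labels where the preset defines them).
#' @export
make_fixture <- function(preset = c("southern_refuge", "uniform", "two_blocks"),
                         n_taxa = 19, n_rows = 40, n_cols = 20, factor = 4,
                         seed = 42L, n_per_species = c(3, 42)) {
  preset <- match.arg(preset)
  seeds <- child_seeds(seed, 4)
  if (preset == "southern_refuge" && n_taxa != 19)
    stop("the southern_refuge preset is defined for 19 species")

  env <- simulate_landscape(n_rows, n_cols, n_env = 3, autocorr_range = 4,
                            seed = seeds[1],
                            gradient_weight = c(1, 0.3, 0))
  grid <- env$grid
  if (preset == "southern_refuge") {
    # the dominant climatic layer combines the latitudinal gradient with a
    # sharp mid-latitude discontinuity (a Palghat-Gap-like break), so the
    # two faunas have environmentally driven range edges
    lin <- seq(-1, 1, length.out = n_rows)
    step <- tanh((seq_len(n_rows) - (n_rows / 2 + 0.5)) / 2)
    env$layers[[1]] <- standardize(matrix(lin + step, n_rows, n_cols))
  }
  g1 <- env$layers[[1]][, 1]          # N-S gradient, identical columns
  row_to_g <- function(r) g1[pmin(pmax(round(r), 1), n_rows)]

  fauna <- NULL
  if (preset == "southern_refuge") {
    tree <- refuge_tree()
    spp <- tree$tip.label
    set.seed(seeds[2])
    target_row <- c(stats::runif(6, 0.72, 0.95) * n_rows,   # old: deep south
                    stats::runif(5, 0.62, 0.95) * n_rows,   # young southern
                    stats::runif(6, 0.05, 0.38) * n_rows,   # young northern
                    rep(n_rows / 2, 2))                     # widespread
    sd_row <- c(stats::runif(6, 3, 5), stats::runif(11, 4, 6.5),
                rep(n_rows, 2))
    fauna <- c(rep("south", 11), rep("north", 6), rep("wide", 2))
    names(fauna) <- spp
    # niche breadth in gradient units spanning +/- sd_row rows around the
    # optimum (the gradient is nonlinear, so measure it locally)
    sd_g <- vapply(seq_along(spp), function(i)
      max(abs(row_to_g(target_row[i] + sd_row[i]) -
                row_to_g(target_row[i] - sd_row[i])) / 2, 1e-3), 0)
    suit <- lapply(seq_along(spp), function(i)
      suitability_from_optima(env, c(row_to_g(target_row[i]), 0, 0),
                              c(sd_g[i], 1e6, 1e6)))
    names(suit) <- spp
    bias_truth <- matrix(rep(seq(1, 0.25, length.out = n_cols), each = n_rows),
                         n_rows, n_cols)  # west half better surveyed
  } else {
    tree <- simulate_tree(n_taxa, 0.08, 0.02, seed = seeds[2])
    spp <- tree$tip.label
    if (preset == "uniform") {
      suit <- lapply(spp, function(s) matrix(1, n_rows, n_cols))
      bias_truth <- matrix(1, n_rows, n_cols)
      names(suit) <- spp
    } else {                            # two_blocks
      south_mask <- (row(matrix(0, n_rows, n_cols)) > n_rows / 2) * 1
      n_south <- ceiling(n_taxa / 2)
      fauna <- c(rep("south", n_south), rep("north", n_taxa - n_south))
      names(fauna) <- spp
      suit <- lapply(seq_along(spp), function(i)
        if (fauna[i] == "south") south_mask else 1 - south_mask)
      names(suit) <- spp
      bias_truth <- matrix(1, n_rows, n_cols)
    }
  }
  true_suit <- env_stack(suit, grid)
  coarse <- coarsen_grid(grid, factor)
  occ_bin <- lapply(suit, function(m) binarize(aggregate_max(m, factor), 0.5))
  true_occupancy <- build_pam(occ_bin, coarse)

  occurrences <- sample_occurrences(true_suit, n_per_species, bias_truth,
                                    seed = seeds[3])
  cell_block <- ifelse(true_occupancy$coords$row > coarse$nrow / 2,
                       "south", "north")
  structure(list(env = env, tree = tree, true_suitability = true_suit,
                 true_occupancy = true_occupancy, occurrences = occurrences,
                 bias_truth = bias_truth, grid = grid, coarse_grid = coarse,
                 factor = factor, seed = seed, preset = preset,
                 truth = list(cell_block = cell_block, species_fauna = fauna)),
            class = "synthetic_world")
}

#' Write a synthetic world to disk
#'
#' Occurrences as CSV (`species,lon,lat`), tree as Newick, environmental
#' layers, per-species truth suitability and the bias surface as ESRI ASCII
#' grids, plus a JSON manifest recording the seed and parameters.
#'
#' @param world A `synthetic_world` from [make_fixture()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest list.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(world$occurrences, file.path(dir, "occurrences.csv"),
                   row.names = FALSE)
  ape::write.tree(world$tree, file.path(dir, "tree.nwk"))
  for (nm in names(world$env$layers))
    write_asc(world$env$layers[[nm]], world$grid,
              file.path(dir, paste0(nm, ".asc")))
  for (nm in names(world$true_suitability$layers))
    write_asc(world$true_suitability$layers[[nm]], world$grid,
              file.path(dir, paste0("truth_", nm, ".asc")))
  write_asc(world$bias_truth, world$grid, file.path(dir, "bias_truth.asc"))
  manifest <- list(preset = world$preset, seed = world$seed,
                   n_taxa = length(world$tree$tip.label),
                   n_rows = world$grid$nrow, n_cols = world$grid$ncol,
                   factor = world$factor)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
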