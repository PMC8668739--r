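test_that("birth-death trees are ultrametric, correctly sized and seeded", {
  t2 <- simulate_tree(2, 0.1, 0, seed = 1)
  expect_equal(length(t2$tip.label), 2)
  expect_equal(nrow(t2$edge), 2)
  expect_equal(t2$edge.length[1], t2$edge.length[2])
  t19 <- simulate_tree(19, 0.08, 0.02, seed = 1)
  expect_equal(length(t19$tip.label), 19)
  expect_equal(nrow(t19$edge), 36)            # 2n - 2 edges, binary rooted
  expect_identical(t19$tip.label, sprintf("sp%02d", 1:19))
  expect_identical(ape::write.tree(simulate_tree(19, 0.08, 0.02, seed = 5)),
                   ape::write.tree(simulate_tree(19, 0.08, 0.02, seed = 5)))
  # ultrametricity: every root-to-tip distance equals the depth
  depths <- ape::node.depth.edgelength(t19)[1:19]
  expect_equal(max(depths) - min(depths), 0, tolerance = 1e-8 * max(depths))
  expect_error(simulate_tree(5, 0.1, 0.2), "birth_rate")
})

test_that("landscapes are standardized, seeded and gradient-structured", {
  env <- simulate_landscape(20, 15, n_env = 1, autocorr_range = 0, seed = 3)
  l <- env$layers[[1]]
  expect_equal(mean(l), 0, tolerance = 1e-10)
  expect_equal(sd(as.vector(l)), 1, tolerance = 0.05)
  env2 <- simulate_landscape(20, 15, n_env = 1, autocorr_range = 0, seed = 3)
  expect_identical(env$layers, env2$layers)
  # a pure gradient layer increases monotonically southwards (row index)
  grad <- simulate_landscape(20, 15, n_env = 1, seed = 1,
                             gradient_weight = 1)$layers[[1]]
  expect_true(all(diff(rowMeans(grad)) > 0))
})

test_that("niche suitability obeys the Gaussian construction and its limits", {
  tr <- simulate_tree(6, 0.1, 0.02, seed = 2)
  env <- simulate_landscape(12, 10, n_env = 2, seed = 2)
  # infinitely broad niches: suitability 1 everywhere
  wide <- simulate_niches(tr, env, niche_sd = 1e9, phylo_signal = 0, seed = 1)
  expect_true(all(abs(unlist(wide$suitability$layers) - 1) < 1e-6))
  nich <- simulate_niches(tr, env, niche_sd = 0.8, phylo_signal = 0.5,
                          seed = 1)
  s <- unlist(nich$suitability$layers)
  expect_true(all(s > 0 & s <= 1))
  # a cell whose environment equals the optimum has suitability exactly 1
  env_d <- env
  env_d$layers[[1]][1, 1] <- nich$optima[1, 1]
  env_d$layers[[2]][1, 1] <- nich$optima[1, 2]
  s_d <- suitability_from_optima(env_d, nich$optima[1, ], 0.8)
  expect_equal(s_d[1, 1], 1)
})

test_that("brownian optima carry phylogenetic signal when requested", {
  # under pure Brownian evolution, species separated by little evolutionary
  # time have similar optima: optimum distance correlates with patristic
  # distance across replicate trees
  set.seed(99)
  cors <- vapply(1:40, function(i) {
    tr <- simulate_tree(8, 0.1, 0.02, seed = 1000 + i)
    env <- simulate_landscape(10, 10, n_env = 1, seed = 1)
    opt <- simulate_niches(tr, env, phylo_signal = 1, seed = i)$optima[, 1]
    pat <- ape::cophenetic.phylo(tr)[names(opt), names(opt)]
    d_opt <- abs(outer(opt, opt, "-"))
    lower <- lower.tri(pat)
    cor(pat[lower], d_opt[lower])
  }, 0)
  expect_gt(mean(cors), 0)
  expect_gt(mean(cors > 0), 0.7)
})

test_that("occurrence sampling respects weights, counts and errors", {
  g <- grid_spec(0, 4, 1, 4, 4)
  delta <- matrix(0, 4, 4); delta[2, 3] <- 1
  suit <- env_stack(list(spA = delta), g)
  occ <- sample_occurrences(suit, n_per_species = 1, seed = 1)
  rc <- cell_of_point(g, occ$lon, occ$lat)
  expect_equal(c(rc$row, rc$col), c(2, 3))
  # exact per-species counts
  flat <- env_stack(list(a = matrix(1, 4, 4), b = matrix(1, 4, 4),
                         c = matrix(1, 4, 4)), g)
  occ3 <- sample_occurrences(flat, n_per_species = 3, seed = 2)
  expect_equal(nrow(occ3), 9)
  expect_true(all(table(occ3$species) == 3))
  # more points than positive cells
  expect_error(sample_occurrences(suit, n_per_species = 5, seed = 1),
               "positive weight")
  # strong western bias concentrates sampling in the west
  gw <- grid_spec(0, 20, 1, 20, 20)
  s_flat <- env_stack(list(a = matrix(1, 20, 20)), gw)
  bias <- matrix(rep(c(1, 0.01), each = 20 * 10), 20, 20)
  west_frac <- vapply(1:10, function(sd) {
    o <- sample_occurrences(s_flat, n_per_species = 20, bias_truth = bias,
                            seed = sd)
    mean(o$lon < 10)
  }, 0)
  expect_gt(mean(west_frac), 0.9)
})

test_that("sampled cell frequencies follow the normalized product weights", {
  # chi-square goodness of fit against suitability x bias, grouped into
  # weight quantile bins to keep expected counts healthy
  g <- grid_spec(0, 50, 1, 50, 40)
  set.seed(12)
  suit <- matrix(runif(2000), 50, 40)
  bias <- matrix(runif(2000), 50, 40)
  stack <- env_stack(list(sp = suit), g)
  counts <- matrix(0, 50, 40)
  for (sd in 1:5) {
    o <- sample_occurrences(stack, n_per_species = 40, bias_truth = bias,
                            seed = sd)
    rc <- cell_of_point(g, o$lon, o$lat)
    for (k in seq_len(nrow(rc))) counts[rc$row[k], rc$col[k]] <-
        counts[rc$row[k], rc$col[k]] + 1
  }
  w <- as.vector(suit * bias)
  bin <- cut(rank(w, ties.method = "first"), 10)
  obs <- tapply(as.vector(counts), bin, sum)
  expct <- tapply(w / sum(w), bin, sum) * sum(counts)
  p <- suppressWarnings(chisq.test(obs, p = expct / sum(expct)))$p.value
  expect_gt(p, 0.001)
})

test_that("fixture worlds satisfy their invariants", {
  for (preset in c("southern_refuge", "uniform", "two_blocks")) {
    w <- make_fixture(preset, n_rows = 40, n_cols = 20, factor = 4, seed = 11)
    spp <- w$tree$tip.label
    # every species has occurrences and occupied coarse cells
    expect_setequal(unique(w$occurrences$species), spp)
    expect_true(all(range_sizes(w$true_occupancy) >= 1))
    expect_setequal(colnames(w$true_occupancy$mat), spp)
    # suitability in [0,1], environment finite
    expect_true(all(unlist(w$true_suitability$layers) >= 0 &
                      unlist(w$true_suitability$layers) <= 1))
    expect_true(all(is.finite(unlist(w$env$layers))))
    # ultrametric within 1e-6 of the depth
    dep <- ape::node.depth.edgelength(w$tree)[seq_along(spp)]
    expect_lt(max(dep) - min(dep), 1e-6 * max(dep))
  }
})

test_that("fixture determinism: identical seeds give identical worlds", {
  w1 <- make_fixture("southern_refuge", seed = 4)
  w2 <- make_fixture("southern_refuge", seed = 4)
  expect_identical(w1$occurrences, w2$occurrences)
  expect_identical(w1$env$layers, w2$env$layers)
  expect_identical(w1$true_occupancy$mat, w2$true_occupancy$mat)
  expect_identical(ape::write.tree(w1$tree), ape::write.tree(w2$tree))
})

test_that("preset structure: blocks are disjoint, uniform is saturated, the
           refuge is diverse in the south", {
  tb <- make_fixture("two_blocks", seed = 6)
  occ <- drop_empty_cells(tb$true_occupancy)
  blk <- ifelse(occ$coords$row > tb$coarse_grid$nrow / 2, "s", "n")
  d <- simpson_dissimilarity(occ)
  expect_true(all(d[blk == "s", blk == "n"] == 1))
  un <- make_fixture("uniform", seed = 6)
  expect_equal(length(unique(taxonomic_diversity(un$true_occupancy))), 1)
  sr <- make_fixture("southern_refuge", seed = 6)
  td <- taxonomic_diversity(sr$true_occupancy)
  rows <- sr$true_occupancy$coords$row
  nr <- sr$coarse_grid$nrow
  expect_gt(mean(td[rows > nr - 3]), mean(td[rows <= 3]))
})

test_that("write_world produces the full text bundle", {
  w <- make_fixture("uniform", n_taxa = 4, n_rows = 12, n_cols = 10,
                    factor = 4, seed = 2)
  d <- tempfile()
  write_world(w, d)
  expect_true(file.exists(file.path(d, "occurrences.csv")))
  expect_true(file.exists(file.path(d, "tree.nwk")))
  expect_true(file.exists(file.path(d, "manifest.json")))
  expect_true(file.exists(file.path(d, "bias_truth.asc")))
  occ <- read_occurrences(file.path(d, "occurrences.csv"))
  expect_equal(occ, w$occurrences[, c("species", "lon", "lat")],
               ignore_attr = TRUE)
  tr <- read_tree(file.path(d, "tree.nwk"))
  expect_setequal(tr$tip.label, w$tree$tip.label)
  unlink(d, recursive = TRUE)
})
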