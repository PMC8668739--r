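test_that("feature construction matches the L/Q/H definitions", {
  x <- matrix(c(0, 1, 2), dimnames = list(NULL, "x"))
  def_l <- attr(build_features(x, feature_spec("L")), "def")
  expect_equal(unname(featurize(def_l, x)[, 1]), c(0, 1, 2))
  def_q <- attr(build_features(x, feature_spec("Q")), "def")
  raw_q <- featurize(def_q, x)
  expect_equal(unname(raw_q[, 1]), c(0, 1, 4))
  # one knot at the median: forward hinge ramps from the knot to the max
  def_h <- attr(build_features(x, feature_spec("H", n_hinge_knots = 1)), "def")
  raw_h <- featurize(def_h, x)
  fwd <- grep("fwd", colnames(raw_h))
  expect_equal(unname(raw_h[, fwd]), c(0, 0, 1))
  rev <- grep("rev", colnames(raw_h))
  expect_equal(unname(raw_h[, rev]), c(1, 0, 0))
})

test_that("categorical covariates expand to indicators regardless of class", {
  x <- cbind(x = c(0, 1, 2, 3), soil = c(1, 1, 2, 3))
  X <- build_features(x, feature_spec("L"), categorical = "soil")
  def <- attr(X, "def")
  expect_equal(sum(def$type == "C"), 3)
  raw <- featurize(def, x)
  expect_equal(unname(raw[, def$type == "C"][, 1]), c(1, 1, 0, 0))
})

test_that("apply_features reuses training standardization on new data", {
  set.seed(1)
  x <- matrix(rnorm(50), dimnames = list(NULL, "x"))
  X <- build_features(x, feature_spec("LQ"))
  def <- attr(X, "def")
  expect_equal(apply_features(def, x), X, ignore_attr = TRUE)
  x_new <- matrix(rnorm(10), dimnames = list(NULL, "x"))
  X_new <- apply_features(def, x_new)
  expect_equal(unname(X_new[, 1]),
               unname((x_new[, 1] - def$center[1]) / def$scale[1]))
})

test_that("uninformative and over-penalized fits shrink to the constant map", {
  set.seed(2)
  const <- matrix(1, 30, 1, dimnames = list(NULL, "x"))
  m <- fit_presence_background(const[1:10, , drop = FALSE],
                               const[11:30, , drop = FALSE],
                               list(fc = "LQ", rm = 1))
  expect_true(all(m$beta == 0))
  pred <- predict(m, matrix(c(0, 5, 9), dimnames = list(NULL, "x")))
  expect_equal(pred[1], pred[2])
  xp <- matrix(rnorm(15, 2), dimnames = list(NULL, "x"))
  xb <- matrix(rnorm(100), dimnames = list(NULL, "x"))
  m_big <- fit_presence_background(xp, xb, list(fc = "LQ", rm = 500))
  expect_true(all(abs(m_big$beta) < 1e-8))
})

test_that("a positive environmental response is recovered with the right sign", {
  set.seed(3)
  xp <- matrix(rnorm(25, 1.5, 0.5), dimnames = list(NULL, "x"))
  xb <- matrix(rnorm(300), dimnames = list(NULL, "x"))
  m <- fit_presence_background(xp, xb, list(fc = "L", rm = 1))
  expect_gt(m$beta[1], 0)
  grid <- matrix(seq(-2, 2, 0.25), dimnames = list(NULL, "x"))
  pr <- predict(m, grid)
  expect_true(all(diff(pr) > 0))
  expect_true(all(pr >= 0 & pr <= 1))
})

test_that("the solver matches direct grid maximization of the objective", {
  set.seed(4)
  for (i in 1:5) {
    n_p <- sample(5:12, 1)
    xp <- matrix(rnorm(n_p, 1), dimnames = list(NULL, "x"))
    xb <- matrix(rnorm(sample(10:25, 1)), dimnames = list(NULL, "x"))
    rm <- sample(c(0.5, 1, 2), 1)
    m <- fit_presence_background(xp, xb, list(fc = "L", rm = rm))
    X <- build_features(rbind(xp, xb), feature_spec("L"))
    Xp <- X[seq_len(n_p), , drop = FALSE]
    Xb_aug <- rbind(X[-seq_len(n_p), , drop = FALSE], Xp)
    lam <- rm / sqrt(n_p)
    grid <- seq(-8, 8, 1e-4)
    obj <- vapply(grid, function(b)
      oracle_pb_objective(b, Xp[, 1], Xb_aug[, 1], lam), 0)
    expect_equal(unname(m$beta[1]), grid[which.max(obj)], tolerance = 5e-4)
  }
})

test_that("collapsing duplicate background draws is exactly draw-level", {
  set.seed(5)
  xp <- matrix(rnorm(10, 1), dimnames = list(NULL, "x"))
  cells <- sample(1:20, 200, replace = TRUE)
  vals <- rnorm(20)
  xb <- matrix(vals[cells], dimnames = list(NULL, "x"))
  m1 <- fit_presence_background(xp, xb, list(fc = "LQ", rm = 1))
  m2 <- fit_presence_background(xp, xb, list(fc = "LQ", rm = 1),
                                background_cells = cells)
  expect_equal(m1$beta, m2$beta, tolerance = 1e-6)
  nd <- matrix(seq(-2, 2, 0.5), dimnames = list(NULL, "x"))
  expect_equal(predict(m1, nd), predict(m2, nd), tolerance = 1e-8)
})

test_that("auc implements the midrank Mann-Whitney form", {
  expect_equal(auc(c(0.9, 0.8), c(0.7, 0.1)), 1)
  expect_equal(auc(0.5, 0.5), 0.5)
  expect_equal(auc(c(0.9, 0.4), c(0.6, 0.2)), 0.75)
  set.seed(6)
  for (i in 1:50) {
    pos <- sample(0:10, sample(1:8, 1), replace = TRUE) / 10
    neg <- sample(0:10, sample(1:8, 1), replace = TRUE) / 10
    expect_equal(auc(pos, neg), oracle_auc(pos, neg))
    # invariance under strictly monotone transforms
    expect_equal(auc(exp(3 * pos), exp(3 * neg)), auc(pos, neg))
  }
})

test_that("bias layer tracks the spatial distribution of pooled points", {
  set.seed(7)
  env <- simulate_landscape(12, 12, n_env = 2, autocorr_range = 0, seed = 1,
                            gradient_weight = c(0, 0),
                            grid = grid_spec(0, 12, 1, 12, 12))
  # east-west gradient as the informative layer
  env$layers[[1]] <- matrix(rep(seq(-1.5, 1.5, length.out = 12),
                                each = 12), 12, 12)
  west <- data.frame(lon = runif(40, 0, 5), lat = runif(40, 0, 12))
  # the small grid has few distinct values, so knot deduplication may warn
  bias <- suppressWarnings(
    make_bias_layer(west, env, n_background = 500, seed = 2))
  expect_true(all(bias >= 0 & bias <= 1))
  expect_gt(mean(bias[, 1:6]), mean(bias[, 7:12]))
  # uniform points give an approximately flat surface
  unif <- data.frame(lon = runif(80, 0, 12), lat = runif(80, 0, 12))
  bias_u <- suppressWarnings(
    make_bias_layer(unif, env, n_background = 500, seed = 3))
  expect_lt(diff(range(bias_u)), 0.35)
})

test_that("background sampling follows the bias weights", {
  g <- grid_spec(0, 2, 1, 2, 2)
  # all mass in one cell
  delta <- matrix(c(0, 0, 1, 0), 2, 2)
  bs <- sample_background(delta, g, n = 50, seed = 1)
  expect_true(all(bs$xy$row == 1 & bs$xy$col == 2))
  expect_error(sample_background(matrix(0, 2, 2), g, 10, 1), "no positive")
  # 1:3 weights on two cells: frequency within exact binomial bounds
  two <- matrix(c(1, 0, 3, 0), 2, 2)
  bs2 <- sample_background(two, g, n = 2000, seed = 2)
  k <- sum(bs2$xy$col == 2)
  ci <- binom.test(k, 2000, 0.75)$conf.int
  expect_true(ci[1] < 0.75 && 0.75 < ci[2])
  # uniform bias: chi-square uniformity over cells
  unif <- matrix(1, 2, 2)
  bs3 <- sample_background(unif, g, n = 4000, seed = 3)
  tab <- table(paste(bs3$xy$row, bs3$xy$col))
  expect_gt(chisq.test(tab)$p.value, 0.001)
})

test_that("partitioning: corner clusters give 4 balanced blocks, small n LOO", {
  set.seed(8)
  corners <- rbind(
    data.frame(lon = runif(5, 0, 1), lat = runif(5, 0, 1)),
    data.frame(lon = runif(5, 9, 10), lat = runif(5, 0, 1)),
    data.frame(lon = runif(5, 0, 1), lat = runif(5, 9, 10)),
    data.frame(lon = runif(5, 9, 10), lat = runif(5, 9, 10)))
  bias <- matrix(1, 10, 10)
  bs <- sample_background(bias, grid_spec(0, 10, 1, 10, 10), n = 200, seed = 1)
  folds <- partition_occurrences(corners, bs)
  expect_length(folds, 4)
  expect_true(all(vapply(folds, function(f) length(f$test_p), 0L) == 5))
  # test sets partition the points
  tests <- sort(unlist(lapply(folds, `[[`, "test_p")))
  expect_identical(tests, 1:20)
  # background is partitioned alongside
  btests <- sort(unlist(lapply(folds, `[[`, "test_b")))
  expect_identical(unique(btests), seq_len(200))
  # fewer than 20 points: leave-one-out with full background
  small <- corners[1:5, ]
  folds_s <- partition_occurrences(small, bs)
  expect_length(folds_s, 5)
  expect_true(all(vapply(folds_s, function(f) length(f$test_p), 0L) == 1))
  expect_true(all(vapply(folds_s, function(f) length(f$train_b), 0L) == 200))
})

test_that("evaluation of a constant model gives AUC 0.5 and zero omission", {
  set.seed(9)
  env <- simulate_landscape(10, 10, n_env = 1, autocorr_range = 0, seed = 1,
                            grid = grid_spec(0, 10, 1, 10, 10))
  bs <- sample_background(matrix(1, 10, 10), env$grid, n = 100, seed = 2,
                          env = env)
  pts <- data.frame(lon = runif(6, 0, 10), lat = runif(6, 0, 10))
  pres_env <- extract_env(env, pts$lon, pts$lat)
  folds <- partition_occurrences(pts, bs)
  # an extreme penalty forces the constant model
  ev <- evaluate_settings(pres_env, bs, list(fc = "L", rm = 1e6), folds)
  expect_equal(ev$auc_test, 0.5)
  expect_equal(ev$auc_diff, 0)
  expect_equal(ev$or_mtp, 0)     # test presences equal the MTP, not below it
  expect_equal(ev$n_folds, 6)
})

test_that("select_model follows the sequential rule and ignores order", {
  single <- data.frame(fc = "L", rm = 1, or_mtp = 0.2, auc_diff = 0.1,
                       auc_test = 0.7)
  expect_equal(select_model(single), single)
  two <- data.frame(fc = c("L", "Q"), rm = 1,
                    or_mtp = c(0.1, 0.2), auc_diff = 0, auc_test = 0.7)
  expect_equal(select_model(two)$fc, "L")
  tie <- data.frame(fc = c("L", "Q"), rm = 1, or_mtp = 0.1, auc_diff = 0.05,
                    auc_test = c(0.8, 0.9))
  expect_equal(select_model(tie)$fc, "Q")
  # filter first: a candidate below the AUC gate never wins
  gated <- data.frame(fc = c("L", "Q"), rm = 1, or_mtp = c(0, 0.3),
                      auc_diff = 0, auc_test = c(0.55, 0.7))
  expect_equal(select_model(gated)$fc, "Q")
  # no candidate passes: fall back to the full set with a warning
  none <- data.frame(fc = c("L", "Q"), rm = 1, or_mtp = c(0.3, 0.1),
                     auc_diff = 0, auc_test = 0.5)
  expect_warning(sel <- select_model(none), "full set")
  expect_equal(sel$fc, "Q")
  # permutation invariance on random tables
  set.seed(10)
  for (i in 1:25) {
    tab <- data.frame(
      fc = sample(c("LQH", "LQ", "QH", "L", "Q", "H"), 12, replace = TRUE),
      rm = sample(seq(0.5, 5, 0.5), 12, replace = TRUE),
      or_mtp = round(runif(12), 1), auc_diff = round(runif(12, 0, 0.2), 2),
      auc_test = round(runif(12, 0.4, 1), 2))
    sel1 <- suppressWarnings(select_model(tab))
    perm <- tab[sample(12), ]
    sel2 <- suppressWarnings(select_model(perm))
    expect_equal(sel1, sel2, ignore_attr = TRUE)
  }
})
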