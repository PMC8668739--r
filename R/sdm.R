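# Presence-background species distribution models: linear / quadratic /
# hinge feature construction, an L1-penalized exponential (Gibbs) model
# fitted by proximal gradient, bias-layer background sampling,
# geographically structured evaluation and sequential model selection.

#' Feature class specification
#'
#' @param classes One of `"LQH"`, `"LQ"`, `"QH"`, `"L"`, `"Q"`, `"H"` (any
#'   nonempty subset of the letters L, Q, H).
#' @param n_hinge_knots Hinge knots per covariate per direction, placed at
#'   equally spaced quantiles of the training values.
#' @return An object of class `feature_spec`.
#' @export
feature_spec <- function(classes = "LQH", n_hinge_knots = 10) {
  cls <- strsplit(classes, "")[[1]]
  stopifnot(length(cls) >= 1, all(cls %in% c("L", "Q", "H")))
  structure(list(classes = cls, n_hinge_knots = n_hinge_knots),
            class = "feature_spec")
}

#' The full candidate settings grid
#'
#' Six feature-class combinations crossed with ten regularization
#' multipliers, 60 settings in all.
#'
#' @param classes Character vector of feature-class combinations.
#' @param rm Numeric vector of regularization multipliers.
#' @return Data frame with columns `fc` and `rm`.
#' @export
settings_grid <- function(classes = c("LQH", "LQ", "QH", "L", "Q", "H"),
                          rm = seq(0.5, 5, by = 0.5)) {
  expand.grid(fc = classes, rm = rm, KEEP.OUT.ATTRS = FALSE,
              stringsAsFactors = FALSE)
}

# Feature definition: everything needed to rebuild the design matrix on new
# data (knots from the training values, standardization constants from the
# training design).
make_feature_def <- function(x, spec, categorical = character(0)) {
  stopifnot(is.matrix(x), !is.null(colnames(x)))
  feats <- list()
  for (cv in colnames(x)) {
    v <- x[, cv]
    if (cv %in% categorical) {
      for (lev in sort(unique(v)))
        feats[[length(feats) + 1L]] <- list(type = "C", cov = cv, level = lev)
      next
    }
    if ("L" %in% spec$classes)
      feats[[length(feats) + 1L]] <- list(type = "L", cov = cv)
    if ("Q" %in% spec$classes)
      feats[[length(feats) + 1L]] <- list(type = "Q", cov = cv)
    if ("H" %in% spec$classes) {
      probs <- seq_len(spec$n_hinge_knots) / (spec$n_hinge_knots + 1)
      knots <- unique(as.numeric(stats::quantile(v, probs, names = FALSE)))
      if (length(knots) < spec$n_hinge_knots)
        warning("covariate ", cv, ": hinge knots deduplicated to ",
                length(knots))
      rng <- range(v)
      for (k in knots) {
        if (k < rng[2])
          feats[[length(feats) + 1L]] <-
            list(type = "H", cov = cv, knot = k, dir = "fwd", rng = rng)
        if (k > rng[1])
          feats[[length(feats) + 1L]] <-
            list(type = "H", cov = cv, knot = k, dir = "rev", rng = rng)
      }
    }
  }
  structure(list(features = feats, center = NULL, scale = NULL),
            class = "feature_def")
}

featurize <- function(def, x) {
  cols <- lapply(def$features, function(f) {
    v <- x[, f$cov]
    switch(f$type,
           L = v,
           Q = v^2,
           C = (v == f$level) * 1,
           H = if (f$dir == "fwd")
             pmax(0, (v - f$knot) / (f$rng[2] - f$knot))
           else
             pmax(0, (f$knot - v) / (f$knot - f$rng[1])))
  })
  m <- do.call(cbind, cols)
  colnames(m) <- vapply(def$features, function(f)
    paste0(f$type, "_", f$cov,
           if (f$type == "H") sprintf("_%s_%.4g", f$dir, f$knot)
           else if (f$type == "C") paste0("_", f$level) else ""), "")
  m
}

#' Build the design matrix for a feature specification
#'
#' Linear features are the covariates themselves, quadratic their squares,
#' hinge features are forward `max(0, (x - k)/(xmax - k))` and reverse
#' `max(0, (k - x)/(k - xmin))` ramps at quantile knots; categorical
#' covariates expand to indicators regardless of the class set. Features
#' are standardized by the mean and sd of the supplied (training) data;
#' the returned definition reapplies the same transform to new data.
#'
#' @param x Numeric matrix of covariates (observations x covariates, named
#'   columns, finite values).
#' @param spec A [feature_spec()].
#' @param categorical Names of covariates to expand as indicators.
#' @return Standardized design matrix with attribute `def` (the
#'   `feature_def` used by [apply_features()]). Zero-variance columns are
#'   kept but flagged in `def$zero_var`.
#' @export
build_features <- function(x, spec, categorical = character(0)) {
  def <- make_feature_def(x, spec, categorical)
  raw <- featurize(def, x)
  def$center <- colMeans(raw)
  def$scale <- apply(raw, 2, stats::sd)
  def$zero_var <- def$scale == 0
  def$scale[def$zero_var] <- 1
  def$type <- vapply(def$features, `[[`, "", "type")
  out <- scale(raw, center = def$center, scale = def$scale)
  attr(out, "def") <- def
  out
}

#' Apply a stored feature definition to new covariates
#'
#' @param def The `feature_def` attribute of a [build_features()] design.
#' @param x New covariate matrix (same column names).
#' @return Standardized design matrix.
#' @export
apply_features <- function(def, x) {
  scale(featurize(def, x), center = def$center, scale = def$scale)
}

logsumexp <- function(v) {
  m <- max(v)
  m + log(sum(exp(v - m)))
}

# Penalized presence-background (Gibbs) log-likelihood:
#   l(beta) = mean_p(eta_p) - log(mean_b exp(eta_b)) - sum_j lambda_j |beta_j|
# maximized by FISTA (proximal gradient with Nesterov momentum and
# backtracking). Duplicate background locations (repeated draws of the same
# cell) may be collapsed into integer counts `cb`; the computation is
# identical to the draw-level one.
pb_objective <- function(beta, Xp, Xb, lambda, cb = NULL) {
  if (is.null(cb)) cb <- rep(1, nrow(Xb))
  etab <- as.vector(Xb %*% beta) + log(cb)
  mean(Xp %*% beta) - (logsumexp(etab) - log(sum(cb))) -
    sum(lambda * abs(beta))
}

pb_fista <- function(Xp, Xb, lambda, beta0 = NULL, tol = 1e-9,
                     max_iter = 5000L, cb = NULL) {
  p <- ncol(Xp)
  beta <- if (is.null(beta0)) numeric(p) else beta0
  y <- beta; t_k <- 1
  mp <- colMeans(Xp)
  log_cb <- if (is.null(cb)) numeric(nrow(Xb)) else log(cb)
  smooth_neg <- function(b) {
    etab <- as.vector(Xb %*% b) + log_cb
    (logsumexp(etab) - logsumexp(log_cb)) - mean(Xp %*% b)
  }
  grad_neg <- function(b) {
    etab <- as.vector(Xb %*% b) + log_cb
    w <- exp(etab - logsumexp(etab))
    as.vector(crossprod(Xb, w)) - mp
  }
  L <- 1
  f_old <- smooth_neg(beta) + sum(lambda * abs(beta))
  for (it in seq_len(max_iter)) {
    g <- grad_neg(y)
    fy <- smooth_neg(y)
    repeat {
      cand <- sign(y - g / L) * pmax(0, abs(y - g / L) - lambda / L)
      diff <- cand - y
      if (smooth_neg(cand) <= fy + sum(g * diff) + L / 2 * sum(diff^2) + 1e-12)
        break
      L <- L * 2
      if (L > 1e12) break
    }
    t_new <- (1 + sqrt(1 + 4 * t_k^2)) / 2
    y <- cand + ((t_k - 1) / t_new) * (cand - beta)
    beta <- cand; t_k <- t_new
    f_new <- smooth_neg(beta) + sum(lambda * abs(beta))
    if (it > 1 && abs(f_old - f_new) < tol * (abs(f_old) + 1)) {
      return(list(beta = beta, converged = TRUE, iter = it))
    }
    f_old <- f_new
    L <- max(L / 2, 1e-3)
  }
  list(beta = beta, converged = FALSE, iter = max_iter)
}

base_penalty_default <- c(L = 1, Q = 1, H = 0.5, C = 0.25)

#' Fit a penalized presence-background distribution model
#'
#' Maximizes the presence-background exponential-model log-likelihood
#' (mean linear predictor at presences minus the log of the mean
#' exponentiated predictor over the background, with the presence
#' locations included in the background so the likelihood stays bounded
#' under complete separation) under a per-feature L1
#' penalty `lambda_j = rm * base(type_j) * sd_j / sqrt(n_presence)`, where
#' `sd_j` is the (post-standardization) feature sd and `base` defaults to 1
#' for linear/quadratic, 0.5 for hinge and 0.25 for categorical features.
#' Predictions are normalized over the training background and mapped to
#' `[0,1]` by the cloglog transform `1 - exp(-exp(H) * raw)`, `H` the
#' entropy of the background raw distribution.
#'
#' @param presence,background Covariate matrices (points x covariates) for
#'   presences (>= 3 rows) and background.
#' @param settings A list or one-row data frame with `fc` (feature classes)
#'   and `rm` (regularization multiplier > 0).
#' @param categorical Names of categorical covariates.
#' @param base_penalty Named per-type penalty constants.
#' @param n_hinge_knots Hinge knots per covariate per direction.
#' @param beta0 Optional warm-start coefficients.
#' @param background_cells Optional id vector (one per background row, e.g.
#'   cell indices): duplicate draws of the same cell are collapsed into
#'   count weights before optimization, which is exactly equivalent to the
#'   draw-level fit but far faster for large background samples.
#' @return An object of class `sdm_model`.
#' @export
fit_presence_background <- function(presence, background, settings,
                                    categorical = character(0),
                                    base_penalty = base_penalty_default,
                                    n_hinge_knots = 10, beta0 = NULL,
                                    background_cells = NULL) {
  # the community pipeline requires >= 3 presences per species; per-fold
  # training sets of a leave-one-out partition may hold one fewer
  stopifnot(nrow(presence) >= 2, nrow(background) >= 1, settings$rm > 0)
  spec <- feature_spec(as.character(settings$fc), n_hinge_knots)
  X <- build_features(rbind(presence, background), spec, categorical)
  def <- attr(X, "def")
  Xp <- X[seq_len(nrow(presence)), , drop = FALSE]
  Xb <- X[-seq_len(nrow(presence)), , drop = FALSE]
  cb <- rep(1, nrow(Xb))
  if (!is.null(background_cells)) {
    cl <- collapse_rows(Xb, background_cells)
    Xb <- cl$X; cb <- cl$counts
  }
  # presence locations join the background (as in Maxent), which keeps the
  # penalized likelihood bounded under complete separation
  pb_fit_design(Xp, rbind(Xb, Xp), def, as.character(settings$fc),
                settings$rm, base_penalty, beta0,
                cb = c(cb, rep(1, nrow(Xp))))
}

collapse_rows <- function(X, ids) {
  u <- which(!duplicated(ids))
  map <- match(ids, ids[u])
  list(X = X[u, , drop = FALSE], counts = tabulate(map, nbins = length(u)),
       u = u, map = map)
}

# Fit on a prebuilt standardized design (shared by fit_presence_background
# and the warm-started tuning loop). `cb` holds background counts when
# duplicate draws of the same cell have been collapsed.
pb_fit_design <- function(Xp, Xb, def, fc, rm, base_penalty, beta0 = NULL,
                          cb = NULL) {
  lambda <- rm * base_penalty[def$type] / sqrt(nrow(Xp))
  # zero-variance features standardize to an all-zero column; a large finite
  # penalty keeps the optimizer away from them and the coefficient at 0
  lambda[def$zero_var] <- 1e10
  fit <- pb_fista(Xp, Xb, lambda, beta0 = beta0, cb = cb)
  if (!fit$converged)
    stop(sprintf("presence-background fit did not converge (fc=%s, rm=%g)",
                 fc, rm))
  beta <- fit$beta
  beta[def$zero_var] <- 0
  if (is.null(cb)) cb <- rep(1, nrow(Xb))
  etab <- as.vector(Xb %*% beta) + log(cb)
  log_z <- logsumexp(etab)
  raw_b <- exp(etab - log_z)
  # entropy of the draw-level background distribution (each of the cb
  # copies of a cell carries mass raw_b/cb)
  entropy <- -sum(raw_b * (log(pmax(raw_b, 1e-300)) - log(cb)))
  structure(list(settings = list(fc = fc, rm = rm),
                 def = def, beta = beta, log_z = log_z, entropy = entropy,
                 iter = fit$iter),
            class = "sdm_model")
}

#' @export
print.sdm_model <- function(x, ...) {
  cat(sprintf("sdm_model: fc=%s rm=%g, %d/%d nonzero features\n",
              x$settings$fc, x$settings$rm, sum(x$beta != 0), length(x$beta)))
  invisible(x)
}

#' Predict relative habitat suitability
#'
#' @param object An `sdm_model`.
#' @param newdata Covariate matrix, or an [env_stack()] (prediction over
#'   every cell, returned as a raster matrix).
#' @param type `"cloglog"` (default, in `[0,1]`), `"logistic"`, `"raw"`
#'   (normalized over the training background) or `"link"`.
#' @param ... Unused.
#' @return Numeric vector, or a matrix when `newdata` is an `env_stack`.
#' @export
predict.sdm_model <- function(object, newdata, type = "cloglog", ...) {
  as_raster <- inherits(newdata, "env_stack")
  if (as_raster) {
    grid <- newdata$grid
    newdata <- do.call(cbind, lapply(newdata$layers, as.vector))
  }
  X <- apply_features(object$def, newdata)
  eta <- as.vector(X %*% object$beta)
  raw <- exp(eta - object$log_z)
  out <- switch(type,
                link = eta,
                raw = raw,
                cloglog = 1 - exp(-exp(object$entropy) * raw),
                logistic = {
                  q <- exp(object$entropy) * raw
                  q / (1 + q)
                },
                stop("unknown type: ", type))
  if (as_raster) matrix(out, grid$nrow, grid$ncol) else out
}

# prediction from an already-built standardized design matrix
predict_design <- function(object, X, type = "cloglog") {
  eta <- as.vector(X %*% object$beta)
  raw <- exp(eta - object$log_z)
  switch(type,
         raw = raw,
         cloglog = 1 - exp(-exp(object$entropy) * raw),
         stop("unknown type: ", type))
}

#' Survey-bias layer from pooled occurrences
#'
#' Fits a default presence-background model (`fc = "LQH"`, `rm = 1`) to the
#' pooled occurrences of all species against uniform random background, so
#' that high values mark environments more likely to have been surveyed.
#'
#' @param occurrences Data frame with `lon`, `lat` for all species pooled
#'   (>= 10 points).
#' @param env An [env_stack()].
#' @param n_background Number of uniform background draws.
#' @param seed Integer seed.
#' @param categorical Categorical covariate names.
#' @return Suitability raster (matrix in `[0,1]`) on the grid of `env`.
#' @export
make_bias_layer <- function(occurrences, env, n_background = 10000,
                            seed = 1L, categorical = character(0)) {
  stopifnot(nrow(occurrences) >= 10)
  set.seed(seed)
  grid <- env$grid
  pres <- extract_env(env, occurrences$lon, occurrences$lat)
  pres <- pres[stats::complete.cases(pres), , drop = FALSE]
  ok_cells <- which(Reduce(`&`, lapply(env$layers, function(l) !is.na(l))))
  cells <- sample(ok_cells, n_background, replace = TRUE)
  bg <- do.call(cbind, lapply(env$layers, function(l) l[cells]))
  model <- fit_presence_background(pres, bg, list(fc = "LQH", rm = 1),
                                   categorical = categorical,
                                   background_cells = cells)
  predict(model, env)
}

#' Sample background locations from a bias layer
#'
#' Cells are drawn with replacement with probability proportional to the
#' bias value; points are placed at cell centres.
#'
#' @param bias Nonnegative raster matrix (at least one positive cell).
#' @param grid The [grid_spec()] of `bias`.
#' @param n Number of draws (default 10,000, a full-scale background sample).
#' @param seed Integer seed.
#' @param env Optional [env_stack()]; when given, covariate values are
#'   attached.
#' @return A `background_set`: list with `xy` (data frame `lon`, `lat`,
#'   `row`, `col`), `env` (matrix or `NULL`), `seed`.
#' @export
sample_background <- function(bias, grid, n = 10000, seed = 1L, env = NULL) {
  w <- as.vector(bias)
  w[is.na(w)] <- 0
  if (all(w <= 0)) stop("bias layer has no positive cell")
  set.seed(seed)
  cells <- sample.int(length(w), n, replace = TRUE, prob = w)
  row <- (cells - 1L) %% grid$nrow + 1L
  col <- (cells - 1L) %/% grid$nrow + 1L
  cc <- cell_center(grid, row, col)
  xy <- data.frame(lon = cc$lon, lat = cc$lat, row = row, col = col)
  ev <- if (!is.null(env)) extract_env(env, xy$lon, xy$lat) else NULL
  structure(list(xy = xy, env = ev, seed = seed), class = "background_set")
}

#' Area under the ROC curve (rank form)
#'
#' Probability that a random positive scores above a random negative, with
#' ties counting one half (Mann-Whitney statistic). Invariant under any
#' strictly monotone transform of the scores.
#'
#' @param pos_scores,neg_scores Nonempty numeric vectors.
#' @return Value in `[0,1]`.
#' @export
auc <- function(pos_scores, neg_scores) {
  np <- length(pos_scores); nn <- length(neg_scores)
  stopifnot(np > 0, nn > 0)
  r <- rank(c(pos_scores, neg_scores))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

#' Geographically structured evaluation folds
#'
#' Species with 20 or more presences: presences and background are assigned
#' to four spatial blocks split at the presence median longitude and
#' latitude; each fold trains on three blocks (presences and background
#' masked alike) and tests on the held-out block. A block holding no
#' presence is merged into the nearest block (by centroid) with a warning.
#' Fewer than 20 presences: leave-one-out over presences with the full
#' background on both sides.
#'
#' @param points Data frame with `lon`, `lat` for one species (>= 3 rows).
#' @param background A `background_set` (see [sample_background()]).
#' @return List of folds, each with integer index vectors `train_p`,
#'   `test_p`, `train_b`, `test_b`.
#' @export
partition_occurrences <- function(points, background) {
  n <- nrow(points)
  stopifnot(n >= 3)
  if (n < 20) {
    all_b <- seq_len(nrow(background$xy))
    return(lapply(seq_len(n), function(i)
      list(train_p = setdiff(seq_len(n), i), test_p = i,
           train_b = all_b, test_b = all_b)))
  }
  mlon <- stats::median(points$lon); mlat <- stats::median(points$lat)
  block_of <- function(lon, lat)
    1L + (lon > mlon) + 2L * (lat > mlat)
  pb <- block_of(points$lon, points$lat)
  bb <- block_of(background$xy$lon, background$xy$lat)
  for (blk in 1:4) {
    if (!any(pb == blk)) {
      cent <- vapply(1:4, function(b)
        if (any(pb == b)) mean(points$lon[pb == b]) else Inf, 0)
      near <- which.min(abs(cent - mean(background$xy$lon[bb == blk])))
      warning("presence block ", blk, " empty; merged into block ", near)
      bb[bb == blk] <- near
      pb[pb == blk] <- near
    }
  }
  blocks <- sort(unique(pb))
  lapply(blocks, function(blk)
    list(train_p = which(pb != blk), test_p = which(pb == blk),
         train_b = which(bb != blk), test_b = which(bb == blk)))
}

#' Evaluate one settings combination by cross-validation
#'
#' Per fold: fit on the training presences and background, take the
#' minimum-training-presence (MTP) threshold as the lowest prediction over
#' training presences, count the fraction of test presences strictly below
#' it (OR_MTP), and compute training and test AUC against the fold's
#' background; metrics are averaged over folds.
#'
#' @param pres_env Covariate matrix at the species' presences.
#' @param background A `background_set` with `env` attached.
#' @param settings List/row with `fc`, `rm`.
#' @param folds Folds from [partition_occurrences()].
#' @param ... Passed to [fit_presence_background()].
#' @return List of class `eval_metrics`: `or_mtp`, `auc_test`, `auc_diff`,
#'   `n_folds`.
#' @export
evaluate_settings <- function(pres_env, background, settings, folds, ...) {
  or <- at <- ad <- numeric(0)
  for (f in folds) {
    m <- tryCatch(
      fit_presence_background(pres_env[f$train_p, , drop = FALSE],
                              background$env[f$train_b, , drop = FALSE],
                              settings, ...),
      error = function(e) NULL)
    if (is.null(m)) {
      warning(sprintf("fold fit failed (fc=%s, rm=%g); fold skipped",
                      settings$fc, settings$rm))
      next
    }
    p_tr <- predict(m, pres_env[f$train_p, , drop = FALSE])
    p_te <- predict(m, pres_env[f$test_p, , drop = FALSE])
    b_tr <- predict(m, background$env[f$train_b, , drop = FALSE])
    b_te <- predict(m, background$env[f$test_b, , drop = FALSE])
    mtp <- min(p_tr)
    or <- c(or, mean(p_te < mtp))
    a_tr <- auc(p_tr, b_tr); a_te <- auc(p_te, b_te)
    at <- c(at, a_te)
    ad <- c(ad, a_tr - a_te)
  }
  if (!length(or)) stop("no fold could be evaluated")
  structure(list(or_mtp = mean(or), auc_test = mean(at), auc_diff = mean(ad),
                 n_folds = length(or)),
            class = "eval_metrics")
}

#' Sequential selection of the best model settings
#'
#' Candidates with test AUC above the filter (default 0.6) are compared
#' sequentially: minimum OR_MTP, then minimum AUC_DIFF, then maximum
#' AUC_TEST. Remaining ties prefer the simpler feature-class combination
#' (order H, Q, L, QH, LQ, LQH) and then the larger regularization
#' multiplier, so selection is deterministic and order-independent. If no
#' candidate passes the filter the full set is used with a warning.
#'
#' @param metrics Data frame with columns `fc`, `rm`, `or_mtp`, `auc_diff`,
#'   `auc_test` (one row per candidate).
#' @param auc_filter Test-AUC filter threshold.
#' @return The selected row of `metrics`.
#' @export
select_model <- function(metrics, auc_filter = 0.6) {
  stopifnot(nrow(metrics) >= 1)
  keep <- metrics$auc_test > auc_filter
  if (!any(keep)) {
    warning("no candidate exceeds AUC_TEST ", auc_filter,
            "; selecting from the full set")
    keep <- rep(TRUE, nrow(metrics))
  }
  cand <- metrics[keep, , drop = FALSE]
  fc_rank <- match(cand$fc, c("H", "Q", "L", "QH", "LQ", "LQH"))
  ord <- order(cand$or_mtp, cand$auc_diff, -cand$auc_test, fc_rank, -cand$rm)
  cand[ord[1], , drop = FALSE]
}

#' Tune a species' model over the settings grid
#'
#' Evaluates every feature-class / regularization combination by
#' cross-validation (sharing folds, with warm starts along the
#' regularization path within each feature class) and applies
#' [select_model()].
#'
#' @param points Data frame with `lon`, `lat` for one species.
#' @param background A `background_set` with `env`.
#' @param env An [env_stack()] used to extract presence covariates.
#' @param grid_settings Candidate settings from [settings_grid()].
#' @param auc_filter Passed to [select_model()].
#' @param ... Passed to [fit_presence_background()].
#' @return List with `metrics` (data frame over candidates), `selected`
#'   (the winning row) and `model` (final fit on all presences).
#' @export
tune_sdm <- function(points, background, env,
                     grid_settings = settings_grid(), auc_filter = 0.6, ...) {
  pres_env <- extract_env(env, points$lon, points$lat)
  ok <- stats::complete.cases(pres_env)
  pres_env <- pres_env[ok, , drop = FALSE]
  pts <- points[ok, , drop = FALSE]
  folds <- partition_occurrences(pts, background)
  metrics <- evaluate_grid(pres_env, background, grid_settings, folds, ...)
  sel <- select_model(metrics, auc_filter)
  model <- fit_presence_background(
    pres_env, background$env, sel,
    background_cells = paste(background$xy$row, background$xy$col), ...)
  list(metrics = metrics, selected = sel, model = model)
}

# Evaluate the whole settings grid: within each feature class the design is
# built once per fold and fits are warm-started along the decreasing
# regularization path, which gives the same estimates as independent fits
# far faster.
evaluate_grid <- function(pres_env, background, grid_settings, folds,
                          categorical = character(0),
                          base_penalty = base_penalty_default,
                          n_hinge_knots = 10) {
  res <- list()
  for (fc in unique(grid_settings$fc)) {
    rms <- sort(grid_settings$rm[grid_settings$fc == fc], decreasing = TRUE)
    or <- at <- ad <- matrix(NA_real_, length(rms), length(folds))
    spec <- feature_spec(fc, n_hinge_knots)
    bg_cells <- paste(background$xy$row, background$xy$col)
    for (fi in seq_along(folds)) {
      f <- folds[[fi]]
      Xp_cov <- pres_env[f$train_p, , drop = FALSE]
      Xb_cov <- background$env[f$train_b, , drop = FALSE]
      X <- build_features(rbind(Xp_cov, Xb_cov), spec, categorical)
      def <- attr(X, "def")
      Xp <- X[seq_len(nrow(Xp_cov)), , drop = FALSE]
      Xb <- X[-seq_len(nrow(Xp_cov)), , drop = FALSE]
      tr_cl <- collapse_rows(Xb, bg_cells[f$train_b])
      te_cl <- collapse_rows(background$env[f$test_b, , drop = FALSE],
                             bg_cells[f$test_b])
      beta0 <- NULL
      Xb_fit <- rbind(tr_cl$X, Xp)        # presences join the background
      cb_fit <- c(tr_cl$counts, rep(1, nrow(Xp)))
      for (ri in seq_along(rms)) {
        m <- tryCatch(
          pb_fit_design(Xp, Xb_fit, def, fc, rms[ri], base_penalty, beta0,
                        cb = cb_fit),
          error = function(e) NULL)
        if (is.null(m)) {
          warning(sprintf("fold fit failed (fc=%s, rm=%g); fold skipped",
                          fc, rms[ri]))
          next
        }
        beta0 <- m$beta
        p_tr <- predict(m, pres_env[f$train_p, , drop = FALSE])
        p_te <- predict(m, pres_env[f$test_p, , drop = FALSE])
        b_tr <- rep(predict_design(m, tr_cl$X), tr_cl$counts)
        b_te <- rep(predict(m, te_cl$X), te_cl$counts)
        mtp <- min(p_tr)
        or[ri, fi] <- mean(p_te < mtp)
        a_tr <- auc(p_tr, b_tr); a_te <- auc(p_te, b_te)
        at[ri, fi] <- a_te
        ad[ri, fi] <- a_tr - a_te
      }
    }
    for (ri in seq_along(rms)) {
      ok <- !is.na(or[ri, ])
      if (!any(ok)) next
      res[[length(res) + 1L]] <-
        data.frame(fc = fc, rm = rms[ri], or_mtp = mean(or[ri, ok]),
                   auc_diff = mean(ad[ri, ok]), auc_test = mean(at[ri, ok]),
                   n_folds = sum(ok), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, res)
}
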