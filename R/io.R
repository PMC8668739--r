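# Readers, writers and the end-to-end pipeline runner. Coordinates are
# geographic degrees with cell-centre semantics on north-up grids; cell
# membership is half-open (shared edges belong to the south-east cell).

#' Read an occurrence table
#'
#' CSV with header `species,lon,lat`. Rows with out-of-range coordinates
#' are rejected with a message; exact duplicate points are retained.
#'
#' @param path CSV file path.
#' @return Data frame with `species`, `lon`, `lat`.
#' @export
read_occurrences <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "lon", "lat")
  if (!all(need %in% names(df)))
    stop("occurrence file must have columns species, lon, lat; found: ",
         paste(names(df), collapse = ", "))
  if (nrow(df) == 0) stop("occurrence file is empty")
  df$species <- trimws(df$species)
  if (!is.numeric(df$lon) || !is.numeric(df$lat))
    stop("lon and lat must be numeric")
  bad <- df$lat < -90 | df$lat > 90 | df$lon < -180 | df$lon > 360 |
    is.na(df$lon) | is.na(df$lat)
  if (any(bad)) {
    message("dropping ", sum(bad), " row(s) with invalid coordinates")
    df <- df[!bad, , drop = FALSE]
  }
  df[, need]
}

#' Read a rooted Newick tree
#'
#' @param path Newick file path.
#' @return A rooted `phylo` object with branch lengths.
#' @export
read_tree <- function(path) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse Newick file: ", path)
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths: ", path)
  if (!ape::is.rooted(tree))
    stop("tree is not rooted: ", path)
  tree
}

#' Write / read a presence-absence matrix as CSV
#'
#' Interchange format between the rasterization and index layers: one row
#' per coarse cell (`cell`, `row`, `col`, `lon`, `lat`), one column per
#' species.
#'
#' @param pam A [pa_matrix()].
#' @param path CSV path.
#' @export
write_pam_csv <- function(pam, path) {
  utils::write.csv(cbind(pam$coords, as.data.frame(pam$mat)), path,
                   row.names = FALSE)
}

#' @rdname write_pam_csv
#' @param grid The coarse [grid_spec()] (stored alongside, not in the CSV).
#' @return For `read_pam_csv`, the reconstructed [pa_matrix()].
#' @export
read_pam_csv <- function(path, grid) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  meta <- c("cell", "row", "col", "lon", "lat")
  spp <- setdiff(names(df), meta)
  mat <- as.matrix(df[, spp, drop = FALSE])
  pa_matrix(mat, df[, meta], grid)
}

#' Pipeline configuration
#'
#' @param n_background Background draws per model.
#' @param grid_settings Candidate SDM settings (see [settings_grid()]).
#' @param auc_filter Test-AUC filter for model selection.
#' @param factor Fine-to-coarse aggregation factor.
#' @param n_null Null-model replicates.
#' @param k_clusters UPGMA bioregion count.
#' @param point_fallback Character vector of species for which raw presence
#'   points are used instead of model predictions.
#' @param region Optional WKT polygon (or vertex matrix) to crop to.
#' @param seed Integer master seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(n_background = 10000,
                            grid_settings = settings_grid(),
                            auc_filter = 0.6, factor = 4, n_null = 999,
                            k_clusters = 4, point_fallback = character(0),
                            region = NULL, seed = 1L) {
  structure(list(n_background = n_background, grid_settings = grid_settings,
                 auc_filter = auc_filter, factor = factor, n_null = n_null,
                 k_clusters = k_clusters, point_fallback = point_fallback,
                 region = region, seed = seed),
            class = "pipeline_config")
}

#' Run the full pipeline
#'
#' Bias layer from pooled occurrences, per-species model tuning and
#' selection, suitability prediction, max-aggregation, maxSSS thresholding
#' and binarization (or raw-point fallback), optional region cropping,
#' per-cell indices with curveball null percentiles, pairwise turnover,
#' UPGMA bioregions and PCoA colour maps. Species whose model fitting
#' fails degrade to the point fallback with a warning rather than aborting
#' the community analysis.
#'
#' @param occurrences Data frame `species`, `lon`, `lat` (all species).
#' @param env An [env_stack()] of predictors.
#' @param tree Rooted `phylo`; tips must cover the species labels.
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory: CSV/Newick/ASCII-grid outputs and a
#'   JSON manifest are written there.
#' @return List with `bias`, `species` (per-species tuning results),
#'   `metrics` (Table-2-like data frame), `pam`, `indices`, `dissim_simpson`,
#'   `dissim_phylosor`, `clusters`, `rgb`, `config`.
#' @export
run_pipeline <- function(occurrences, env, tree, config = pipeline_config(),
                         out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  spp <- sort(unique(occurrences$species))
  missing_tips <- setdiff(spp, tree$tip.label)
  if (length(missing_tips))
    stop("species absent from the tree: ", paste(missing_tips, collapse = ", "))
  seeds <- child_seeds(config$seed, length(spp) + 3L)
  grid <- env$grid
  coarse <- coarsen_grid(grid, config$factor)

  message("fitting bias layer from ", nrow(occurrences), " pooled points")
  bias <- make_bias_layer(occurrences, env, n_background = config$n_background,
                          seed = seeds[1])
  background <- sample_background(bias, grid, n = config$n_background,
                                  seed = seeds[2], env = env)

  binary <- list(); tuned <- list(); metrics <- list()
  for (i in seq_along(spp)) {
    sp <- spp[i]
    pts <- occurrences[occurrences$species == sp, , drop = FALSE]
    use_points <- sp %in% config$point_fallback
    fit <- NULL
    if (!use_points) {
      fit <- tryCatch(
        tune_sdm(pts, background, env, config$grid_settings,
                 config$auc_filter),
        error = function(e) {
          warning("species ", sp, ": model fitting failed (", e$message,
                  "); falling back to presence points")
          NULL
        })
      if (is.null(fit)) use_points <- TRUE
      # a fully penalized model (no nonzero coefficient) predicts a constant
      # map, i.e. the species everywhere — the overprediction failure mode;
      # raw presence locations are used instead
      if (!use_points && all(fit$model$beta == 0)) {
        message(sp, ": selected model is constant (no environmental signal)",
                "; using presence points")
        use_points <- TRUE
      }
    }
    if (use_points) {
      binary[[sp]] <- points_to_binary(pts, coarse)
      metrics[[sp]] <- data.frame(species = sp, n = nrow(pts), fc = NA,
                                  rm = NA, or_mtp = NA, auc_diff = NA,
                                  auc_test = NA, fallback = TRUE,
                                  stringsAsFactors = FALSE)
      message(sp, ": presence points used directly (", nrow(pts), " points)")
      next
    }
    tuned[[sp]] <- fit
    suit <- predict(fit$model, env)
    suit_coarse <- aggregate_max(suit, config$factor)
    rc <- cell_of_point(coarse, pts$lon, pts$lat)
    pres_scores <- suit_coarse[cbind(rc$row, rc$col)]
    bg_rc <- cell_of_point(coarse, background$xy$lon, background$xy$lat)
    bg_scores <- suit_coarse[cbind(bg_rc$row, bg_rc$col)]
    thr <- threshold_maxsss(pres_scores[!is.na(pres_scores)],
                            bg_scores[!is.na(bg_scores)])
    binary[[sp]] <- binarize(suit_coarse, thr)
    sel <- fit$selected
    metrics[[sp]] <- data.frame(species = sp, n = nrow(pts), fc = sel$fc,
                                rm = sel$rm, or_mtp = sel$or_mtp,
                                auc_diff = sel$auc_diff,
                                auc_test = sel$auc_test, fallback = FALSE,
                                stringsAsFactors = FALSE)
    message(sprintf("%s: n=%d fc=%s rm=%.1f OR_MTP=%.3f AUC_TEST=%.3f",
                    sp, nrow(pts), sel$fc, sel$rm, sel$or_mtp, sel$auc_test))
  }
  metrics <- do.call(rbind, c(metrics, list(make.row.names = FALSE)))

  pam <- build_pam(binary, coarse)
  if (!is.null(config$region)) pam <- crop_to_region(pam, config$region)
  indices <- cell_indices(tree, pam, n_null = config$n_null, seed = seeds[3])

  occ_pam <- drop_empty_cells(pam)
  d_sim <- simpson_dissimilarity(occ_pam)
  d_phy <- phylosor_turnover(tree, occ_pam)
  clusters <- upgma_cluster(d_sim, k = min(config$k_clusters, nrow(d_sim)))
  rgb <- pcoa_rgb(d_sim)

  out <- list(bias = bias, species = tuned, metrics = metrics, pam = pam,
              indices = indices, dissim_simpson = d_sim,
              dissim_phylosor = d_phy, clusters = clusters, rgb = rgb,
              config = config)
  if (!is.null(out_dir)) write_pipeline_outputs(out, env, out_dir)
  out
}

write_pipeline_outputs <- function(out, env, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out_dir, ...)
  write_asc(out$bias, env$grid, p("bias.asc"))
  utils::write.csv(out$metrics, p("model_metrics.csv"), row.names = FALSE)
  write_pam_csv(out$pam, p("pam.csv"))
  utils::write.csv(out$indices, p("cell_indices.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(out$dissim_simpson), p("dissim_simpson.csv"))
  utils::write.csv(as.data.frame(out$dissim_phylosor),
                   p("dissim_phylosor.csv"))
  utils::write.csv(data.frame(cell = names(out$clusters$cluster),
                              cluster = as.integer(out$clusters$cluster)),
                   p("clusters.csv"), row.names = FALSE)
  utils::write.csv(out$rgb, p("rgb.csv"), row.names = FALSE)
  dend <- ape::as.phylo(out$clusters$dendrogram)
  ape::write.tree(dend, p("upgma_dendrogram.nwk"))
  manifest <- list(seed = out$config$seed,
                   n_background = out$config$n_background,
                   factor = out$config$factor, n_null = out$config$n_null,
                   k_clusters = out$config$k_clusters,
                   n_species = ncol(out$pam$mat),
                   n_cells = nrow(out$pam$mat))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(out_dir)
}
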