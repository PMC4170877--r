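#' Pipeline configuration
#'
#' Collects the knobs of the full validation pipeline. `mode` selects the
#' input: `"synthetic"` (built-in generator), `"matrix"` (feature-matrix
#' CSV at `input`), or `"features"` (long raw-signal CSV at `input` with
#' columns `subject`, `condition`, `value`, processed by
#' [build_feature_matrix()]).
#'
#' @param mode Input mode.
#' @param input Input CSV path (modes `matrix` / `features`).
#' @param out_dir Output directory (created if missing).
#' @param R Bootstrap replicates (default 1000).
#' @param alpha Polygon trim level in `[0, 1)` (default 0: hulls of all
#'   replicate points, on which untypical observations are easiest to see).
#' @param m `"auto"` (use the non-overlap criterion, floored at 2 so the
#'   principal plane can be drawn) or an integer number of dimensions.
#' @param seed Master seed; every random draw in the run flows from it.
#' @param fs Sampling rate for mode `features`.
#' @param n_subjects,beta_theta_contrast Generator settings for mode
#'   `synthetic`, see [synth_feature_matrix()].
#' @param min_epochs,reject_k Epoching settings for mode `features`.
#' @return A validated list of class `pb_config`.
#' @export
pb_config <- function(mode = c("synthetic", "matrix", "features"),
                      input = NULL, out_dir = tempfile("pcboot-run-"),
                      R = 1000, alpha = 0, m = "auto", seed = 1, fs = 400,
                      n_subjects = 24, beta_theta_contrast = 0,
                      min_epochs = 150, reject_k = Inf) {
  mode <- match.arg(mode)
  if (mode != "synthetic" && (is.null(input) || !file.exists(input))) {
    abort(sprintf("Mode '%s' needs an existing `input` file.", mode))
  }
  if (R < 1) abort("`R` must be >= 1.")
  if (alpha < 0 || alpha >= 1) abort("`alpha` must be in [0, 1).")
  if (!identical(m, "auto") && (!is.numeric(m) || m < 1)) {
    abort("`m` must be \"auto\" or an integer >= 1.")
  }
  structure(list(mode = mode, input = input, out_dir = out_dir, R = as.integer(R),
                 alpha = alpha, m = m, seed = as.integer(seed), fs = fs,
                 n_subjects = n_subjects,
                 beta_theta_contrast = beta_theta_contrast,
                 min_epochs = min_epochs, reject_k = reject_k),
            class = "pb_config")
}

#' Run the full partial-bootstrap validation pipeline
#'
#' Features (or a ready feature matrix) -> correlation-matrix PCA ->
#' partial bootstrap (replicate eigenvalues + projected score cloud) ->
#' per-object confidence polygons and centroids -> dimensionality report ->
#' UPGMA dendrograms of the original scores and of the bootstrap centroids,
#' with their partition agreement. All artifacts are written to
#' `cfg$out_dir` as plain text; reruns with the same config and seed
#' produce byte-identical files.
#'
#' Files written: `feature_matrix.csv`, `model.json`, `scores.csv`,
#' `eigenvalue_replicates.csv`, `eigenvalue_ci.csv`, `cloud.csv`,
#' `polygons.csv`, `polygon_vertices.json`, `centroids.csv`,
#' `dimensionality.json`, `dendrogram_scores.nwk`,
#' `dendrogram_centroids.nwk`, `partition_comparison.csv`, `run_log.txt`.
#'
#' @param cfg A [pb_config()].
#' @return Invisibly, a list with the in-memory results (`data`, `fit`,
#'   `plan`, `eigen`, `dimensionality`, `cloud`, `polygons`, `centroids`,
#'   `dendro_scores`, `dendro_centroids`, `comparison`, `m_used`, `paths`).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pb_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- function(f) file.path(cfg$out_dir, f)

  data <- switch(cfg$mode,
    synthetic = synth_feature_matrix(n_subjects = cfg$n_subjects,
                                     beta_theta_contrast = cfg$beta_theta_contrast,
                                     seed = cfg$seed),
    matrix = read_feature_matrix(cfg$input),
    features = {
      signals <- readr::read_csv(cfg$input, show_col_types = FALSE, progress = FALSE)
      build_feature_matrix(signals, fs = cfg$fs, min_epochs = cfg$min_epochs,
                           reject_k = cfg$reject_k)
    }
  )
  write_feature_matrix(data, path("feature_matrix.csv"))

  fit <- fit_pca(data)
  write_pca_json(fit, path("model.json"))
  readr::write_csv(tidy(fit, "scores"), path("scores.csv"))

  plan <- resample_plan(nrow(data), cfg$R, seed = cfg$seed + 1L)
  eig <- bootstrap_eigenvalues(data, plan)
  dim_rep <- nonoverlap_dimension(eig, fit = fit)
  readr::write_csv(tidy(eig), path("eigenvalue_replicates.csv"))
  readr::write_csv(eigenvalue_bands(eig, alpha = 0), path("eigenvalue_ci.csv"))
  jsonlite::write_json(
    list(m_star = dim_rep$m_star, n_separated = dim_rep$n_separated,
         explained_at_m = dim_rep$explained_at_m,
         gap_table = dim_rep$gap_table, scree = scree_table(fit)),
    path("dimensionality.json"), digits = NA, auto_unbox = TRUE, dataframe = "columns"
  )

  # the plane needs 2 dims even when only 1 axis is retained
  m_used <- if (identical(cfg$m, "auto")) max(2L, dim_rep$m_star) else as.integer(cfg$m)
  m_used <- min(m_used, fit$p)
  cloud <- bootstrap_scores(data, fit, plan, m = m_used)
  readr::write_csv(tibble::as_tibble(cloud), path("cloud.csv"))

  polys <- confidence_polygons(cloud, alpha = cfg$alpha)
  readr::write_csv(
    dplyr::select(tibble::as_tibble(polys), -"vertices"),
    path("polygons.csv")
  )
  jsonlite::write_json(
    purrr::map(setNames(polys$vertices, polys$object_id),
               ~ as.data.frame(.x)),
    path("polygon_vertices.json"), digits = NA, dataframe = "columns"
  )
  centroids <- polygon_centroids(polys)
  readr::write_csv(centroids, path("centroids.csv"))

  scores2 <- dplyr::select(tidy(fit, "scores"), "object_id", "PC1", "PC2")
  den_s <- average_linkage(scores2)
  den_c <- average_linkage(centroids)
  as_newick(den_s, path("dendrogram_scores.nwk"))
  as_newick(den_c, path("dendrogram_centroids.nwk"))
  cut_s <- suggest_cut(den_s)
  cut_c <- suggest_cut(den_c)
  part_s <- cut_tree(den_s, cut_s)
  part_c <- cut_tree(den_c, cut_c)
  cmp <- compare_partitions(part_s, part_c)
  readr::write_csv(
    tibble::tibble(
      cut_scores = cut_s, cut_centroids = cut_c,
      clusters_scores = length(unique(part_s$cluster)),
      clusters_centroids = length(unique(part_c$cluster)),
      rand = cmp$rand, adjusted_rand = cmp$adjusted_rand
    ),
    path("partition_comparison.csv")
  )

  writeLines(c(
    sprintf("mode: %s", cfg$mode),
    sprintf("seed: %d", cfg$seed),
    sprintf("n: %d  p: %d", fit$n, fit$p),
    sprintf("R requested: %d  R effective: %d", cfg$R, eig$R_effective),
    sprintf("alpha: %g", cfg$alpha),
    sprintf("m_star: %d  (leading separated ranks: %d)", dim_rep$m_star, dim_rep$n_separated),
    sprintf("m used for the plane: %d%s", m_used,
            if (identical(cfg$m, "auto") && dim_rep$m_star < 2)
              "  [dim 2 drawn but not retained]" else ""),
    sprintf("explained variance at m_star: %.4f%%", dim_rep$explained_at_m)
  ), path("run_log.txt"))

  invisible(list(data = data, fit = fit, plan = plan, eigen = eig,
                 dimensionality = dim_rep, cloud = cloud, polygons = polys,
                 centroids = centroids, dendro_scores = den_s,
                 dendro_centroids = den_c, comparison = cmp,
                 m_used = m_used, paths = cfg$out_dir))
}
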