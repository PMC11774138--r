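#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end analysis with the survey
#' defaults: 2500 stratified points, 1 cm and 50 cm rugosity resolutions,
#' 10 transects per direction, k = 3 complete-linkage clusters, 9999
#' permutations. The resolved configuration is written next to the outputs
#' of every run.
#'
#' @param n_points Annotation points per plot.
#' @param categories Benthic category set.
#' @param resolutions Rugosity sampling resolutions (m).
#' @param n_transects Transects per direction.
#' @param k,linkage Clustering cut and linkage.
#' @param n_permutations Permutations for ANOSIM/PERMANOVA/Mantel.
#' @param seed Root seed; all stage seeds are fanned out from it.
#' @param n_islands,sites_per_island,spatial_range_km Region layout.
#' @param survey_dates Survey dates.
#' @param standardize_columns Columns min-max standardized in the feature
#'   matrix.
#' @param ... Additional overrides stored as-is.
#' @return A `reef_config` list.
#' @export
reef_config <- function(n_points = 2500, categories = benthic_categories(),
                        resolutions = c(0.01, 0.5), n_transects = 10,
                        k = 3, linkage = "complete",
                        n_permutations = 9999, seed = 1,
                        n_islands = 4, sites_per_island = 9,
                        spatial_range_km = 5,
                        survey_dates = as.Date(c("2017-07-01", "2019-07-01",
                                                 "2021-07-01", "2023-07-01")),
                        standardize_columns = c("heterogeneity",
                                                "rugosity_1cm",
                                                "rugosity_50cm",
                                                "fractal_dimension"),
                        ...) {
  cfg <- c(as.list(environment()), list(...))
  class(cfg) <- "reef_config"
  cfg
}

#' Run the analysis pipeline end-to-end
#'
#' Chains the stages in dependency order: `simulate` (synthetic region) ->
#' `annotate`/`metrics` (computed during simulation) -> `features`
#' (feature matrix + Bray-Curtis) -> `cluster`, `ordinate`, `test`
#' (ANOSIM by cluster and island, PERMANOVA, Mantel correlogram) ->
#' `trajectory` (rates, transitions, group comparison). Every stage seeds
#' its randomness from the root seed, so a rerun with the same
#' configuration is identical; artifacts (CSV/JSON) are written under
#' `out_dir` when given.
#'
#' @param config A [reef_config()].
#' @param stages Subset of
#'   `c("simulate", "features", "cluster", "ordinate", "test", "trajectory")`;
#'   earlier stages required by a requested stage are run automatically.
#' @param out_dir Optional artifact directory.
#' @param region Optional pre-generated `reef_region` (skips `simulate`).
#' @param verbose Print progress.
#' @return A `reef_pipeline` list with the region, feature matrix,
#'   distance matrix, clustering, ordination, test results, and trajectory
#'   summaries for the stages run.
#' @export
run_reef_pipeline <- function(config = reef_config(),
                              stages = c("simulate", "features", "cluster",
                                         "ordinate", "test", "trajectory"),
                              out_dir = NULL, region = NULL,
                              verbose = FALSE) {
  known <- c("simulate", "features", "cluster", "ordinate", "test",
             "trajectory")
  bad <- setdiff(stages, known)
  if (length(bad))
    stop("unknown stage(s): ", paste(bad, collapse = ", "),
         "; valid stages: ", paste(known, collapse = ", "), call. = FALSE)
  # dependency closure: everything up to the latest requested stage
  need <- known[seq_len(max(match(stages, known)))]
  res <- list(config = config)
  seed <- config$seed

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    cfg_out <- config
    cfg_out$survey_dates <- format(cfg_out$survey_dates)
    jsonlite::write_json(unclass(cfg_out),
                         file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, force = TRUE, digits = NA)
  }

  if (is.null(region) && "simulate" %in% need) {
    if (verbose) message("simulate: generating region")
    region <- generate_region(
      n_islands = config$n_islands,
      sites_per_island = config$sites_per_island,
      spatial_range_km = config$spatial_range_km,
      seed = .child_seed(seed, 1L), survey_dates = config$survey_dates,
      n_points = config$n_points, n_transects = config$n_transects,
      verbose = verbose)
  }
  res$region <- region
  obs <- region$observations

  if ("features" %in% need) {
    fm <- feature_matrix(obs, cover_columns = intersect(config$categories,
                                                        names(obs)))
    d <- bray_curtis(fm)
    obs_id <- paste(obs$site_id, format(obs$survey_date), sep = "|")
    dimnames(d) <- list(obs_id, obs_id)
    res$features <- fm
    res$distance <- d
    if (!is.null(out_dir)) {
      utils::write.csv(as.data.frame(fm),
                       file.path(out_dir, "feature_matrix.csv"),
                       row.names = FALSE)
      write_distance_csv(d, file.path(out_dir, "bray_curtis.csv"))
    }
  }

  if ("cluster" %in% need) {
    res$regimes <- hierarchical_cluster(res$distance,
                                        linkage = config$linkage,
                                        k = config$k)
    if (!is.null(out_dir)) {
      utils::write.csv(data.frame(id = rownames(res$distance),
                                  regime = res$regimes$labels),
                       file.path(out_dir, "regimes.csv"), row.names = FALSE)
      if (requireNamespace("ape", quietly = TRUE))
        write_newick(res$regimes, file.path(out_dir, "dendrogram.nwk"))
    }
  }

  if ("ordinate" %in% need) {
    res$ordination <- reef_nmds(res$distance, seed = .child_seed(seed, 2L))
    if (!is.null(out_dir))
      utils::write.csv(data.frame(id = rownames(res$distance),
                                  res$ordination$points),
                       file.path(out_dir, "nmds_coordinates.csv"),
                       row.names = FALSE)
  }

  if ("test" %in% need) {
    np <- config$n_permutations
    # a grouping level with a single observation cannot enter ANOSIM
    anosim_on <- function(groups, s) {
      keep <- groups %in% names(which(table(groups) >= 2))
      reef_anosim(res$distance[keep, keep], groups[keep],
                  n_permutations = np, seed = s)
    }
    res$anosim_cluster <- anosim_on(res$regimes$labels,
                                    .child_seed(seed, 3L))
    res$anosim_island <- anosim_on(obs$island, .child_seed(seed, 4L))
    covars <- region$sites[match(obs$site_id, region$sites$site_id), ]
    pdat <- data.frame(island = factor(obs$island),
                       irradiance = covars$irradiance,
                       wave_power = covars$wave_power)
    res$permanova <- reef_permanova(res$distance,
                                    ~ island + irradiance + wave_power,
                                    data = pdat,
                                    n_permutations = min(np, 999),
                                    scheme = "blocked_by_site",
                                    site = obs$site_id,
                                    seed = .child_seed(seed, 5L))
    # site-level autocorrelation: mean features per site
    fm <- res$features
    fv <- feature_values(fm)
    site_means <- apply(fv, 2, function(v) tapply(v, obs$site_id, mean))
    dsite <- bray_curtis(site_means)
    coords <- region$sites[match(rownames(site_means),
                                 region$sites$site_id), c("x_km", "y_km")]
    res$mantel <- mantel_correlogram(dsite, as.matrix(coords),
                                     n_permutations = min(np, 999),
                                     seed = .child_seed(seed, 6L))
    if (!is.null(out_dir)) {
      write_result_json(res$anosim_cluster,
                        file.path(out_dir, "anosim_cluster.json"), seed)
      write_result_json(res$anosim_island,
                        file.path(out_dir, "anosim_island.json"), seed)
      write_result_json(res$permanova,
                        file.path(out_dir, "permanova.json"), seed)
      write_result_json(res$mantel,
                        file.path(out_dir, "mantel_correlogram.json"), seed)
    }
  }

  if ("trajectory" %in% need) {
    res$rates <- region_rates(region)
    reg_groups <- stats::setNames(region$sites$archetype,
                                  region$sites$site_id)
    isl_groups <- stats::setNames(region$sites$island, region$sites$site_id)
    mk <- function(groups) {
      data.frame(site = res$rates$site_id,
                 group = groups[res$rates$site_id],
                 rate = res$rates$d_cover_per_month)
    }
    res$rate_regime <- group_rate_comparison(mk(reg_groups),
                                             n_permutations = min(config$n_permutations, 999),
                                             seed = .child_seed(seed, 7L))
    res$rate_island <- group_rate_comparison(mk(isl_groups),
                                             n_permutations = min(config$n_permutations, 999),
                                             seed = .child_seed(seed, 8L))
    if (!is.null(out_dir)) {
      utils::write.csv(res$rates, file.path(out_dir, "rates.csv"),
                       row.names = FALSE)
      write_result_json(res$rate_regime,
                        file.path(out_dir, "rate_regime.json"), seed)
      write_result_json(res$rate_island,
                        file.path(out_dir, "rate_island.json"), seed)
    }
  }

  class(res) <- "reef_pipeline"
  res
}

#' Per-site monthly rates of change for a region
#'
#' Total coral cover (sum of the coral categories) and 1 cm rugosity are
#' converted to monthly rates per consecutive survey pair.
#'
#' @param region A `reef_region`.
#' @return Data frame: `site_id`, `timestep`, `start_date`, `end_date`,
#'   `months`, `d_cover_per_month`, `d_rugosity_per_month`.
#' @export
region_rates <- function(region) {
  obs <- region$observations
  coral_cols <- intersect(coral_categories(), names(obs))
  out <- lapply(split(obs, obs$site_id), function(df) {
    df <- df[order(df$survey_date), ]
    coral <- rowSums(df[coral_cols])
    rc <- monthly_rate(coral, df$survey_date)
    rr <- monthly_rate(df$rugosity_1cm, df$survey_date)
    data.frame(site_id = df$site_id[1], timestep = rc$timestep,
               start_date = rc$start_date, end_date = rc$end_date,
               months = rc$months, d_cover_per_month = rc$rate,
               d_rugosity_per_month = rr$rate)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' @export
print.reef_pipeline <- function(x, ...) {
  cat("Reef pipeline results\n")
  if (!is.null(x$region)) print(x$region)
  if (!is.null(x$regimes)) print(x$regimes)
  if (!is.null(x$ordination)) print(x$ordination)
  if (!is.null(x$anosim_cluster)) {
    cat("by cluster: "); print(x$anosim_cluster)
    cat("by island:  "); print(x$anosim_island)
  }
  invisible(x)
}
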