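#' @keywords internal
.child_seed <- function(seed, k) {
  as.integer(((as.double(seed) %% 2147483647) * 48271 + as.double(k)) %%
               2147483647)
}

#' Default per-archetype monthly change rates
#'
#' Net coral-cover changes observed over the 2017-2023 series (+4.89
#' points on low-cover *Porites* reefs, -6.32 on intermediate reefs,
#' -8.81 on high-cover *Montipora* reefs, over ~72 months) converted to
#' percentage points per month and applied to each archetype's dominant
#' coral category; high-cover reefs also gain a little rugosity (+0.07
#' over the series).
#'
#' @return Named list per archetype with elements `cover` (named rates,
#'   points/month) and `rugosity` (units/month).
#' @export
default_change_rates <- function() {
  list(
    low_cover_porites = list(
      cover = c("Porites lobata" = 4.89 / 72), rugosity = 0),
    intermediate_diverse = list(
      cover = c("Porites lobata" = -6.32 / 72), rugosity = 0),
    high_cover_montipora = list(
      cover = c("Montipora capitata" = -8.81 / 72), rugosity = 0.07 / 72))
}

#' Generate a survey time series for one site
#'
#' Produces one reef plot per survey. Expected cover drifts linearly at
#' `change_rates` (percentage points per month) between surveys, the
#' residual being absorbed by a background category (turf algae, the
#' dominant non-coral space-holder) so totals stay at 100; drift that
#' would push a category negative is clamped at 0 with a warning. The
#' depth surface is shared across surveys, recalibrated when
#' `rugosity_rate` is nonzero. Small per-survey cover jitter
#' (`survey_jitter_sd`) represents annotation-independent fine change.
#'
#' @param profile An [archetype_profile()].
#' @param spec A [plot_spec()] (survey_date is overwritten per survey).
#' @param survey_dates Dates, strictly increasing, length >= 2.
#' @param change_rates Named numeric, percentage points per month (missing
#'   categories drift at 0).
#' @param seed Integer seed.
#' @param rugosity_rate Rugosity units per month (default 0).
#' @param background Category absorbing drift residuals.
#' @param survey_jitter_sd Per-survey cover jitter (points), default 0.3.
#' @param cell_size Label raster cell (m).
#' @param depth_cell Depth grid cell (m).
#' @param site_jitter If `TRUE` (default) the site's baseline cover and
#'   rugosity target are jittered around the archetype values.
#' @return List of [reef_plot()]s, one per survey, each carrying its label
#'   field and depth surface.
#' @export
generate_site_timeseries <- function(profile, spec, survey_dates,
                                     change_rates = NULL, seed = 1,
                                     rugosity_rate = 0,
                                     background = "turf algae",
                                     survey_jitter_sd = 0.3,
                                     cell_size = 0.01, depth_cell = 0.01,
                                     site_jitter = TRUE) {
  survey_dates <- as.Date(survey_dates)
  if (length(survey_dates) < 2) stop("need >= 2 surveys", call. = FALSE)
  if (any(diff(survey_dates) <= 0))
    stop("survey dates must be strictly increasing", call. = FALSE)
  cats <- names(profile$mean_cover)
  if (!background %in% cats)
    stop("background category not in the profile", call. = FALSE)
  rates <- stats::setNames(rep(0, length(cats)), cats)
  if (!is.null(change_rates)) {
    unknown <- setdiff(names(change_rates), cats)
    if (length(unknown)) stop("unknown categories in change_rates: ",
                              paste(unknown, collapse = ", "), call. = FALSE)
    rates[names(change_rates)] <- change_rates
  }

  set.seed(.child_seed(seed, 1L))
  base <- if (site_jitter) .jitter_cover(profile$mean_cover, profile$cover_sd)
          else profile$mean_cover
  rug0 <- if (site_jitter)
    max(1, profile$rugosity_target + stats::rnorm(1, 0, 0.05))
  else profile$rugosity_target

  surf0 <- generate_depth_surface(spec, hurst = profile$hurst, amplitude = 1,
                                  cell_size = depth_cell,
                                  seed = .child_seed(seed, 2L))
  months <- as.numeric(survey_dates - survey_dates[1]) / 30.4375

  out <- vector("list", length(survey_dates))
  for (t in seq_along(survey_dates)) {
    target <- base + rates * months[t]
    if (any(target < 0)) {
      warning("drift clamped at 0 for: ",
              paste(cats[target < 0], collapse = ", "))
      target <- pmax(target, 0)
    }
    if (survey_jitter_sd > 0 && t > 1) {
      set.seed(.child_seed(seed, 100L + t))
      z <- pmax(pmin(stats::rnorm(length(target)), 2), -2)
      target <- pmax(target + survey_jitter_sd * z, 0)
    }
    resid <- 100 - sum(target[cats != background])
    if (resid < 0) {
      target[cats != background] <-
        target[cats != background] * 100 / sum(target[cats != background])
      target[background] <- 0
    } else target[background] <- resid

    spec_t <- spec
    spec_t$survey_date <- survey_dates[t]
    field <- generate_label_field(profile, spec_t,
                                  seed = .child_seed(seed, 200L + t),
                                  cell_size = cell_size,
                                  target_cover = target)
    rug_t <- max(1, rug0 + rugosity_rate * months[t])
    surface <- calibrate_rugosity(surf0, rug_t,
                                  resolution = max(0.01, depth_cell))
    surface$spec <- spec_t
    out[[t]] <- reef_plot(spec_t, field = field, surface = surface,
                          metadata = list(archetype = profile$name,
                                          rugosity_target = rug_t,
                                          target_cover = target))
  }
  out
}

.default_mix <- function(islands) {
  arch <- c("low_cover_porites", "intermediate_diverse",
            "high_cover_montipora")
  base <- rbind(c(0.60, 0.30, 0.10),   # Kaho'olawe-like
                c(0.05, 0.35, 0.60),   # Lana'i-like
                c(0.65, 0.30, 0.05),   # Maui-like
                c(0.05, 0.30, 0.65))   # Moloka'i-like
  m <- base[rep_len(seq_len(4), length(islands)), , drop = FALSE]
  dimnames(m) <- list(islands, arch)
  m
}

.island_covariates <- function(island_idx) {
  # island contrasts kept small relative to the within-island spread so
  # the induced pairwise correlations stay comfortably below |0.54|
  means <- list(depth_m = c(10, 10, 10, 10),
                wave_power = c(9, 7, 11, 8),
                sst_sd = c(0.62, 0.56, 0.66, 0.58),
                chl_a = c(0.13, 0.11, 0.18, 0.14),
                irradiance = c(40.5, 40, 37, 38.5),
                sediment_export = c(0.6, 0.4, 1.2, 0.8),
                effluent = c(4, 3, 11, 7))
  sds <- c(depth_m = 0.8, wave_power = 3, sst_sd = 0.07, chl_a = 0.08,
           irradiance = 2, sediment_export = 0.5, effluent = 6)
  out <- lapply(names(means), function(v) {
    mu <- means[[v]][((island_idx - 1) %% 4) + 1]
    pmax(stats::rnorm(length(island_idx), mu, sds[[v]]), 0.01)
  })
  stats::setNames(as.data.frame(out), names(means))
}

#' Generate a multi-island survey region
#'
#' Builds the full synthetic study system: islands with clustered site
#' positions, spatially clumped archetype assignment (nearby sites share
#' archetypes more often than chance, with range `spatial_range_km`),
#' island-specific environmental covariates, and a survey time series per
#' site with per-archetype drift. Site-level metrics (percent cover from
#' stratified point annotation, Voronoi unlike-adjacency heterogeneity,
#' rugosity at both resolutions, fractal dimension) are computed as each
#' plot is generated and the large rasters are then discarded unless
#' `keep_fields = TRUE`.
#'
#' @param n_islands,sites_per_island Region size (defaults 4 x 9 = 36
#'   sites).
#' @param archetype_mix Matrix (islands x archetypes) of mixture rows
#'   summing to 1; defaults to the regional pattern (low-cover reefs
#'   concentrated on two islands, high-cover on the other two).
#' @param spatial_range_km Range of archetype clumping (default 5).
#' @param seed Integer seed.
#' @param survey_dates Survey dates (default four surveys, 2017-2023).
#' @param change_rates As [default_change_rates()].
#' @param rate_sd Between-site sd of the site drift rate (points/month).
#' @param n_points Annotation points per plot (default 2500).
#' @param cell_size,depth_cell Raster cells (m).
#' @param n_transects Transects per direction for complexity metrics.
#' @param plot_width,plot_height Plot dimensions (m).
#' @param keep_fields Keep label fields/surfaces (memory-heavy).
#' @param verbose Print progress.
#' @return A `reef_region`: `sites` (positions, island, archetype truth,
#'   covariates), `observations` (one row per site x survey with cover and
#'   metric columns), and `params`.
#' @export
generate_region <- function(n_islands = 4, sites_per_island = 9,
                            archetype_mix = NULL, spatial_range_km = 5,
                            seed = 1,
                            survey_dates = as.Date(c("2017-07-01",
                                                     "2019-07-01",
                                                     "2021-07-01",
                                                     "2023-07-01")),
                            change_rates = default_change_rates(),
                            rate_sd = 0.03, n_points = 2500,
                            cell_size = 0.01, depth_cell = 0.01,
                            n_transects = 10, plot_width = 10,
                            plot_height = 10, keep_fields = FALSE,
                            verbose = FALSE) {
  stopifnot(n_islands >= 1, sites_per_island >= 1)
  island_names <- c("Kahoolawe", "Lanai", "Maui", "Molokai")
  islands <- if (n_islands <= 4) island_names[seq_len(n_islands)]
             else c(island_names, paste0("island_", 5:n_islands))
  if (is.null(archetype_mix)) archetype_mix <- .default_mix(islands)
  if (any(abs(rowSums(archetype_mix) - 1) > 1e-9))
    stop("archetype_mix rows must sum to 1", call. = FALSE)
  arch_names <- colnames(archetype_mix)
  profiles <- lapply(arch_names, default_archetype)
  names(profiles) <- arch_names

  set.seed(.child_seed(seed, 0L))
  centers <- rbind(c(0, 0), c(25, 8), c(48, -4), c(22, 32))
  if (n_islands > 4)
    centers <- rbind(centers, matrix(stats::runif((n_islands - 4) * 2,
                                                  -20, 80), ncol = 2))
  centers <- centers[seq_len(n_islands), , drop = FALSE]

  # sites sit in within-island clumps whose spread matches the archetype
  # autocorrelation range; archetype counts per island follow the mixture
  # exactly (largest remainder) and are laid out clump-wise, so sites
  # within spatial_range_km share archetypes far more often than chance
  # while every type keeps its regional share
  clump_sd <- spatial_range_km / 4
  sites <- NULL
  for (i in seq_len(n_islands)) {
    clumps <- matrix(stats::runif(6, -10, 10), ncol = 2)
    ci <- sort(rep_len(seq_len(3), sites_per_island))
    x <- centers[i, 1] + clumps[ci, 1] +
      stats::rnorm(sites_per_island, 0, clump_sd)
    y <- centers[i, 2] + clumps[ci, 2] +
      stats::rnorm(sites_per_island, 0, clump_sd)

    mix <- archetype_mix[islands[i], ]
    raw <- mix * sites_per_island
    cnt <- floor(raw)
    rem <- sites_per_island - sum(cnt)
    if (rem > 0) {
      ord <- order(raw - cnt, decreasing = TRUE)
      cnt[ord[seq_len(rem)]] <- cnt[ord[seq_len(rem)]] + 1
    }
    # contiguous archetype blocks over clump-ordered sites; block order
    # randomized so no island always leads with the same type
    blocks <- sample(arch_names[cnt > 0])
    arch_i <- unlist(lapply(blocks, function(a) rep(a, cnt[a])))

    sites <- rbind(sites, data.frame(
      site_id = sprintf("%s_%02d", substr(islands[i], 1, 3),
                        seq_len(sites_per_island)),
      island = islands[i], x_km = x, y_km = y, archetype = arch_i,
      stringsAsFactors = FALSE))
  }
  n_sites <- nrow(sites)
  arch <- sites$archetype
  sites <- cbind(sites, .island_covariates(match(sites$island, islands)))

  obs <- list()
  plots <- if (keep_fields) list() else NULL
  for (s in seq_len(n_sites)) {
    if (verbose) message("site ", sites$site_id[s], " (", arch[s], ")")
    prof <- profiles[[arch[s]]]
    cr <- change_rates[[arch[s]]]
    set.seed(.child_seed(seed, 5000L + s))
    site_rates <- cr$cover + stats::rnorm(length(cr$cover), 0, rate_sd)
    spec <- plot_spec(plot_width, plot_height, site_id = sites$site_id[s],
                      island = sites$island[s])
    series <- generate_site_timeseries(
      prof, spec, survey_dates, change_rates = site_rates,
      seed = .child_seed(seed, 10000L + s), rugosity_rate = cr$rugosity,
      cell_size = cell_size, depth_cell = depth_cell)
    for (t in seq_along(series)) {
      pl <- series[[t]]
      pts <- stratified_random_points(pl$spec, n_points,
                                      seed = .child_seed(seed, 20000L + 101L * s + t))
      ann <- annotate_points(pts, pl$field)
      cov <- percent_cover(ann)
      tess <- voronoi_tessellate(pts, pl$spec, labels = ann$category)
      het <- unlike_adjacency_proportion(tess)$value
      res_fine <- max(0.01, depth_cell)
      cx <- complexity_metrics(pl$surface,
                               resolutions = c(res_fine, 0.5),
                               n_per_direction = n_transects,
                               fd_steps = unique(pmax(c(0.02, 0.04, 0.08,
                                                        0.16, 0.32),
                                                      2 * res_fine)))
      row <- data.frame(site_id = sites$site_id[s], island = sites$island[s],
                        survey_date = survey_dates[t], archetype = arch[s],
                        stringsAsFactors = FALSE)
      row[names(cov)] <- as.list(unname(cov))
      row$heterogeneity <- het
      row$rugosity_1cm <- cx$rugosity_1cm
      row$rugosity_50cm <- cx$rugosity_50cm
      row$fractal_dimension <- cx$fractal_dimension
      obs[[length(obs) + 1L]] <- row
      if (keep_fields) {
        pl$annotations <- ann
        plots[[length(plots) + 1L]] <- pl
      }
    }
  }
  observations <- do.call(rbind, obs)
  rownames(observations) <- NULL
  structure(list(sites = sites, observations = observations, plots = plots,
                 params = list(seed = seed, n_islands = n_islands,
                               sites_per_island = sites_per_island,
                               spatial_range_km = spatial_range_km,
                               survey_dates = survey_dates,
                               n_points = n_points,
                               archetype_mix = archetype_mix)),
            class = "reef_region")
}

#' @export
print.reef_region <- function(x, ...) {
  cat(sprintf("Reef region: %d sites on %d island(s), %d surveys (%d observations)\n",
              nrow(x$sites), length(unique(x$sites$island)),
              length(x$params$survey_dates), nrow(x$observations)))
  print(table(island = x$sites$island, archetype = x$sites$archetype))
  invisible(x)
}
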