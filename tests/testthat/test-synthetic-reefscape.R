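test_that("plot and archetype constructors enforce their invariants", {
  expect_error(plot_spec(width = 0), "positive")
  sp <- plot_spec(width = 12, height = 5, site_id = "K6")
  expect_equal(c(sp$width, sp$height), c(12, 5))

  bad <- c(a = 60, b = 30)  # sums to 90
  expect_error(archetype_profile("x", bad), "off by -10")
  expect_error(archetype_profile("x", c(a = 110, b = -10)), "negative")
  expect_error(archetype_profile("x", c(a = 100), hurst = 1.2), "hurst")

  for (nm in c("low_cover_porites", "intermediate_diverse",
               "high_cover_montipora")) {
    pr <- default_archetype(nm)
    expect_equal(sum(pr$mean_cover), 100, tolerance = 1e-9)
    expect_length(pr$mean_cover, 15)
  }
  # printed community means are honoured by the defaults
  hi <- default_archetype("high_cover_montipora")
  expect_equal(unname(hi$mean_cover["Montipora capitata"]), 48.62)
  lo <- default_archetype("low_cover_porites")
  expect_equal(unname(lo$mean_cover["turf algae"]), 53.52)
  expect_equal(unname(lo$mean_cover["Porites lobata"]), 15.23)
})

test_that("label fields conserve cover, are deterministic, and track targets", {
  f1 <- toy_field(seed = 5)
  expect_equal(sum(f1$true_cover), 100, tolerance = 1e-12)
  f2 <- toy_field(seed = 5)
  expect_identical(f1$raster, f2$raster)
  f3 <- toy_field(seed = 6)
  expect_false(identical(f1$raster, f3$raster))

  # single category covers everything
  fm <- generate_label_field(mono_profile(), small_spec(2, 2), seed = 1,
                             cell_size = 0.02)
  expect_true(all(label_at(fm, runif(50, 0, 2), runif(50, 0, 2)) == "only"))
  expect_equal(unname(fm$true_cover["only"]), 100)

  # exact targets realized to raster rounding when jitter is off
  expect_true(all(abs(f1$true_cover - c(a = 50, b = 30, c = 20)) < 0.5))
})

test_that("realized cover tracks archetype means within 2 points on average", {
  pr <- default_archetype("high_cover_montipora")
  sp <- plot_spec(5, 5)
  errs <- sapply(1:20, function(s) {
    f <- generate_label_field(pr, sp, seed = s)
    mean(abs(f$true_cover - pr$mean_cover))
  })
  expect_lt(mean(errs), 2)
  # and the dominant coral realizes within +/- 5 points of its mean
  f <- generate_label_field(pr, sp, seed = 99)
  expect_lt(abs(f$true_cover["Montipora capitata"] - 48.62), 5)
})

test_that("depth surfaces: flat case, determinism, monotone amplitude", {
  sp <- small_spec()
  flat <- generate_depth_surface(sp, amplitude = 0, seed = 1)
  expect_true(all(flat$z == flat$z[1, 1]))
  expect_error(generate_depth_surface(sp, cell_size = 10), "larger")
  expect_error(generate_depth_surface(sp, hurst = 0), "hurst")

  s1 <- generate_depth_surface(sp, hurst = 0.5, amplitude = 0.1, seed = 3,
                               cell_size = 0.02)
  s2 <- generate_depth_surface(sp, hurst = 0.5, amplitude = 0.1, seed = 3,
                               cell_size = 0.02)
  expect_identical(s1$z, s2$z)
  s3 <- generate_depth_surface(sp, hurst = 0.5, amplitude = 0.3, seed = 3,
                               cell_size = 0.02)
  expect_gte(plot_rugosity(s3, 0.02), plot_rugosity(s1, 0.02))

  cal <- calibrate_rugosity(s1, 1.8, resolution = 0.02)
  expect_equal(plot_rugosity(cal, 0.02), 1.8, tolerance = 1e-6)
})

test_that("site time series drift linearly with turf absorbing the residual", {
  pr <- toy_profile(covers = c("coral" = 50, "turf algae" = 40, "sand" = 10))
  sp <- small_spec()
  dates <- as.Date(c("2020-01-01", "2022-01-01"))
  months <- as.numeric(diff(dates)) / 30.4375

  series <- generate_site_timeseries(
    pr, sp, dates, change_rates = c("coral" = -0.25), seed = 2,
    cell_size = 0.02, depth_cell = 0.02, survey_jitter_sd = 0,
    site_jitter = FALSE)
  expect_length(series, 2)
  d_coral <- series[[2]]$field$true_cover["coral"] -
    series[[1]]$field$true_cover["coral"]
  expect_equal(unname(d_coral), -0.25 * months, tolerance = 0.2)
  # totals stay closed
  for (pl in series) expect_equal(sum(pl$field$true_cover), 100)

  # stationary series stays put up to sampling tolerance
  stat <- generate_site_timeseries(pr, sp, dates, seed = 3,
                                   cell_size = 0.02, depth_cell = 0.02,
                                   site_jitter = FALSE)
  d <- abs(stat[[2]]$field$true_cover - stat[[1]]$field$true_cover)
  expect_lt(max(d), 2)

  # drift through zero is clamped with a warning
  expect_warning(
    generate_site_timeseries(pr, sp, dates, change_rates = c(sand = -1),
                             seed = 4, cell_size = 0.02, depth_cell = 0.02,
                             survey_jitter_sd = 0, site_jitter = FALSE),
    "clamped")
})

test_that("regions lay out islands, sites, covariates and clumped archetypes", {
  reg <- generate_region(n_islands = 4, sites_per_island = 9, seed = 3,
                         survey_dates = as.Date(c("2021-01-01",
                                                  "2023-01-01")),
                         n_points = 100, cell_size = 0.05, depth_cell = 0.05,
                         plot_width = 4, plot_height = 4, n_transects = 4)
  expect_equal(nrow(reg$sites), 36)
  expect_equal(nrow(reg$observations), 72)
  covs <- reg$sites[c("depth_m", "wave_power", "sst_sd", "chl_a",
                      "irradiance", "sediment_export", "effluent")]
  expect_false(anyNA(covs))
  cors <- stats::cor(covs)
  expect_lte(max(abs(cors[upper.tri(cors)])), 0.54)

  # archetype concentration drives island-level coral cover
  coral <- rowSums(reg$observations[intersect(coral_categories(),
                                              names(reg$observations))])
  by_island <- tapply(coral, reg$observations$island, mean)
  hi_isl <- names(sort(tapply(
    reg$sites$archetype == "high_cover_montipora",
    reg$sites$island, mean), decreasing = TRUE))[1]
  expect_gt(by_island[hi_isl], mean(by_island))

  # reproducibility of the whole region
  reg2 <- generate_region(n_islands = 2, sites_per_island = 2, seed = 8,
                          survey_dates = as.Date(c("2021-01-01",
                                                   "2023-01-01")),
                          n_points = 64, cell_size = 0.05, depth_cell = 0.05,
                          plot_width = 4, plot_height = 4, n_transects = 4)
  reg3 <- generate_region(n_islands = 2, sites_per_island = 2, seed = 8,
                          survey_dates = as.Date(c("2021-01-01",
                                                   "2023-01-01")),
                          n_points = 64, cell_size = 0.05, depth_cell = 0.05,
                          plot_width = 4, plot_height = 4, n_transects = 4)
  expect_identical(reg2$observations, reg3$observations)
})
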