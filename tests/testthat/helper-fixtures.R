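# shared fixture builders; everything is generated in code at test time

# a small plot for fast raster work
small_spec <- function(w = 4, h = 4) plot_spec(width = w, height = h)

# a three-category archetype with controllable patchiness
toy_profile <- function(agg = 0.8, covers = c(a = 50, b = 30, c = 20),
                        sds = NULL, rug = 1.5, hurst = 0.5) {
  archetype_profile("toy", covers, sds, aggregation_scale = agg,
                    rugosity_target = rug, hurst = hurst)
}

# single-category degenerate profile
mono_profile <- function(cat = "only") {
  archetype_profile("mono", stats::setNames(100, cat),
                    aggregation_scale = 1)
}

# small fast label field
toy_field <- function(seed = 1, agg = 0.8, w = 4, cell = 0.02,
                      jitter = FALSE) {
  generate_label_field(toy_profile(agg = agg), small_spec(w, w), seed = seed,
                       cell_size = cell, jitter = jitter)
}

# Euclidean reef_dist from a coordinate matrix
euclid_dist <- function(m) {
  d <- as.matrix(stats::dist(m))
  structure(d, metric = "euclidean", class = c("reef_dist", "matrix"))
}
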