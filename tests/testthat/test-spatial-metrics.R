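# dense-grid nearest-site rasterization: the independent adjacency oracle
grid_adjacency <- function(x, y, w, h, res = 0.001) {
  gx <- seq(res / 2, w - res / 2, by = res)
  gy <- seq(res / 2, h - res / 2, by = res)
  lab <- matrix(0L, length(gy), length(gx))
  best <- matrix(Inf, length(gy), length(gx))
  for (k in seq_along(x)) {
    d2 <- outer((gy - y[k])^2, (gx - x[k])^2, "+")
    upd <- d2 < best
    lab[upd] <- k
    best[upd] <- d2[upd]
  }
  pairs <- rbind(cbind(as.vector(lab[-1, ]), as.vector(lab[-nrow(lab), ])),
                 cbind(as.vector(lab[, -1]), as.vector(lab[, -ncol(lab)])))
  pairs <- pairs[pairs[, 1] != pairs[, 2], , drop = FALSE]
  if (nrow(pairs) == 0) return(data.frame(i = integer(0), j = integer(0)))
  u <- unique(data.frame(i = pmin(pairs[, 1], pairs[, 2]),
                         j = pmax(pairs[, 1], pairs[, 2])))
  u[order(u$i, u$j), ]
}

test_that("Voronoi cells tile the plot and adjacency matches the grid oracle", {
  sp <- plot_spec(1, 1)
  # 2 points: two half-plane cells, one adjacency
  t2 <- voronoi_tessellate(cbind(c(0.3, 0.7), c(0.5, 0.5)), sp)
  expect_equal(length(t2$polygons), 2)
  expect_equal(nrow(t2$adjacency), 1)
  expect_equal(sum(t2$area), 1, tolerance = 1e-9)

  # random point sets up to 12 points: geometric == rasterized adjacency
  for (seed in 1:3) {
    set.seed(seed)
    n <- sample(5:12, 1)
    x <- runif(n); y <- runif(n)
    tess <- voronoi_tessellate(cbind(x, y), sp)
    expect_equal(sum(tess$area), 1, tolerance = 1e-6)
    got <- tess$adjacency[c("i", "j")]
    rownames(got) <- NULL
    oracle <- grid_adjacency(x, y, 1, 1)
    rownames(oracle) <- NULL
    expect_equal(got, oracle)
  }

  # duplicate points are perturbed, not fatal
  expect_warning(td <- voronoi_tessellate(cbind(c(0.5, 0.5, 0.2),
                                                c(0.5, 0.5, 0.2)), sp),
                 "perturbed")
  expect_equal(length(td$polygons), 3)
})

test_that("lattice tessellations give square cells and exact adjacency counts", {
  k <- 10
  sp <- plot_spec(10, 10)
  ctr <- expand.grid(x = seq(0.5, 9.5), y = seq(0.5, 9.5))
  tess <- voronoi_tessellate(ctr, sp)
  expect_true(all(abs(tess$area - 1) < 1e-9))
  # interior lattice adjacency count: 2 * k * (k - 1)
  expect_equal(nrow(tess$adjacency), 2 * k * (k - 1))

  # left/right half split: 10 unlike of 180 adjacencies
  labs <- ifelse(ctr$x < 5, "L", "R")
  h <- unlike_adjacency_proportion(tess, labels = labs)
  expect_equal(h$n_adjacencies, 180)
  expect_equal(h$n_unlike, 10)
  expect_equal(h$value, 10 / 180)
})

test_that("heterogeneity hits its bounds and is invariant to relabeling and rotation", {
  sp <- plot_spec(1, 1)
  set.seed(42)
  x <- runif(30); y <- runif(30)
  labs <- sample(letters[1:4], 30, replace = TRUE)
  tess <- voronoi_tessellate(cbind(x, y), sp, labels = labs)

  expect_equal(unlike_adjacency_proportion(tess, labels = rep("a", 30))$value, 0)
  t2 <- voronoi_tessellate(cbind(c(0.3, 0.7), c(0.5, 0.5)), sp,
                           labels = c("a", "b"))
  expect_equal(unlike_adjacency_proportion(t2)$value, 1)

  h0 <- unlike_adjacency_proportion(tess)$value
  relab <- c(a = "w", b = "x", c = "y", d = "z")[labs]
  expect_equal(unlike_adjacency_proportion(tess, labels = relab)$value, h0)
  rot <- voronoi_tessellate(cbind(y, 1 - x), sp, labels = labs)
  expect_equal(unlike_adjacency_proportion(rot)$value, h0)

  # edge-length weighting stays in [0, 1] and is deterministic
  hl <- unlike_adjacency_proportion(tess, weighting = "edge_length")$value
  expect_true(hl >= 0 && hl <= 1)

  # a tessellation without labels cannot be scored
  unlab <- voronoi_tessellate(cbind(x, y), sp)
  expect_error(unlike_adjacency_proportion(unlab), "no labels")
})

test_that("mean heterogeneity falls as patches grow", {
  hmean <- sapply(c(0.4, 0.8, 1.6), function(agg) {
    mean(sapply(1:20, function(s) {
      f <- toy_field(seed = s, agg = agg)
      pts <- stratified_random_points(small_spec(), 100, seed = 1000 + s)
      ann <- annotate_points(pts, f)
      tess <- voronoi_tessellate(pts, small_spec(), labels = ann$category)
      unlike_adjacency_proportion(tess)$value
    }))
  })
  expect_true(all(diff(hmean) < 0))
})

test_that("virtual transects sample the expected geometry", {
  sp <- plot_spec()
  flat <- generate_depth_surface(sp, amplitude = 0, seed = 1, cell_size = 0.01)
  profs <- virtual_transects(flat, 10, 0.01)
  expect_length(profs, 20)
  offs <- sort(unique(sapply(profs, attr, "offset")))
  expect_equal(offs, seq(0.5, 9.5))
  expect_equal(nrow(profs[[1]]), 1001)
  expect_true(all(sapply(profs, function(p) sd(p$depth) == 0)))
  expect_error(virtual_transects(flat, 5, 0.001), "cell_size")
})

test_that("linear rugosity matches analytic geometry", {
  flat <- data.frame(distance = seq(0, 10, 0.5), depth = rep(3, 21))
  expect_identical(linear_rugosity(flat), 1)

  # sawtooth with |dz/dx| = 1 sampled at its vertices
  d <- seq(0, 4, by = 0.5)
  z <- 5 + abs((d %% 1) - 0.5)
  expect_equal(linear_rugosity(data.frame(distance = d, depth = z)), sqrt(2),
               tolerance = 1e-9)

  # half-sine bump vs adaptive-quadrature arc length
  d <- seq(0, 10, by = 0.01)
  z <- 0.5 * sin(pi * d / 10)
  arc <- integrate(function(x) sqrt(1 + (0.05 * pi * cos(pi * x / 10))^2),
                   0, 10, rel.tol = 1e-12)$value
  expect_equal(linear_rugosity(data.frame(distance = d, depth = z)),
               arc / 10, tolerance = 1e-6)

  expect_error(linear_rugosity(data.frame(distance = 1, depth = 1)), "samples")
  expect_error(linear_rugosity(data.frame(distance = c(1, 1), depth = c(1, 2))),
               "planar")
})

test_that("plot rugosity equals a second transect-by-transect implementation", {
  sp <- plot_spec(4, 4)
  surf <- generate_depth_surface(sp, hurst = 0.5, amplitude = 0.3, seed = 9,
                                 cell_size = 0.02)
  # independent re-implementation: explicit loops, scalar bilinear lookup
  bil <- function(s, xq, yq) {
    cs <- s$cell_size
    gx <- xq / cs; gy <- yq / cs
    c0 <- min(floor(gx), ncol(s$z) - 2); r0 <- min(floor(gy), nrow(s$z) - 2)
    tx <- gx - c0; ty <- gy - r0
    (1 - ty) * ((1 - tx) * s$z[r0 + 1, c0 + 1] + tx * s$z[r0 + 1, c0 + 2]) +
      ty * ((1 - tx) * s$z[r0 + 2, c0 + 1] + tx * s$z[r0 + 2, c0 + 2])
  }
  oracle <- function(s, res, n) {
    vals <- c()
    for (orient in c("x", "y")) for (i in seq_len(n)) {
      off <- (i - 0.5) * 4 / n
      dd <- seq(0, 4, by = res)
      zz <- sapply(dd, function(t)
        if (orient == "x") bil(s, t, off) else bil(s, off, t))
      vals <- c(vals, sum(sqrt(diff(dd)^2 + diff(zz)^2)) / (max(dd) - min(dd)))
    }
    mean(vals)
  }
  for (res in c(0.02, 0.5))
    expect_equal(plot_rugosity(surf, res, 5), oracle(surf, res, 5),
                 tolerance = 1e-9)
})

test_that("rugosity never increases with coarser sampling", {
  sp <- plot_spec(4, 4)
  for (s in 1:3) {
    surf <- generate_depth_surface(sp, hurst = 0.4, amplitude = 0.4,
                                   seed = s, cell_size = 0.02)
    r <- sapply(c(0.02, 0.1, 0.5), function(res) plot_rugosity(surf, res, 5))
    expect_true(all(diff(r) <= 1e-12))
    expect_true(all(r >= 1))
  }
})

test_that("fractal dimension: analytic cases and Hurst recovery", {
  # flat and uniformly sloped profiles are one-dimensional
  d <- seq(0, 10, 0.01)
  expect_equal(fractal_dimension(data.frame(distance = d, depth = rep(2, length(d)))), 1)
  expect_equal(fractal_dimension(data.frame(distance = d, depth = 2 + 0.3 * d)),
               1, tolerance = 1e-9)
  expect_error(fractal_dimension(data.frame(distance = d, depth = d),
                                 step_sizes = 0.1), ">= 2 step")

  # fBm profiles: D within 2 - H +/- 0.15
  sp <- plot_spec()
  Ds <- sapply(1:3, function(s) {
    surf <- generate_depth_surface(sp, hurst = 0.5, amplitude = 3, seed = s)
    fractal_dimension(virtual_transects(surf, 3, 0.01))
  })
  expect_lt(abs(mean(Ds) - 1.5), 0.15)
})
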