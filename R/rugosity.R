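#' Extract virtual depth profiles from a surface
#'
#' Emulates a virtual profile gauge: `n_per_direction` equally spaced
#' transects parallel to each plot axis (at offsets `(k - 0.5) * extent / n`),
#' with depth sampled by bilinear interpolation at the stated resolution.
#'
#' @param surface A `depth_surface`.
#' @param n_per_direction Transects per axis direction (total `2 * n`).
#' @param resolution Sampling step along the transect (m); must be at least
#'   the surface cell size.
#' @return List of `depth_profile` data frames with columns `distance` and
#'   `depth` and attributes `orientation` (`"x"` or `"y"`), `offset`, and
#'   `resolution`.
#' @export
virtual_transects <- function(surface, n_per_direction = 10,
                              resolution = 0.01) {
  stopifnot(inherits(surface, "depth_surface"))
  if (resolution < surface$cell_size - 1e-12)
    stop("resolution must be >= surface cell_size", call. = FALSE)
  out <- vector("list", 2L * n_per_direction)
  idx <- 1L
  for (orient in c("x", "y")) {
    span <- if (orient == "x") surface$width else surface$height
    extent <- if (orient == "x") surface$height else surface$width
    offs <- (seq_len(n_per_direction) - 0.5) * extent / n_per_direction
    d <- seq(0, span, by = resolution)
    for (o in offs) {
      z <- if (orient == "x") .bilinear(surface, d, rep(o, length(d)))
           else .bilinear(surface, rep(o, length(d)), d)
      p <- data.frame(distance = d, depth = z)
      attr(p, "orientation") <- orient
      attr(p, "offset") <- o
      attr(p, "resolution") <- resolution
      class(p) <- c("depth_profile", "data.frame")
      out[[idx]] <- p
      idx <- idx + 1L
    }
  }
  out
}

# bilinear interpolation on the node grid; x along columns, y along rows
.bilinear <- function(surface, x, y) {
  cs <- surface$cell_size
  nr <- nrow(surface$z); nc <- ncol(surface$z)
  if (any(x < -1e-9 | x > surface$width + 1e-9 |
          y < -1e-9 | y > surface$height + 1e-9))
    stop("transect sample outside surface extent", call. = FALSE)
  gx <- pmin(pmax(x / cs, 0), nc - 1)
  gy <- pmin(pmax(y / cs, 0), nr - 1)
  c0 <- pmin(floor(gx), nc - 2); r0 <- pmin(floor(gy), nr - 2)
  tx <- gx - c0; ty <- gy - r0
  z <- surface$z
  i00 <- cbind(r0 + 1, c0 + 1); i01 <- cbind(r0 + 1, c0 + 2)
  i10 <- cbind(r0 + 2, c0 + 1); i11 <- cbind(r0 + 2, c0 + 2)
  (1 - ty) * ((1 - tx) * z[i00] + tx * z[i01]) +
    ty * ((1 - tx) * z[i10] + tx * z[i11])
}

#' Linear rugosity of a depth profile
#'
#' Contour length divided by planar length. A perfectly flat profile has
#' rugosity exactly 1; rougher surfaces score higher. Coarser sampling can
#' only shorten the contour, so rugosity is non-increasing in resolution.
#'
#' @param profile A `depth_profile` (or any data frame with `distance` and
#'   `depth` columns, >= 2 rows).
#' @return Dimensionless rugosity >= 1.
#' @export
linear_rugosity <- function(profile) {
  d <- profile$distance; z <- profile$depth
  if (length(d) < 2) stop("profile needs >= 2 samples", call. = FALSE)
  planar <- d[length(d)] - d[1]
  if (planar <= 0) stop("profile has zero planar length", call. = FALSE)
  sum(sqrt(diff(d)^2 + diff(z)^2)) / planar
}

#' Plot-level linear rugosity
#'
#' Mean linear rugosity over virtual transects in both axis directions at a
#' given sampling resolution (the survey reports 1 cm and 50 cm).
#'
#' @inheritParams virtual_transects
#' @return Dimensionless rugosity >= 1.
#' @export
plot_rugosity <- function(surface, resolution = 0.01, n_per_direction = 10) {
  profs <- virtual_transects(surface, n_per_direction, resolution)
  mean(vapply(profs, linear_rugosity, numeric(1)))
}

#' Profile fractal dimension by the divider method
#'
#' Each profile is resampled at a series of horizontal step sizes; the
#' contour length `L(s)` at step `s` follows `log L(s) = c + (1 - D) log s`
#' for a fractal profile, and `D` is estimated per profile by least squares
#' on that line and averaged across profiles. Estimates are clamped to
#' `[1, 2]` with a warning. The relation `D = 2 - H` for fractional
#' Brownian profiles holds where the relief dominates the step size
#' (the self-affine scaling regime).
#'
#' @param profiles List of `depth_profile`s (native sampling at least as
#'   fine as the smallest step).
#' @param step_sizes Horizontal steps (m); at least 2, >= 3 spanning a
#'   decade recommended.
#' @return Mean fractal dimension in `[1, 2]`.
#' @export
fractal_dimension <- function(profiles,
                              step_sizes = c(0.02, 0.04, 0.08, 0.16, 0.32)) {
  if (inherits(profiles, "data.frame")) profiles <- list(profiles)
  step_sizes <- sort(step_sizes)
  if (length(step_sizes) < 2)
    stop("need >= 2 step sizes", call. = FALSE)
  ds <- vapply(profiles, function(p) {
    span <- max(p$distance) - min(p$distance)
    ok <- step_sizes <= span / 2
    if (sum(ok) < 2) stop("fewer than 2 valid step sizes for a profile",
                          call. = FALSE)
    lens <- vapply(step_sizes[ok], function(s) {
      d <- seq(min(p$distance), max(p$distance), by = s)
      # close the walk at the profile end so every step size spans the
      # same planar extent (flat and ramp profiles then scale exactly)
      if (d[length(d)] < max(p$distance)) d <- c(d, max(p$distance))
      z <- stats::approx(p$distance, p$depth, xout = d)$y
      sum(sqrt(diff(d)^2 + diff(z)^2))
    }, numeric(1))
    if (stats::sd(log(lens)) < 1e-12) return(1)  # flat: L(s) constant
    fit <- stats::lm.fit(cbind(1, log(step_sizes[ok])), log(lens))
    1 - fit$coefficients[2]
  }, numeric(1))
  D <- mean(ds)
  if (D < 1 || D > 2) {
    warning(sprintf("fractal dimension %.3f clamped to [1, 2]", D))
    D <- min(max(D, 1), 2)
  }
  D
}

#' Structural complexity metrics for one surface
#'
#' Bundles the three complexity descriptors used in the site-level feature
#' matrix: linear rugosity at 1 cm and 50 cm sampling resolution and the
#' divider-method fractal dimension of the 1 cm profiles.
#'
#' @param surface A `depth_surface`.
#' @param resolutions Length-2 numeric, fine and coarse sampling steps (m).
#' @param n_per_direction Transects per axis direction.
#' @param fd_steps Step sizes for [fractal_dimension()].
#' @return Named list: `rugosity_1cm`, `rugosity_50cm`, `fractal_dimension`.
#' @export
complexity_metrics <- function(surface, resolutions = c(0.01, 0.5),
                               n_per_direction = 10,
                               fd_steps = c(0.02, 0.04, 0.08, 0.16, 0.32)) {
  fine <- virtual_transects(surface, n_per_direction, min(resolutions))
  r1 <- mean(vapply(fine, linear_rugosity, numeric(1)))
  r50 <- plot_rugosity(surface, max(resolutions), n_per_direction)
  fd <- fractal_dimension(fine, fd_steps)
  list(rugosity_1cm = r1, rugosity_50cm = r50, fractal_dimension = fd)
}
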