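#' Generate a fractional-Brownian depth surface
#'
#' Synthesizes a gridded depth surface (metres, positive down) by spectral
#' synthesis: independent complex Gaussian spectral coefficients are shaped
#' by a power-law amplitude `(fx^2 + fy^2)^-((H+1)/2)` and inverse
#' Fourier-transformed, giving a fractional-Brownian-type surface whose
#' profiles have fractal dimension `D = 2 - H` in the self-affine regime.
#' `amplitude` sets the standard deviation of the relief; `amplitude = 0`
#' yields a perfectly flat surface.
#'
#' @param spec A [plot_spec()].
#' @param hurst Hurst exponent in (0, 1).
#' @param amplitude Standard deviation of the relief (m), >= 0.
#' @param cell_size Grid spacing (m); must not exceed the plot dimensions.
#'   Keep at or below 0.01 m when 1 cm rugosity will be computed.
#' @param seed Integer seed.
#' @param mean_depth Mean depth of the plot (m), default 10.
#' @return An object of class `depth_surface`: a node grid `z` (rows run
#'   along y), `cell_size`, and the plot extent.
#' @export
generate_depth_surface <- function(spec, hurst = 0.5, amplitude = 0.25,
                                   cell_size = 0.01, seed = 1,
                                   mean_depth = 10) {
  stopifnot(inherits(spec, "plot_spec"))
  if (hurst <= 0 || hurst >= 1) stop("hurst must lie in (0, 1)", call. = FALSE)
  if (amplitude < 0) stop("amplitude must be >= 0", call. = FALSE)
  if (cell_size > spec$width || cell_size > spec$height)
    stop("cell_size larger than the plot", call. = FALSE)
  nr <- as.integer(round(spec$height / cell_size)) + 1L
  nc <- as.integer(round(spec$width / cell_size)) + 1L
  if (amplitude == 0) {
    z <- matrix(mean_depth, nr, nc)
  } else {
    set.seed(as.integer(seed))
    z <- mean_depth + amplitude * .fbm2d(nr, nc, hurst)
  }
  structure(list(z = z, cell_size = cell_size, width = spec$width,
                 height = spec$height, hurst = hurst, amplitude = amplitude,
                 spec = spec),
            class = "depth_surface")
}

.fft_freq <- function(n) {
  k <- 0:(n - 1)
  k[k > n / 2] <- k[k > n / 2] - n
  k / n
}

.fbm2d <- function(nr, nc, hurst) {
  fr <- matrix(.fft_freq(nr), nr, nc)
  fc <- matrix(.fft_freq(nc), nr, nc, byrow = TRUE)
  f2 <- fr^2 + fc^2
  f2[1, 1] <- Inf                       # kill the DC component
  shape <- f2^(-(hurst + 1) / 2)
  coef <- matrix(stats::rnorm(nr * nc), nr, nc) +
    1i * matrix(stats::rnorm(nr * nc), nr, nc)
  z <- Re(stats::fft(coef * shape, inverse = TRUE))
  (z - mean(z)) / stats::sd(z)
}

#' @export
print.depth_surface <- function(x, ...) {
  cat(sprintf(
    "Depth surface: %d x %d nodes (%.2g m cells), relief sd %.3f m\n",
    nrow(x$z), ncol(x$z), x$cell_size, stats::sd(x$z)))
  invisible(x)
}

#' Rescale a surface's relief to hit a rugosity target
#'
#' Scales the relief about its mean so that [plot_rugosity()] at the stated
#' resolution equals `target`. Rugosity is monotone in the relief scale, so
#' the factor is found by 1-D root finding on the fixed transect increments
#' (no re-simulation; the result is deterministic given the surface).
#'
#' @param surface A `depth_surface`.
#' @param target Target mean linear rugosity (>= 1).
#' @param resolution Sampling resolution (m) at which the target is defined.
#' @param n_per_direction Transects per axis direction.
#' @return The rescaled `depth_surface`.
#' @export
calibrate_rugosity <- function(surface, target, resolution = 0.01,
                               n_per_direction = 10) {
  stopifnot(inherits(surface, "depth_surface"))
  if (target < 1) stop("rugosity target must be >= 1", call. = FALSE)
  mu <- mean(surface$z)
  if (target == 1) {
    surface$z[] <- mu
    surface$amplitude <- 0
    return(surface)
  }
  profs <- virtual_transects(surface, n_per_direction, resolution)
  segs <- lapply(profs, function(p) {
    list(dx = diff(p$distance), dz = diff(p$depth), span = sum(diff(p$distance)))
  })
  rug_at <- function(a) {
    mean(vapply(segs, function(s)
      sum(sqrt(s$dx^2 + (a * s$dz)^2)) / s$span, numeric(1)))
  }
  if (rug_at(1) <= 1 + 1e-12)
    stop("surface has no relief to calibrate", call. = FALSE)
  hi <- 1
  while (rug_at(hi) < target) hi <- hi * 2
  a <- stats::uniroot(function(a) rug_at(a) - target, c(0, hi),
                      tol = 1e-10)$root
  surface$z <- mu + a * (surface$z - mu)
  surface$amplitude <- surface$amplitude * a
  surface
}
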