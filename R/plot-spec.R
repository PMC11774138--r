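#' Define the geometry and identity of a survey plot
#'
#' A plot is the fixed quadrat over which a site is imaged and annotated.
#' The monitoring design uses 10 x 10 m plots; one rectangular 12 x 5 m
#' variant exists in the region, so arbitrary positive dimensions are
#' accepted.
#'
#' @param width,height Plot dimensions in metres (> 0). Default 10 x 10.
#' @param origin Numeric length-2, south-west corner in plot coordinates (m).
#' @param site_id Site identifier.
#' @param island Island identifier.
#' @param survey_date Survey date (`Date` or coercible).
#' @return An object of class `plot_spec`.
#' @examples
#' plot_spec()
#' plot_spec(width = 12, height = 5, site_id = "K6")
#' @export
plot_spec <- function(width = 10, height = 10, origin = c(0, 0),
                      site_id = "site", island = NA_character_,
                      survey_date = as.Date("2023-01-01")) {
  stopifnot(is.numeric(width), is.numeric(height), length(origin) == 2)
  if (width <= 0 || height <= 0)
    stop("plot dimensions must be positive", call. = FALSE)
  structure(
    list(width = as.numeric(width), height = as.numeric(height),
         origin = as.numeric(origin), site_id = as.character(site_id),
         island = as.character(island), survey_date = as.Date(survey_date)),
    class = "plot_spec")
}

#' @export
print.plot_spec <- function(x, ...) {
  cat(sprintf("Reef plot %s (%s): %g x %g m, surveyed %s\n",
              x$site_id, x$island, x$width, x$height,
              format(x$survey_date)))
  invisible(x)
}

#' The default 15-category benthic classification
#'
#' Point annotations are aggregated into 15 categories covering the dominant
#' Hawaiian reef taxa and functional groups: eight named coral taxa plus an
#' other-coral pool, crustose coralline algae (CCA), turf algae, fleshy
#' macroalgae, sand/sediment, sessile invertebrates, and bare limestone.
#' The set is configurable everywhere it is consumed.
#'
#' @return Character vector of length 15.
#' @export
benthic_categories <- function() {
  c("Porites lobata", "Porites compressa", "Montipora capitata",
    "Montipora patula", "Pocillopora", "Pavona", "Leptastrea",
    "Psammocora", "other coral", "CCA", "turf algae",
    "fleshy macroalgae", "sand/sediment", "sponge/zoanthid/other invert",
    "bare limestone")
}

#' Coral categories within the default classification
#'
#' @return Character vector of the nine coral categories; total coral cover
#'   is the sum of these columns of a cover matrix.
#' @export
coral_categories <- function() benthic_categories()[1:9]

#' Construct a community archetype profile
#'
#' An archetype bundles the expected benthic composition of a community type
#' with the spatial texture the generator should reproduce: mean percent
#' cover per category (summing to 100), a between-site standard deviation
#' per category, a characteristic patch diameter, and targets for the
#' surface roughness (1 cm linear rugosity) and the Hurst exponent of the
#' depth surface.
#'
#' @param name Archetype name.
#' @param mean_cover Named numeric, percent cover per category; must sum to
#'   100 within 0.01.
#' @param cover_sd Named numeric, between-site standard deviation of cover
#'   (percentage points); recycled from 0 if omitted.
#' @param aggregation_scale Characteristic patch diameter (m).
#' @param rugosity_target Target 1 cm linear rugosity (>= 1).
#' @param hurst Hurst exponent of the depth surface, in (0, 1).
#' @return An object of class `archetype_profile`.
#' @export
archetype_profile <- function(name, mean_cover, cover_sd = NULL,
                              aggregation_scale = 1, rugosity_target = 1.7,
                              hurst = 0.5) {
  stopifnot(is.numeric(mean_cover), !is.null(names(mean_cover)))
  if (any(mean_cover < 0))
    stop("mean_cover has negative entries", call. = FALSE)
  tot <- sum(mean_cover)
  if (abs(tot - 100) > 0.01)
    stop(sprintf("mean_cover sums to %.4f, not 100 (off by %.4f)",
                 tot, tot - 100), call. = FALSE)
  if (is.null(cover_sd)) cover_sd <- stats::setNames(rep(0, length(mean_cover)),
                                                     names(mean_cover))
  stopifnot(all(names(mean_cover) %in% names(cover_sd)) ||
              length(cover_sd) == length(mean_cover))
  cover_sd <- cover_sd[names(mean_cover)]
  if (rugosity_target < 1) stop("rugosity_target must be >= 1", call. = FALSE)
  if (hurst <= 0 || hurst >= 1) stop("hurst must lie in (0, 1)", call. = FALSE)
  structure(
    list(name = name, mean_cover = mean_cover, cover_sd = cover_sd,
         aggregation_scale = aggregation_scale,
         rugosity_target = rugosity_target, hurst = hurst),
    class = "archetype_profile")
}

#' @export
print.archetype_profile <- function(x, ...) {
  cat(sprintf("Archetype '%s': %d categories, patch scale %.2g m, rugosity target %.2f\n",
              x$name, length(x$mean_cover), x$aggregation_scale,
              x$rugosity_target))
  top <- sort(x$mean_cover, decreasing = TRUE)[1:3]
  cat("  dominant:", paste(sprintf("%s %.1f%%", names(top), top),
                           collapse = ", "), "\n")
  invisible(x)
}

# Default compositions for the three regional community types. Printed
# category means (community coral totals, P. lobata, turf, P. compressa,
# Pavona, CCA, macroalgae, M. capitata, M. patula) are honoured exactly;
# the remaining categories are filled with fixed plausible values so each
# profile sums to 100.
.archetype_covers <- function(name) {
  cats <- benthic_categories()
  v <- switch(name,
    low_cover_porites = c(15.23, 4.00, 3.00, 2.00, 2.00, 1.50, 2.50, 2.00,
                          2.86, 3.00, 53.52, 1.50, 3.50, 1.89, 1.50),
    intermediate_diverse = c(12.00, 11.45, 10.00, 6.00, 5.00, 1.24, 3.00,
                             3.00, 4.05, 9.19, 24.00, 2.49, 5.00, 1.80, 1.78),
    high_cover_montipora = c(2.00, 2.00, 48.62, 13.00, 1.00, 0.50, 0.30,
                             0.20, 0.20, 4.00, 20.00, 1.00, 4.00, 1.18, 2.00),
    stop("unknown archetype: ", name))
  stats::setNames(v, cats)
}

.archetype_sds <- function(mean_cover) {
  sd <- ifelse(mean_cover >= 10, 2, ifelse(mean_cover >= 2, 1, 0.3))
  # printed between-site SEs where available
  sd[names(mean_cover) == "Montipora capitata"] <-
    ifelse(mean_cover[names(mean_cover) == "Montipora capitata"] > 40, 2.07,
           sd[names(mean_cover) == "Montipora capitata"])
  stats::setNames(sd, names(mean_cover))
}

#' Built-in community archetypes
#'
#' Three regional reef community types: low coral cover *Porites*/turf
#' reefs (moderate complexity, low heterogeneity, 35.09% coral), diverse
#' intermediate-cover reefs (high complexity and heterogeneity, 55.74%
#' coral), and high-cover *Montipora* reefs (low complexity and
#' heterogeneity, 67.82% coral).
#'
#' @param name One of `"low_cover_porites"`, `"intermediate_diverse"`,
#'   `"high_cover_montipora"`.
#' @return An [archetype_profile()].
#' @examples
#' default_archetype("high_cover_montipora")
#' @export
default_archetype <- function(name = c("low_cover_porites",
                                       "intermediate_diverse",
                                       "high_cover_montipora")) {
  name <- match.arg(name)
  mc <- .archetype_covers(name)
  pars <- switch(name,
    low_cover_porites = list(agg = 1.2, rug = 1.75, hurst = 0.5),
    intermediate_diverse = list(agg = 0.5, rug = 1.95, hurst = 0.5),
    high_cover_montipora = list(agg = 1.0, rug = 1.60, hurst = 0.5))
  archetype_profile(name, mc, .archetype_sds(mc),
                    aggregation_scale = pars$agg,
                    rugosity_target = pars$rug, hurst = pars$hurst)
}

#' Assemble a reef plot bundle
#'
#' Container for everything known about one site at one survey: the plot
#' geometry, and optionally the categorical label field, the depth surface,
#' the point annotations, and summary metrics. Generator and annotation
#' stages fill components in as they run.
#'
#' @param spec A [plot_spec()].
#' @param field Optional label field (see [generate_label_field()]).
#' @param surface Optional depth surface (see [generate_depth_surface()]).
#' @param annotations Optional annotation table.
#' @param metadata Optional named list of site metadata.
#' @return An object of class `reef_plot`.
#' @export
reef_plot <- function(spec, field = NULL, surface = NULL,
                      annotations = NULL, metadata = list()) {
  stopifnot(inherits(spec, "plot_spec"))
  structure(list(spec = spec, field = field, surface = surface,
                 annotations = annotations, metadata = metadata),
            class = "reef_plot")
}

#' @export
print.reef_plot <- function(x, ...) {
  print(x$spec)
  parts <- c(field = !is.null(x$field), surface = !is.null(x$surface),
             annotations = !is.null(x$annotations))
  cat("  components:", paste(names(parts)[parts], collapse = ", "), "\n")
  invisible(x)
}
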