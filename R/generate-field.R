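#' Generate a categorical benthic label field
#'
#' Simulates the spatial mosaic of benthic categories inside one plot as a
#' fine raster (1 cm cells by default). Per-category area targets are drawn
#' around the archetype means, one seed cell is planted per patch (patch
#' count follows the archetype's characteristic patch diameter), and
#' capacity-constrained region growing claims cells in order of distance
#' from each seed, so realized covers track the targets while patches stay
#' contiguous. Cells walled off by exhausted categories are filled from
#' their nearest neighbour and a boundary-swap pass trims the overshoot.
#'
#' @param profile An [archetype_profile()].
#' @param spec A [plot_spec()].
#' @param seed Integer seed; identical arguments give bit-identical fields.
#' @param cell_size Raster cell size (m), default 0.01.
#' @param jitter If `TRUE` (default) per-category targets are jittered by a
#'   truncated normal (|z| <= 2, sd capped at 2 points) around
#'   `profile$mean_cover`; if `FALSE`, or via `target_cover`, targets are
#'   used exactly.
#' @param target_cover Optional named percent vector overriding the
#'   archetype means (must sum to 100).
#' @return An object of class `label_field` with the category raster,
#'   category set, and `true_cover`, the realized areal percent per
#'   category (sums to 100 exactly).
#' @seealso [label_at()] to query the field, [stratified_random_points()]
#'   and [annotate_points()] to sample it.
#' @export
generate_label_field <- function(profile, spec, seed, cell_size = 0.01,
                                 jitter = TRUE, target_cover = NULL) {
  stopifnot(inherits(profile, "archetype_profile"), inherits(spec, "plot_spec"))
  set.seed(as.integer(seed))
  cats <- names(profile$mean_cover)

  target <- if (!is.null(target_cover)) {
    if (abs(sum(target_cover) - 100) > 0.01)
      stop(sprintf("target_cover sums to %.4f, not 100 (off by %.4f)",
                   sum(target_cover), sum(target_cover) - 100), call. = FALSE)
    target_cover[cats]
  } else if (jitter) {
    .jitter_cover(profile$mean_cover, profile$cover_sd)
  } else profile$mean_cover

  nr <- max(2L, as.integer(round(spec$height / cell_size)))
  nc <- max(2L, as.integer(round(spec$width / cell_size)))
  ncell <- nr * nc

  # integer cell targets, exact total by largest remainder
  raw <- target / 100 * ncell
  cells <- floor(raw)
  rem <- ncell - sum(cells)
  if (rem > 0) {
    ord <- order(raw - cells, decreasing = TRUE)
    cells[ord[seq_len(rem)]] <- cells[ord[seq_len(rem)]] + 1
  }

  # patch seeds: one per ~patch area, uniform positions
  patch_area <- pi * (profile$aggregation_scale / 2)^2
  seed_row <- integer(0); seed_col <- integer(0); patch_cat <- integer(0)
  for (k in seq_along(cats)) {
    if (cells[k] == 0) next
    area_k <- cells[k] * cell_size^2
    np <- max(1L, as.integer(round(area_k / patch_area)))
    sr <- pmin(nr - 1L, as.integer(floor(stats::runif(np) * nr)))
    sc <- pmin(nc - 1L, as.integer(floor(stats::runif(np) * nc)))
    seed_row <- c(seed_row, sr); seed_col <- c(seed_col, sc)
    patch_cat <- c(patch_cat, rep(k, np))
  }

  lab <- grow_label_field_cpp(nr, nc, seed_row, seed_col, patch_cat,
                              as.integer(cells))
  raster <- matrix(lab, nrow = nr, ncol = nc, byrow = TRUE)
  counts <- tabulate(lab, nbins = length(cats))
  true_cover <- stats::setNames(100 * counts / ncell, cats)

  structure(list(raster = raster, categories = cats, cell_size = cell_size,
                 spec = spec, true_cover = true_cover,
                 target_cover = stats::setNames(as.numeric(target), cats)),
            class = "label_field")
}

# truncated-normal jitter around archetype means, renormalized to 100;
# |z| <= 2 and sd capped at 2 points keep every category within ~5 points
.jitter_cover <- function(mean_cover, cover_sd) {
  sd_eff <- pmin(cover_sd, 2)
  z <- stats::rnorm(length(mean_cover))
  z <- pmax(pmin(z, 2), -2)
  v <- pmax(mean_cover + sd_eff * z, 0)
  v / sum(v) * 100
}

#' Query a label field
#'
#' @param field A `label_field`.
#' @param x,y Plot coordinates in metres (vectorized). Cells are half-open
#'   `[x0, x1)`; the far plot edge maps to the last cell.
#' @return Character vector of category labels.
#' @export
label_at <- function(field, x, y) {
  stopifnot(inherits(field, "label_field"))
  w <- field$spec$width; h <- field$spec$height
  if (any(x < 0 | x > w | y < 0 | y > h))
    stop("query point outside plot", call. = FALSE)
  nr <- nrow(field$raster); nc <- ncol(field$raster)
  col <- pmin(nc, floor(x / w * nc) + 1L)
  row <- pmin(nr, floor(y / h * nr) + 1L)
  field$categories[field$raster[cbind(row, col)]]
}

#' @export
print.label_field <- function(x, ...) {
  cat(sprintf("Label field: %d x %d cells (%.2g m), %d categories\n",
              nrow(x$raster), ncol(x$raster), x$cell_size,
              length(x$categories)))
  top <- sort(x$true_cover, decreasing = TRUE)[1:3]
  cat("  realized cover:", paste(sprintf("%s %.1f%%", names(top), top),
                                 collapse = ", "), "\n")
  invisible(x)
}
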