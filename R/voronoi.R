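#' Voronoi tessellation of annotated points, clipped to the plot
#'
#' Builds the Voronoi cell of every point by incremental half-plane
#' clipping against the plot rectangle, and records which cells share a
#' boundary segment of positive length (> 1e-9 m; corner-touching cells are
#' not adjacent). Duplicate points are perturbed deterministically by at
#' most 1e-9 m with a warning.
#'
#' @param points A `point_set` or two-column matrix/data frame of plot
#'   coordinates (m).
#' @param spec A [plot_spec()] giving the clip rectangle.
#' @param labels Optional per-point category labels (e.g. the `category`
#'   column of an annotation table), stored on the tessellation for
#'   [unlike_adjacency_proportion()].
#' @return A `reef_tessellation`: polygons (one matrix per cell), cell
#'   areas, an adjacency data frame (`i`, `j`, `length`) with `i < j`, and
#'   the labels.
#' @export
voronoi_tessellate <- function(points, spec, labels = NULL) {
  stopifnot(inherits(spec, "plot_spec"))
  if (is.matrix(points)) {
    x <- points[, 1]; y <- points[, 2]
  } else {
    x <- points[[1]]; y <- points[[2]]
  }
  n <- length(x)
  if (n < 2) stop("need >= 2 points", call. = FALSE)
  if (!is.null(labels) && length(labels) != n)
    stop("labels must match the number of points", call. = FALSE)

  key <- paste(x, y)
  if (anyDuplicated(key)) {
    warning("duplicate points perturbed by <= 1e-9 m")
    dup <- duplicated(key)
    set.seed(20221L)  # fixed internal seed: deterministic perturbation
    x[dup] <- x[dup] + stats::runif(sum(dup), -1e-9, 1e-9)
    y[dup] <- y[dup] + stats::runif(sum(dup), -1e-9, 1e-9)
  }

  res <- voronoi_cells_cpp(x, y, 0, spec$width, 0, spec$height)

  ei <- res$edge_i; ej <- res$edge_j; el <- res$edge_len
  a <- pmin(ei, ej); b <- pmax(ei, ej)
  keep <- el > 1e-9
  if (any(keep)) {
    pk <- paste(a[keep], b[keep])
    agg <- tapply(el[keep], pk, max)
    ij <- do.call(rbind, strsplit(names(agg), " "))
    adjacency <- data.frame(i = as.integer(ij[, 1]), j = as.integer(ij[, 2]),
                            length = as.numeric(agg))
    adjacency <- adjacency[order(adjacency$i, adjacency$j), ]
    rownames(adjacency) <- NULL
  } else {
    adjacency <- data.frame(i = integer(0), j = integer(0),
                            length = numeric(0))
  }

  structure(list(polygons = res$polygons, area = res$area,
                 adjacency = adjacency, labels = labels, spec = spec,
                 sites = cbind(x = x, y = y)),
            class = "reef_tessellation")
}

#' @export
print.reef_tessellation <- function(x, ...) {
  cat(sprintf("Voronoi tessellation: %d cells, %d adjacencies, area %.4f / %.4f m^2\n",
              length(x$polygons), nrow(x$adjacency), sum(x$area),
              x$spec$width * x$spec$height))
  invisible(x)
}

#' Landscape heterogeneity: proportion of unlike adjacencies
#'
#' The heterogeneity of a labelled tessellation is the proportion of
#' adjacent Voronoi cell pairs whose points carry different benthic
#' categories ("unlike adjacencies"). Under `edge_count` weighting every
#' adjacent pair counts once; under `edge_length` pairs are weighted by
#' their shared boundary length. Well-mixed fine-grained mosaics score near
#' 1, heavily aggregated single-taxon stands near 0.
#'
#' @param tess A `reef_tessellation` carrying labels (or supply `labels`).
#' @param weighting `"edge_count"` (default) or `"edge_length"`.
#' @param labels Optional per-cell labels overriding those stored.
#' @return A `heterogeneity_score` list: `value` in `[0, 1]`,
#'   `n_adjacencies`, `n_unlike`, `weighting`.
#' @export
unlike_adjacency_proportion <- function(tess,
                                        weighting = c("edge_count",
                                                      "edge_length"),
                                        labels = NULL) {
  stopifnot(inherits(tess, "reef_tessellation"))
  weighting <- match.arg(weighting)
  if (is.null(labels)) labels <- tess$labels
  if (is.null(labels)) stop("tessellation has no labels", call. = FALSE)
  adj <- tess$adjacency
  if (nrow(adj) == 0) stop("tessellation has no adjacencies", call. = FALSE)
  unlike <- labels[adj$i] != labels[adj$j]
  value <- if (weighting == "edge_count") mean(unlike)
           else sum(adj$length[unlike]) / sum(adj$length)
  structure(list(value = value, n_adjacencies = nrow(adj),
                 n_unlike = sum(unlike), weighting = weighting),
            class = "heterogeneity_score")
}

#' @export
print.heterogeneity_score <- function(x, ...) {
  cat(sprintf("Landscape heterogeneity: %.4f (%d unlike of %d adjacencies, %s)\n",
              x$value, x$n_unlike, x$n_adjacencies, x$weighting))
  invisible(x)
}
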