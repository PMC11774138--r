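#' Min-max standardize selected columns of a feature matrix
#'
#' Rescales each named column to `[0, 1]` by `(x - min) / (max - min)`,
#' computed jointly across all rows (all sites and surveys), so values are
#' comparable with percent-cover columns. The per-column min and max are
#' kept as an attribute so new rows can be transformed identically.
#' Constant columns map to 0 with a warning.
#'
#' @param x A data frame or matrix.
#' @param columns Character vector of columns to standardize.
#' @param ranges Optional previously stored ranges (named list of
#'   `c(min, max)`) to reuse.
#' @return `x` with the named columns rescaled and an attribute
#'   `standardization` recording the ranges.
#' @export
minmax_standardize <- function(x, columns, ranges = NULL) {
  out <- x
  store <- list()
  for (cl in columns) {
    v <- out[[cl]]
    if (!is.numeric(v)) stop("column not numeric: ", cl, call. = FALSE)
    r <- if (!is.null(ranges)) ranges[[cl]] else range(v)
    if (diff(r) == 0) {
      warning("constant column mapped to 0: ", cl)
      out[[cl]] <- rep(0, length(v))
    } else {
      out[[cl]] <- (v - r[1]) / (r[2] - r[1])
    }
    store[[cl]] <- r
  }
  attr(out, "standardization") <- store
  out
}

#' Assemble the site x survey feature matrix
#'
#' Binds the 15 percent-cover columns with the four landscape/structure
#' descriptors (heterogeneity, 1 cm rugosity, 50 cm rugosity, fractal
#' dimension) and min-max standardizes the descriptors to `[0, 1]` across
#' all observations, matching the scaling used before computing
#' Bray-Curtis dissimilarities.
#'
#' @param obs A data frame with one row per site x survey holding the cover
#'   columns (percent) and the metric columns.
#' @param cover_columns Names of the cover columns (default
#'   [benthic_categories()]).
#' @param metric_columns Names of the descriptor columns.
#' @return A `feature_matrix` data frame (cover + standardized metrics)
#'   with id columns preserved and the standardization ranges attached.
#' @export
feature_matrix <- function(obs,
                           cover_columns = benthic_categories(),
                           metric_columns = c("heterogeneity",
                                              "rugosity_1cm",
                                              "rugosity_50cm",
                                              "fractal_dimension")) {
  missing_cols <- setdiff(c(cover_columns, metric_columns), names(obs))
  if (length(missing_cols))
    stop("missing feature columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (anyNA(obs[c(cover_columns, metric_columns)]))
    stop("feature matrix has missing values", call. = FALSE)
  out <- minmax_standardize(obs, metric_columns)
  attr(out, "cover_columns") <- cover_columns
  attr(out, "metric_columns") <- metric_columns
  class(out) <- c("feature_matrix", "data.frame")
  out
}

#' Numeric feature block of a feature matrix
#'
#' @param fm A `feature_matrix`.
#' @return Numeric matrix of cover + standardized metric columns.
#' @export
feature_values <- function(fm) {
  cols <- c(attr(fm, "cover_columns"), attr(fm, "metric_columns"))
  as.matrix(as.data.frame(fm)[cols])
}

#' Bray-Curtis dissimilarity matrix
#'
#' `BC(x, y) = sum |x_i - y_i| / sum (x_i + y_i)` between nonnegative
#' feature rows; bounded in `[0, 1]`, 0 for identical rows, 1 for disjoint
#' support. A pair of all-zero rows is assigned 0 with a warning.
#'
#' @param x A `feature_matrix`, data frame, or numeric matrix with
#'   nonnegative entries.
#' @return A `reef_dist` object: symmetric matrix with zero diagonal and a
#'   `metric` attribute `"bray_curtis"`.
#' @export
bray_curtis <- function(x) {
  m <- if (inherits(x, "feature_matrix")) feature_values(x) else as.matrix(x)
  if (any(m < 0)) stop("Bray-Curtis requires nonnegative entries",
                       call. = FALSE)
  num <- as.matrix(stats::dist(m, method = "manhattan"))
  rs <- rowSums(m)
  den <- outer(rs, rs, "+")
  bc <- num / den
  if (any(den == 0)) {
    warning("pair(s) with all-zero rows assigned dissimilarity 0")
    bc[den == 0] <- 0
  }
  diag(bc) <- 0
  rn <- rownames(m)
  if (is.null(rn)) rn <- as.character(seq_len(nrow(m)))
  dimnames(bc) <- list(rn, rn)
  structure(bc, metric = "bray_curtis", class = c("reef_dist", "matrix"))
}

#' Pairwise geographic distances (km) from planar or geographic coordinates
#'
#' Longitude/latitude pairs are converted to planar km by the
#' equirectangular approximation (adequate for extents up to ~100 km);
#' planar inputs are used as-is.
#'
#' @param coords Two-column matrix/data frame: `lon`/`lat` in decimal
#'   degrees (detected by column names or `lonlat = TRUE`) or planar km.
#' @param lonlat Force geographic interpretation.
#' @return A `reef_dist` matrix (km) with metric
#'   `"euclidean_geographic_km"`.
#' @export
geographic_distance <- function(coords, lonlat = NULL) {
  m <- as.matrix(coords)
  if (is.null(lonlat))
    lonlat <- all(c("lon", "lat") %in% tolower(colnames(m)))
  if (isTRUE(lonlat)) {
    lon <- m[, 1]; lat <- m[, 2]
    lat0 <- mean(lat) * pi / 180
    xy <- cbind(lon * cos(lat0), lat) * 111.32
  } else xy <- m
  d <- as.matrix(stats::dist(xy))
  structure(d, metric = "euclidean_geographic_km",
            class = c("reef_dist", "matrix"))
}

#' @export
print.reef_dist <- function(x, ...) {
  cat(sprintf("Distance matrix (%s): %d observations, range [%.4f, %.4f]\n",
              attr(x, "metric"), nrow(x), min(x[upper.tri(x)]),
              max(x[upper.tri(x)])))
  invisible(x)
}
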