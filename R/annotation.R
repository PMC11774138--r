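#' Stratified random point sample of a plot
#'
#' Divides the plot into a grid of equal strata and draws one uniform point
#' per cell. The default survey effort is 2500 points, a 50 x 50 grid of
#' 0.2 m cells on a 10 x 10 m plot. For rectangular plots the factor pair
#' `rows * cols = n` whose cell shape is closest to square is used; when no
#' factorization gives reasonably square cells (e.g. a prime `n`) a
#' near-square row-major grid is used instead, with a warning.
#'
#' @param spec A [plot_spec()].
#' @param n_points Number of points (default 2500).
#' @param seed Integer seed.
#' @return A `point_set` data frame with columns `x`, `y` and attributes
#'   `strata` (rows, cols) and `spec`. Cell membership uses half-open
#'   intervals `[x0, x1)`.
#' @export
stratified_random_points <- function(spec, n_points = 2500, seed = 1) {
  stopifnot(inherits(spec, "plot_spec"), n_points >= 1)
  set.seed(as.integer(seed))
  n <- as.integer(n_points)
  w <- spec$width; h <- spec$height

  divs <- which(n %% seq_len(n) == 0)
  rows_cand <- divs
  cols_cand <- n %/% divs
  # cell aspect = (w / cols) / (h / rows); penalty symmetric in log
  asp <- (w / cols_cand) / (h / rows_cand)
  pen <- pmax(asp, 1 / asp)
  best <- which.min(pen)

  if (pen[best] <= 2) {
    rows <- rows_cand[best]; cols <- cols_cand[best]
    cells <- seq_len(n)
  } else {
    rows <- max(1L, as.integer(round(sqrt(n * h / w))))
    cols <- as.integer(ceiling(n / rows))
    warning(sprintf(
      "n_points = %d has no near-square factorization for a %g x %g plot; using row-major %d x %d grid",
      n, w, h, rows, cols))
    cells <- seq_len(n)  # first n cells, row-major
  }
  cw <- w / cols; ch <- h / rows
  row_i <- (cells - 1L) %/% cols
  col_i <- (cells - 1L) %% cols
  x <- (col_i + stats::runif(n)) * cw
  y <- (row_i + stats::runif(n)) * ch
  out <- data.frame(x = x, y = y)
  attr(out, "strata") <- c(rows = rows, cols = cols)
  attr(out, "spec") <- spec
  class(out) <- c("point_set", "data.frame")
  out
}

#' Annotate sampled points against a label field
#'
#' Looks up the benthic label under every point and maps raw labels to the
#' analysis category set. Every raw label must be covered by the map: an
#' unmapped label is an error, never a silent drop.
#'
#' @param points A `point_set`.
#' @param field A `label_field`.
#' @param category_map Named character vector `raw label -> category`;
#'   `NULL` (default) keeps raw labels as categories.
#' @param categories Optional ordered category set for downstream cover
#'   vectors; defaults to the mapped field categories.
#' @return An `annotation_table` data frame with columns `site_id`,
#'   `survey_date`, `x`, `y`, `raw_label`, `category`.
#' @export
annotate_points <- function(points, field, category_map = NULL,
                            categories = NULL) {
  stopifnot(inherits(points, "point_set"), inherits(field, "label_field"))
  raw <- label_at(field, points$x, points$y)
  if (is.null(category_map)) {
    category <- raw
    if (is.null(categories)) categories <- field$categories
  } else {
    missing_lab <- setdiff(unique(raw), names(category_map))
    if (length(missing_lab))
      stop("unmapped raw label(s): ", paste(missing_lab, collapse = ", "),
           call. = FALSE)
    category <- unname(category_map[raw])
    if (is.null(categories)) categories <- unique(unname(category_map))
  }
  spec <- field$spec
  out <- data.frame(site_id = spec$site_id,
                    survey_date = spec$survey_date,
                    x = points$x, y = points$y,
                    raw_label = raw, category = category,
                    stringsAsFactors = FALSE)
  attr(out, "categories") <- categories
  class(out) <- c("annotation_table", "data.frame")
  out
}

#' Percent cover from an annotation table
#'
#' Cover of category i is `100 * count_i / n` over the configured category
#' set; categories absent from the table appear with 0 and the vector sums
#' to 100.
#'
#' @param table An `annotation_table` (or data frame with a `category`
#'   column).
#' @param categories Ordered category set; defaults to the table's
#'   `categories` attribute, else the observed categories.
#' @return Named numeric percent-cover vector with attributes `site_id` and
#'   `survey_date` when available.
#' @export
percent_cover <- function(table, categories = NULL) {
  if (nrow(table) == 0) stop("empty annotation table", call. = FALSE)
  if (is.null(categories)) categories <- attr(table, "categories")
  if (is.null(categories)) categories <- sort(unique(table$category))
  extra <- setdiff(unique(table$category), categories)
  if (length(extra))
    stop("categories outside the configured set: ",
         paste(extra, collapse = ", "), call. = FALSE)
  counts <- tabulate(match(table$category, categories),
                     nbins = length(categories))
  p <- 100 * counts / nrow(table)
  names(p) <- categories
  attr(p, "site_id") <- table$site_id[1]
  attr(p, "survey_date") <- table$survey_date[1]
  p
}
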