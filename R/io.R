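#' Write a depth surface as an ESRI ASCII grid
#'
#' @param surface A `depth_surface`.
#' @param path Output `.asc` path.
#' @export
write_ascii_grid <- function(surface, path) {
  z <- surface$z
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("ncols %d", ncol(z)),
               sprintf("nrows %d", nrow(z)),
               "xllcorner 0", "yllcorner 0",
               sprintf("cellsize %.10g", surface$cell_size),
               "NODATA_value -9999"), con)
  # ESRI grids store the top row first; rows of z run south to north
  for (r in rev(seq_len(nrow(z))))
    writeLines(paste(format(z[r, ], digits = 10, trim = TRUE),
                     collapse = " "), con)
  invisible(path)
}

#' Read an ESRI ASCII grid as a depth surface
#'
#' @param path `.asc` path.
#' @return A `depth_surface`.
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  vals <- scan(text = lines[i:length(lines)], quiet = TRUE)
  nr <- hdr$nrows; nc <- hdr$ncols
  z <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  z <- z[rev(seq_len(nr)), , drop = FALSE]   # back to south-first rows
  cs <- hdr$cellsize
  structure(list(z = z, cell_size = cs, width = (nc - 1) * cs,
                 height = (nr - 1) * cs, hurst = NA, amplitude = NA,
                 spec = plot_spec((nc - 1) * cs, (nr - 1) * cs)),
            class = "depth_surface")
}

#' Write a reef plot bundle to a directory
#'
#' One directory per site per survey: `annotations.csv` (site_id,
#' survey_date, x_m, y_m, raw_label, category), `depth.asc` (ESRI ASCII
#' grid), `metadata.csv`, and `manifest.json` listing the bundle.
#'
#' @param plot A [reef_plot()] with annotations (and optionally a surface).
#' @param dir Output directory (created if needed).
#' @export
write_reef_bundle <- function(plot, dir) {
  stopifnot(inherits(plot, "reef_plot"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  if (!is.null(plot$annotations)) {
    ann <- plot$annotations
    out <- data.frame(site_id = ann$site_id, survey_date = ann$survey_date,
                      x_m = ann$x, y_m = ann$y, raw_label = ann$raw_label,
                      category = ann$category)
    utils::write.csv(out, file.path(dir, "annotations.csv"),
                     row.names = FALSE)
    files <- c(files, "annotations.csv")
  }
  if (!is.null(plot$surface)) {
    write_ascii_grid(plot$surface, file.path(dir, "depth.asc"))
    files <- c(files, "depth.asc")
  }
  meta <- data.frame(
    site_id = plot$spec$site_id, island = plot$spec$island,
    survey_date = format(plot$spec$survey_date),
    width_m = plot$spec$width, height_m = plot$spec$height)
  utils::write.csv(meta, file.path(dir, "metadata.csv"), row.names = FALSE)
  files <- c(files, "metadata.csv")
  jsonlite::write_json(list(site_id = plot$spec$site_id,
                            survey_date = format(plot$spec$survey_date),
                            files = files),
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Read the annotation table of a reef plot bundle
#'
#' @param path `annotations.csv` path (or bundle directory).
#' @param categories Optional ordered category set.
#' @return An `annotation_table`.
#' @export
read_annotations <- function(path, categories = NULL) {
  if (dir.exists(path)) path <- file.path(path, "annotations.csv")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- data.frame(site_id = df$site_id,
                    survey_date = as.Date(df$survey_date),
                    x = df$x_m, y = df$y_m, raw_label = df$raw_label,
                    category = df$category, stringsAsFactors = FALSE)
  attr(out, "categories") <- if (is.null(categories))
    sort(unique(out$category)) else categories
  class(out) <- c("annotation_table", "data.frame")
  out
}

#' Write / read a distance matrix as square CSV
#'
#' Header row and first column carry observation IDs.
#'
#' @param d A `reef_dist` matrix.
#' @param path CSV path.
#' @export
write_distance_csv <- function(d, path) {
  m <- as.matrix(d)
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_distance_csv
#' @param metric Metric tag to attach on read.
#' @export
read_distance_csv <- function(path, metric = "bray_curtis") {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  structure(m, metric = metric, class = c("reef_dist", "matrix"))
}

#' Export a dendrogram as Newick with merge heights as branch lengths
#'
#' @param assignment A `regime_assignment` (or `hclust`).
#' @param path Output `.nwk` path.
#' @export
write_newick <- function(assignment, path) {
  if (!requireNamespace("ape", quietly = TRUE))
    stop("the ape package is required for Newick export", call. = FALSE)
  tree <- if (inherits(assignment, "hclust")) assignment else assignment$tree
  ape::write.tree(ape::as.phylo(tree), file = path)
  invisible(path)
}

#' Export a labelled tessellation as GeoJSON
#'
#' Each Voronoi cell becomes a Polygon feature with `site_index` and
#' `category` properties.
#'
#' @param tess A `reef_tessellation`.
#' @param path Output `.geojson` path.
#' @export
write_geojson <- function(tess, path) {
  stopifnot(inherits(tess, "reef_tessellation"))
  feats <- lapply(seq_along(tess$polygons), function(i) {
    pm <- tess$polygons[[i]]
    ring <- rbind(pm, pm[1, , drop = FALSE])
    list(type = "Feature",
         properties = list(site_index = i,
                           category = if (!is.null(tess$labels))
                             tess$labels[i] else NA),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                                                   function(k) ring[k, ]))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a test result as JSON
#'
#' @param result A `reef_anosim`, `reef_permanova`, `mantel_correlogram`,
#'   or `rate_comparison` object.
#' @param path Output path.
#' @param seed Seed to record.
#' @export
write_result_json <- function(result, path, seed = NA) {
  x <- unclass(result)
  x$seed <- seed
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE, dataframe = "columns")
  invisible(path)
}
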