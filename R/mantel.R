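#' Mantel correlogram of community dissimilarity against distance classes
#'
#' Tests spatial autocorrelation of community structure: geographic pair
#' distances are binned into classes (Sturges' rule by default) and, per
#' class, a Mantel correlation is computed between the community
#' dissimilarities and membership of that class. The sign convention is
#' ecological: positive r means observations in the class are *more similar*
#' than expected (r is minus the Pearson correlation between community
#' dissimilarity and class membership). Per-class
#' permutation p-values (two-sided, add-one) are corrected progressively in
#' increasing class order (Holm within the first k classes for class k).
#'
#' @param d_community Community dissimilarity matrix.
#' @param coords Observation coordinates: two-column planar km matrix,
#'   lon/lat (see [geographic_distance()]), or a precomputed distance
#'   matrix.
#' @param n_classes Number of distance classes or `"auto"` (Sturges on the
#'   pair count).
#' @param n_permutations Default 999.
#' @param correction `"holm_progressive"` (default) or `"none"`.
#' @param seed Integer seed.
#' @return A `mantel_correlogram` object with a `classes` data frame:
#'   break points, midpoint, pair count, Mantel r, raw and corrected p,
#'   and a `tested` flag (classes with < 2 pairs are skipped).
#' @export
mantel_correlogram <- function(d_community, coords, n_classes = "auto",
                               n_permutations = 999,
                               correction = c("holm_progressive", "none"),
                               seed = 1) {
  correction <- match.arg(correction)
  D <- as.matrix(if (inherits(d_community, "dist")) as.matrix(d_community)
                 else d_community)
  n <- nrow(D)
  Geo <- if (is.matrix(coords) && nrow(coords) == ncol(coords) &&
             isTRUE(all.equal(unname(coords), unname(t(coords)))))
    as.matrix(coords) else as.matrix(geographic_distance(coords))
  if (nrow(Geo) != n)
    stop("coordinates must cover every observation", call. = FALSE)

  lower <- which(lower.tri(D))
  dvec <- D[lower]
  gvec <- Geo[lower]
  if (identical(n_classes, "auto"))
    n_classes <- max(3L, as.integer(ceiling(log2(length(gvec)) + 1)))
  breaks <- seq(0, max(gvec) * (1 + 1e-9), length.out = n_classes + 1)
  cls <- cut(gvec, breaks, include.lowest = TRUE, labels = FALSE)

  set.seed(as.integer(seed))
  dperm <- vapply(seq_len(n_permutations), function(b) {
    p <- sample.int(n)
    D[p, p][lower]
  }, numeric(length(lower)))

  r <- p_raw <- rep(NA_real_, n_classes)
  tested <- rep(FALSE, n_classes)
  counts <- tabulate(cls, nbins = n_classes)
  for (k in seq_len(n_classes)) {
    ind <- as.numeric(cls == k)
    if (counts[k] < 2 || stats::sd(ind) == 0) next
    tested[k] <- TRUE
    r[k] <- -stats::cor(dvec, ind)
    cors <- as.vector(stats::cor(dperm, ind))
    exceed <- sum(abs(cors) >= abs(r[k]) - 1e-12)
    p_raw[k] <- (1 + exceed) / (1 + n_permutations)
  }

  p_adj <- p_raw
  if (correction == "holm_progressive") {
    tk <- which(tested)
    for (pos in seq_along(tk))
      p_adj[tk[pos]] <- stats::p.adjust(p_raw[tk[seq_len(pos)]],
                                        method = "holm")[pos]
  }

  classes <- data.frame(
    lower = breaks[-length(breaks)], upper = breaks[-1],
    midpoint = (breaks[-1] + breaks[-length(breaks)]) / 2,
    n_pairs = counts, mantel_r = r, p_value = p_raw,
    p_corrected = p_adj, tested = tested)
  structure(list(classes = classes, correction = correction,
                 n_permutations = n_permutations,
                 total_pairs = length(gvec)),
            class = "mantel_correlogram")
}

#' @export
print.mantel_correlogram <- function(x, ...) {
  cat(sprintf("Mantel correlogram: %d classes over %d pairs (%s correction)\n",
              nrow(x$classes), x$total_pairs, x$correction))
  tab <- x$classes
  tab$mantel_r <- round(tab$mantel_r, 4)
  print(tab, row.names = FALSE, digits = 4)
  invisible(x)
}
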