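#' Hierarchical clustering of observations into community regimes
#'
#' Agglomerative clustering of a dissimilarity matrix (complete linkage by
#' default, Ward's method as a robustness alternative) cut at `k` groups.
#' Three groups is the regional default: low-cover *Porites*, diverse
#' intermediate, and high-cover *Montipora* reefs.
#'
#' @param d A `reef_dist` matrix or `dist`.
#' @param linkage `"complete"` (default) or `"ward"` (Ward.D2 on
#'   dissimilarities).
#' @param k Number of groups to cut (default 3).
#' @return A `regime_assignment`: integer `labels` in `1..k` (ordered by
#'   first appearance), the `hclust` merge `tree`, `linkage`, and `k`.
#' @export
hierarchical_cluster <- function(d, linkage = c("complete", "ward"), k = 3) {
  linkage <- match.arg(linkage)
  dd <- if (inherits(d, "dist")) d else stats::as.dist(as.matrix(d))
  n <- attr(dd, "Size")
  if (k > n) stop("k exceeds the number of observations", call. = FALSE)
  method <- if (linkage == "ward") "ward.D2" else "complete"
  tree <- stats::hclust(dd, method = method)
  labels <- stats::cutree(tree, k = k)
  structure(list(labels = unname(labels), k = k, linkage = linkage,
                 tree = tree, ids = attr(dd, "Labels")),
            class = "regime_assignment")
}

#' @export
print.regime_assignment <- function(x, ...) {
  cat(sprintf("Regime assignment: %d observations in %d groups (%s linkage)\n",
              length(x$labels), x$k, x$linkage))
  print(table(regime = x$labels))
  invisible(x)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two clusterings: 1 for identical
#' partitions (up to relabeling), ~0 for independent ones.
#'
#' @param a,b Integer or factor label vectors of equal length.
#' @return Numeric scalar.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)
  (sum_ij - expected) / (max_idx - expected)
}
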