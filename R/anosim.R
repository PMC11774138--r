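#' Analysis of similarities (ANOSIM)
#'
#' Rank-based test of whether dissimilarities between groups exceed those
#' within groups. All `M = n(n-1)/2` pairwise dissimilarities are ranked
#' (mid-ranks for ties) and `R = (r_between - r_within) / (M / 2)`, which is
#' 1 under perfect separation and near 0 without structure. Significance is
#' assessed by freely permuting the group labels (default 9999
#' permutations, add-one p-value); when the number of distinct label
#' arrangements is at most 10000 the full enumeration is used and the
#' p-value is exact.
#'
#' @param d Dissimilarity matrix (`reef_dist`, `dist`, or matrix).
#' @param groups Group labels, one per observation; every group needs at
#'   least 2 members.
#' @param n_permutations Number of free permutations (default 9999).
#' @param seed Integer seed.
#' @return A `reef_anosim` object: `statistic` (R), `p_value`, `method`
#'   (`"exact"` or `"permutation"`), `n_permutations`, mean between/within
#'   ranks, and `M`.
#' @export
reef_anosim <- function(d, groups, n_permutations = 9999, seed = 1) {
  D <- as.matrix(if (inherits(d, "dist")) as.matrix(d) else d)
  n <- nrow(D)
  groups <- as.factor(groups)
  if (length(groups) != n) stop("groups must match observations", call. = FALSE)
  sizes <- table(groups)
  if (length(sizes) < 2) stop("need >= 2 groups", call. = FALSE)
  if (any(sizes < 2)) stop("every group needs >= 2 members", call. = FALSE)

  lower <- which(lower.tri(D))
  rk <- rank(D[lower])                  # mid-ranks for ties
  M <- length(rk)
  pair <- which(lower.tri(D), arr.ind = TRUE)

  r_stat <- function(g) {
    within <- g[pair[, 1]] == g[pair[, 2]]
    (mean(rk[!within]) - mean(rk[within])) / (M / 2)
  }
  obs <- r_stat(as.integer(groups))

  n_distinct <- .multinomial_count(as.integer(sizes))
  if (!is.na(n_distinct) && n_distinct <= 10000) {
    perms <- .group_assignments(as.integer(sizes))
    stats_all <- apply(perms, 2, r_stat)
    p <- mean(stats_all >= obs - 1e-12)   # observed included: exact, never 0
    method <- "exact"
    n_used <- ncol(perms)
    rb <- mean(rk[groups[pair[, 1]] != groups[pair[, 2]]])
    rw <- mean(rk[groups[pair[, 1]] == groups[pair[, 2]]])
  } else {
    set.seed(as.integer(seed))
    g0 <- as.integer(groups)
    exceed <- 0L
    for (b in seq_len(n_permutations)) {
      if (r_stat(sample(g0)) >= obs - 1e-12) exceed <- exceed + 1L
    }
    p <- (1 + exceed) / (1 + n_permutations)
    method <- "permutation"
    n_used <- n_permutations
    rb <- mean(rk[groups[pair[, 1]] != groups[pair[, 2]]])
    rw <- mean(rk[groups[pair[, 1]] == groups[pair[, 2]]])
  }
  structure(list(statistic = obs, p_value = p, method = method,
                 n_permutations = n_used, mean_rank_between = rb,
                 mean_rank_within = rw, M = M, groups = groups),
            class = "reef_anosim")
}

# number of distinct assignments of labelled groups to positions
.multinomial_count <- function(sizes) {
  v <- exp(lgamma(sum(sizes) + 1) - sum(lgamma(sizes + 1)))
  if (!is.finite(v)) NA_real_ else round(v)
}

# enumerate all assignments of group labels (1, 2, ...) with given sizes;
# returns an integer matrix, one assignment per column
.group_assignments <- function(sizes) {
  n <- sum(sizes)
  rec <- function(free, sizes_left, g) {
    if (length(sizes_left) == 1) {
      out <- matrix(0L, n, 1)
      out[free, 1] <- g
      return(out)
    }
    ch <- utils::combn(free, sizes_left[1])
    cols <- lapply(seq_len(ncol(ch)), function(k) {
      sub <- rec(setdiff(free, ch[, k]), sizes_left[-1], g + 1L)
      sub[ch[, k], ] <- g
      sub
    })
    do.call(cbind, cols)
  }
  rec(seq_len(n), sizes, 1L)
}

#' @export
print.reef_anosim <- function(x, ...) {
  cat(sprintf("ANOSIM: R = %.4f, p = %.4g (%s, %d %s)\n",
              x$statistic, x$p_value, x$method, x$n_permutations,
              if (x$method == "exact") "arrangements" else "permutations"))
  invisible(x)
}
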