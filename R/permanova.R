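#' Permutational multivariate analysis of variance (PERMANOVA)
#'
#' Partitions the total sum of squares of a dissimilarity matrix among the
#' terms of a model formula. The matrix is Gower-centered
#' (`G = -1/2 C d^2 C`), terms are fitted sequentially (Type I) via
#' hat-matrix projections, and each term gets a pseudo-F and a partial R^2
#' (`SS_term / SS_total`); term R^2 plus residual R^2 sum to 1. On
#' Euclidean distances the decomposition equals the classical multivariate
#' ANOVA trace decomposition.
#'
#' P-values come from permutation: `"free"` permutes observations;
#' `"blocked_by_site"` is the repeated-measures scheme for fixed sites
#' resurveyed over time - whole sites are exchanged (all surveys of a site
#' move together, permuted among sites with equal survey counts), keeping
#' the within-site structure intact.
#'
#' @param d Dissimilarity matrix (`reef_dist`, `dist`, or matrix).
#' @param formula Right-hand-side formula over columns of `data`, e.g.
#'   `~ island + irradiance`. Order matters (sequential fitting).
#' @param data Data frame of covariates/factors, one row per observation.
#' @param n_permutations Default 999.
#' @param scheme `"free"` or `"blocked_by_site"`.
#' @param site Site identifier per observation (required for the blocked
#'   scheme).
#' @param seed Integer seed.
#' @return A `reef_permanova` object with an `aov_table` data frame (df,
#'   SS, pseudo-F, R2, p per term plus residual and total rows), the
#'   permutation scheme, and seed.
#' @export
reef_permanova <- function(d, formula, data, n_permutations = 999,
                           scheme = c("free", "blocked_by_site"),
                           site = NULL, seed = 1) {
  scheme <- match.arg(scheme)
  D <- as.matrix(if (inherits(d, "dist")) as.matrix(d) else d)
  n <- nrow(D)
  if (nrow(data) != n) stop("data must have one row per observation",
                            call. = FALSE)
  if (scheme == "blocked_by_site" && is.null(site))
    stop("blocked_by_site scheme requires site labels", call. = FALSE)

  # Gower-centered inner-product matrix
  A <- -0.5 * D^2
  G <- sweep(sweep(A, 1, rowMeans(A)), 2, colMeans(A)) + mean(A)
  ss_total <- sum(diag(G))

  tl <- attr(stats::terms(formula), "term.labels")
  if (length(tl) == 0) stop("formula has no terms", call. = FALSE)
  mm_full <- stats::model.matrix(formula, data)
  qr_full <- qr(mm_full)
  if (qr_full$rank < ncol(mm_full)) {
    aliased <- colnames(mm_full)[qr_full$pivot[-seq_len(qr_full$rank)]]
    stop("rank-deficient design; aliased: ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }

  # cumulative hat matrices H_0 (intercept) .. H_p (full model)
  hats <- vector("list", length(tl) + 1)
  dfs <- integer(length(tl))
  prev_rank <- 1L
  hats[[1]] <- matrix(1 / n, n, n)
  for (k in seq_along(tl)) {
    fk <- stats::reformulate(tl[seq_len(k)])
    mmk <- stats::model.matrix(fk, data)
    qk <- qr(mmk)
    Q <- qr.Q(qk)[, seq_len(qk$rank), drop = FALSE]
    hats[[k + 1]] <- tcrossprod(Q)
    dfs[k] <- qk$rank - prev_rank
    prev_rank <- qk$rank
  }
  df_res <- n - prev_rank

  trHG <- function(H, G) sum(H * G)    # tr(HG) for symmetric H, G
  decomp <- function(G) {
    ss <- numeric(length(tl))
    for (k in seq_along(tl))
      ss[k] <- trHG(hats[[k + 1]], G) - trHG(hats[[k]], G)
    # G is double-centered, so tr(G) excludes the grand mean already
    list(ss = ss, ss_res = sum(diag(G)) - sum(ss))
  }

  obs <- decomp(G)
  F_obs <- (obs$ss / dfs) / (obs$ss_res / df_res)

  set.seed(as.integer(seed))
  exceed <- rep(0L, length(tl))
  for (b in seq_len(n_permutations)) {
    p <- .permute_obs(n, scheme, site)
    Gp <- G[p, p]
    pd <- decomp(Gp)
    Fp <- (pd$ss / dfs) / (pd$ss_res / df_res)
    exceed <- exceed + (Fp >= F_obs - 1e-12)
  }
  pvals <- (1 + exceed) / (1 + n_permutations)

  tab <- data.frame(
    term = c(tl, "residual", "total"),
    df = c(dfs, df_res, n - 1),
    SS = c(obs$ss, obs$ss_res, ss_total),
    pseudo_F = c(F_obs, NA, NA),
    R2 = c(obs$ss, obs$ss_res, ss_total) / ss_total,
    p_value = c(pvals, NA, NA))
  structure(list(aov_table = tab, scheme = scheme,
                 n_permutations = n_permutations, seed = seed),
            class = "reef_permanova")
}

# observation permutation under the chosen exchangeability scheme
.permute_obs <- function(n, scheme, site) {
  if (scheme == "free") return(sample.int(n))
  site <- as.character(site)
  idx_by_site <- split(seq_len(n), site)
  sizes <- lengths(idx_by_site)
  p <- seq_len(n)
  for (sz in unique(sizes)) {
    sites_sz <- names(sizes)[sizes == sz]
    if (length(sites_sz) < 2) next
    perm_sites <- sample(sites_sz)
    for (k in seq_along(sites_sz))
      p[idx_by_site[[sites_sz[k]]]] <- idx_by_site[[perm_sites[k]]]
  }
  p
}

#' @export
print.reef_permanova <- function(x, ...) {
  cat(sprintf("PERMANOVA (%s scheme, %d permutations)\n", x$scheme,
              x$n_permutations))
  tab <- x$aov_table
  tab$SS <- round(tab$SS, 4); tab$R2 <- round(tab$R2, 4)
  tab$pseudo_F <- round(tab$pseudo_F, 4)
  print(tab, row.names = FALSE)
  invisible(x)
}
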