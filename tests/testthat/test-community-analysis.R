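test_that("min-max standardization rescales jointly and keeps its ranges", {
  df <- data.frame(a = c(1.4, 1.8, 2.2), b = c(5, 5, 5))
  expect_warning(out <- minmax_standardize(df, c("a", "b")), "constant")
  expect_equal(out$a, c(0, 0.5, 1))
  expect_equal(out$b, c(0, 0, 0))
  rng <- attr(out, "standardization")
  expect_equal(rng$a, c(1.4, 2.2))
  # new rows transform identically under the stored ranges
  new <- minmax_standardize(data.frame(a = 1.8), "a", ranges = rng)
  expect_equal(new$a, 0.5)
})

test_that("Bray-Curtis matches hand values, bounds, and vegan", {
  m <- rbind(c(10, 0, 5), c(5, 5, 5))
  expect_equal(bray_curtis(m)[1, 2], 10 / 30)
  same <- rbind(c(3, 1), c(3, 1))
  expect_equal(bray_curtis(same)[1, 2], 0)
  disj <- rbind(c(1, 0), c(0, 2))
  expect_equal(bray_curtis(disj)[1, 2], 1)
  expect_error(bray_curtis(rbind(c(-1, 2), c(1, 1))), "nonnegative")
  expect_warning(bray_curtis(rbind(c(0, 0), c(0, 0), c(1, 2))), "all-zero")

  skip_if_not_installed("vegan")
  set.seed(3)
  mm <- matrix(abs(rnorm(8 * 5)), 8)
  expect_equal(unname(as.matrix(bray_curtis(mm))),
               unname(as.matrix(vegan::vegdist(mm, "bray"))),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("complete-linkage merge heights equal hand agglomeration", {
  # d(a,b)=1, d(c,d)=2, all cross pairs >= 5: merges at 1, 2, then max = 8
  D <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  D["a", "b"] <- 1; D["c", "d"] <- 2
  D["a", "c"] <- 5; D["a", "d"] <- 6; D["b", "c"] <- 7; D["b", "d"] <- 8
  D <- D + t(D)
  cl <- hierarchical_cluster(D, "complete", k = 2)
  expect_equal(cl$tree$height, c(1, 2, 8))
  expect_equal(cl$labels, c(1, 1, 2, 2))

  expect_error(hierarchical_cluster(D, k = 5), "exceeds")
  tiny <- hierarchical_cluster(D[1:2, 1:2], k = 2)
  expect_equal(sort(unique(tiny$labels)), c(1, 2))
})

test_that("clustering recovers well-separated synthetic groups either linkage", {
  set.seed(7)
  centers <- rbind(c(0, 0), c(10, 0), c(0, 10))
  truth <- rep(1:3, each = 8)
  pts <- centers[truth, ] + matrix(rnorm(48, sd = 0.5), ncol = 2)
  d <- euclid_dist(pts)
  for (link in c("complete", "ward")) {
    cl <- hierarchical_cluster(d, link, k = 3)
    expect_equal(adjusted_rand_index(cl$labels, truth), 1)
  }
  skip_if_not_installed("mclust")
  # our ARI implementation agrees with the reference implementation
  set.seed(8)
  a <- sample(1:3, 30, TRUE); b <- sample(1:3, 30, TRUE)
  expect_equal(adjusted_rand_index(a, b), mclust::adjustedRandIndex(a, b))
})

test_that("NMDS embeds exact configurations and its stress trace never rises", {
  set.seed(5)
  xy <- matrix(rnorm(24), ncol = 2)
  d <- euclid_dist(xy)
  fit <- reef_nmds(d, seed = 1)
  expect_lt(fit$stress, 0.01)
  expect_true(all(diff(fit$stress_trace) <= 1e-12))

  expect_error(reef_nmds(d[1:2, 1:2], n_dim = 2), "n_dim")
})

test_that("NMDS stress is competitive with a many-restart oracle", {
  skip_if_not_installed("vegan")
  set.seed(11)
  m <- matrix(abs(rnorm(6 * 4)), 6)
  d <- bray_curtis(m)
  fit <- reef_nmds(d, n_restarts = 8, seed = 2)
  # oracle: best of 500 random-start monotone MDS runs
  set.seed(99)
  oracle <- min(sapply(1:500, function(i) {
    init <- matrix(rnorm(12), 6)
    vegan::monoMDS(stats::as.dist(d), y = init, k = 2, model = "global")$stress
  }))
  expect_lte(fit$stress, oracle + 0.005)
})

test_that("ANOSIM: perfect separation, vegan agreement, exact enumeration", {
  # two tight groups, all between > all within
  pts <- rbind(matrix(rnorm(8, sd = 0.01), 4), matrix(5 + rnorm(8, sd = 0.01), 4))
  d <- euclid_dist(pts)
  g <- rep(c("a", "b"), each = 4)
  res <- reef_anosim(d, g, seed = 1)
  expect_equal(res$statistic, 1)
  expect_equal(res$method, "exact")

  expect_error(reef_anosim(d, c(rep("a", 7), "b")), ">= 2 members")

  # full-enumeration oracle on n = 6, written independently
  set.seed(21)
  D6 <- as.matrix(dist(matrix(rnorm(12), 6)))
  g6 <- rep(c("x", "y"), each = 3)
  res6 <- reef_anosim(D6, g6)
  rk <- rank(D6[lower.tri(D6)])
  pair <- which(lower.tri(D6), arr.ind = TRUE)
  M <- length(rk)
  r_of <- function(lab) {
    w <- lab[pair[, 1]] == lab[pair[, 2]]
    (mean(rk[!w]) - mean(rk[w])) / (M / 2)
  }
  splits <- combn(6, 3)
  all_r <- apply(splits, 2, function(ix) {
    lab <- rep("y", 6); lab[ix] <- "x"
    r_of(lab)
  })
  expect_equal(res6$n_permutations, 20)
  expect_equal(res6$statistic, r_of(g6))
  expect_equal(res6$p_value, mean(all_r >= r_of(g6) - 1e-12))

  skip_if_not_installed("vegan")
  set.seed(4)
  m <- matrix(abs(rnorm(24 * 5)), 24)
  gg <- rep(letters[1:3], each = 8)
  dd <- bray_curtis(m)
  ours <- reef_anosim(dd, gg, n_permutations = 199, seed = 5)
  ref <- vegan::anosim(stats::as.dist(dd), gg, permutations = 99)
  expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-12)
})

test_that("ANOSIM is centred on zero for structureless data", {
  rs <- sapply(1:200, function(s) {
    set.seed(s)
    m <- matrix(rnorm(10 * 3), 10)
    g <- rep(c("a", "b"), each = 5)
    reef_anosim(euclid_dist(m), g, n_permutations = 0 + 19, seed = s)$statistic
  })
  expect_lt(abs(mean(rs)), 0.05)
})

test_that("PERMANOVA reproduces the classical decomposition on Euclidean data", {
  set.seed(9)
  y <- matrix(rnorm(30), 10, 3)
  grp <- factor(rep(1:2, each = 5))
  d <- euclid_dist(y)
  fit <- reef_permanova(d, ~ grp, data.frame(grp = grp),
                        n_permutations = 99, seed = 1)
  # classical MANOVA trace decomposition from the raw coordinates
  X <- model.matrix(~ grp)
  H <- X %*% solve(crossprod(X)) %*% t(X)
  Yc <- scale(y, scale = FALSE)
  ssb <- sum(diag(t(Yc) %*% (H - 1 / 10) %*% Yc))
  sst <- sum(Yc^2)
  expect_equal(fit$aov_table$SS[1], ssb, tolerance = 1e-8)
  expect_equal(fit$aov_table$SS[3], sst, tolerance = 1e-8)
  F_classic <- (ssb / 1) / ((sst - ssb) / 8)
  expect_equal(fit$aov_table$pseudo_F[1], F_classic, tolerance = 1e-8)

  # R2 partition sums to one
  expect_equal(sum(fit$aov_table$R2[1:2]), 1, tolerance = 1e-9)

  # sequential terms against the vegan reference
  skip_if_not_installed("vegan")
  set.seed(10)
  m <- matrix(abs(rnorm(20 * 4)), 20)
  fac <- factor(rep(1:2, each = 10)); cv <- rnorm(20)
  dbc <- bray_curtis(m)
  ours <- reef_permanova(dbc, ~ fac + cv, data.frame(fac = fac, cv = cv),
                         n_permutations = 99, seed = 2)
  ref <- vegan::adonis2(stats::as.dist(dbc) ~ fac + cv,
                        data = data.frame(fac = fac, cv = cv),
                        permutations = 99, by = "terms")
  expect_equal(ours$aov_table$SS[1:3], ref$SumOfSqs[1:3], tolerance = 1e-10)
  expect_equal(ours$aov_table$pseudo_F[1:2], ref$F[1:2], tolerance = 1e-10)

  expect_error(reef_permanova(d, ~ grp + grp2,
                              data.frame(grp = grp,
                                         grp2 = factor(rep(1:2, each = 5))),
                              n_permutations = 9),
               "aliased")
})

test_that("blocked permutation keeps surveys of a site together", {
  # strong site effect, null group factor at site level
  set.seed(13)
  n_site <- 8; n_srv <- 3
  site <- rep(paste0("s", 1:n_site), each = n_srv)
  site_mean <- rnorm(n_site, sd = 3)[rep(1:n_site, each = n_srv)]
  y <- site_mean + rnorm(n_site * n_srv, sd = 0.3)
  grp <- factor(rep(rep(c("a", "b"), each = n_srv), n_site / 2))
  # grp is balanced within the region but constant within each site
  grp_site <- factor(rep(c("a", "b"), n_site / 2)[rep(1:n_site, each = n_srv)])
  d <- euclid_dist(cbind(y))
  fit <- reef_permanova(d, ~ grp_site, data.frame(grp_site = grp_site),
                        n_permutations = 199, scheme = "blocked_by_site",
                        site = site, seed = 3)
  expect_true(fit$aov_table$p_value[1] > 0.025)
  # determinism under the same seed
  fit2 <- reef_permanova(d, ~ grp_site, data.frame(grp_site = grp_site),
                         n_permutations = 199, scheme = "blocked_by_site",
                         site = site, seed = 3)
  expect_identical(fit$aov_table, fit2$aov_table)
  expect_error(reef_permanova(d, ~ grp_site,
                              data.frame(grp_site = grp_site),
                              scheme = "blocked_by_site"),
               "site labels")
})

test_that("Mantel correlogram partitions pairs and finds planted structure", {
  set.seed(17)
  n <- 20
  coords <- cbind(runif(n, 0, 30), runif(n, 0, 30))
  feats <- matrix(abs(rnorm(n * 4)), n)
  d <- bray_curtis(feats)
  mc <- mantel_correlogram(d, coords, n_permutations = 99, seed = 1)
  expect_equal(sum(mc$classes$n_pairs), n * (n - 1) / 2)
  expect_true(all(abs(mc$classes$mantel_r[mc$classes$tested]) <= 1))

  # planted autocorrelation: two spatial blobs with distinct communities
  blob <- rep(1:2, each = 10)
  coords2 <- cbind(ifelse(blob == 1, 0, 40) + runif(n, 0, 3),
                   runif(n, 0, 3))
  feats2 <- matrix(abs(rnorm(n * 4)), n) + 5 * (blob == 1)
  mc2 <- mantel_correlogram(bray_curtis(feats2), coords2,
                            n_classes = 4, n_permutations = 199, seed = 2)
  first <- which(mc2$classes$tested)[1]
  expect_gt(mc2$classes$mantel_r[first], 0)
  expect_lt(mc2$classes$p_corrected[first], 0.05)
})
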