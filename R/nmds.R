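#' Non-metric multidimensional scaling (Kruskal stress-1)
#'
#' Embeds a dissimilarity matrix in `n_dim` dimensions by minimizing
#' Kruskal's stress-1, alternating monotone (isotonic) regression of the
#' configuration distances on the dissimilarity ranks with Guttman-transform
#' configuration updates (non-metric SMACOF). One metric start (classical
#' scaling) plus `n_restarts - 1` seeded random starts are run and the best
#' configuration is returned; within a run the accepted stress trace is
#' non-increasing.
#'
#' @param d Symmetric dissimilarity matrix (`reef_dist`, `dist`, or
#'   matrix).
#' @param n_dim Embedding dimension (default 2).
#' @param n_restarts Total starts (default 8).
#' @param max_iter Iteration cap per start (default 500).
#' @param tol Stop when the stress improvement drops below this (default
#'   1e-6).
#' @param seed Integer seed for the random starts.
#' @return A `reef_nmds` object: `points` (n x n_dim), `stress` (stress-1),
#'   `converged`, `n_restarts`, and the accepted `stress_trace` of the best
#'   start.
#' @export
reef_nmds <- function(d, n_dim = 2, n_restarts = 8, max_iter = 500,
                      tol = 1e-6, seed = 1) {
  D <- as.matrix(if (inherits(d, "dist")) as.matrix(d) else d)
  n <- nrow(D)
  if (n < n_dim + 1) stop("need at least n_dim + 1 observations",
                          call. = FALSE)
  lower <- which(lower.tri(D))
  dvec <- D[lower]
  set.seed(as.integer(seed))

  starts <- vector("list", n_restarts)
  cm <- suppressWarnings(stats::cmdscale(D, k = n_dim))
  if (ncol(cm) < n_dim)
    cm <- cbind(cm, matrix(0, n, n_dim - ncol(cm)))
  starts[[1]] <- cm
  if (n_restarts > 1)
    for (s in 2:n_restarts) starts[[s]] <- matrix(stats::rnorm(n * n_dim), n)

  best <- NULL
  for (X0 in starts) {
    run <- .nmds_run(X0, dvec, lower, n, n_dim, max_iter, tol)
    if (is.null(best) || run$stress < best$stress) best <- run
  }
  structure(list(points = best$X, stress = best$stress,
                 converged = best$converged, n_restarts = n_restarts,
                 stress_trace = best$trace),
            class = "reef_nmds")
}

.nmds_run <- function(X, dvec, lower, n, k, max_iter, tol) {
  cd_vec <- function(X) {
    cd <- as.matrix(stats::dist(X))[lower]
    pmax(cd, 1e-12)
  }
  stress1 <- function(cd, dhat) sqrt(sum((cd - dhat)^2) / sum(cd^2))

  cd <- cd_vec(X)
  trace <- numeric(0)
  prev <- Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    ord <- order(dvec, cd)               # primary approach to ties
    dhat <- numeric(length(cd))
    dhat[ord] <- stats::isoreg(cd[ord])$yf
    s <- stress1(cd, dhat)
    if (s > prev + 1e-12) break          # keep the previous (better) config
    trace <- c(trace, s)
    if (prev - s < tol) { converged <- TRUE; prev <- s; Xbest <- X; break }
    prev <- s
    Xbest <- X
    # Guttman transform with target distances dhat
    Dhat <- matrix(0, n, n); Dhat[lower] <- dhat
    CD <- matrix(0, n, n); CD[lower] <- cd
    Dhat <- Dhat + t(Dhat); CD <- CD + t(CD)
    B <- -Dhat / pmax(CD, 1e-12)
    diag(B) <- 0
    diag(B) <- -rowSums(B)
    X <- (B %*% X) / n
    cd <- cd_vec(X)
  }
  if (!exists("Xbest", inherits = FALSE)) { Xbest <- X; prev <- stress1(cd, cd) }
  list(X = Xbest, stress = prev, converged = converged, trace = trace)
}

#' @export
print.reef_nmds <- function(x, ...) {
  cat(sprintf("NMDS: %d points in %d dimensions, stress-1 = %.4f (%s, %d starts)\n",
              nrow(x$points), ncol(x$points), x$stress,
              if (x$converged) "converged" else "not converged",
              x$n_restarts))
  invisible(x)
}
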