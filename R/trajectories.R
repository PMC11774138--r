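#' Monthly rates of change between consecutive surveys
#'
#' Converts a per-survey measurement series into per-timestep monthly
#' rates, `(v[t+1] - v[t]) / months`, where a month is fixed at 30.4375
#' days so unevenly spaced surveys are comparable.
#'
#' @param values Numeric per-survey measurements (e.g. percent coral cover
#'   or 1 cm rugosity).
#' @param dates Survey dates (`Date`), strictly increasing.
#' @return A `rate_series` data frame: `timestep`, `start_date`,
#'   `end_date`, `months`, `rate` (units per month).
#' @export
monthly_rate <- function(values, dates) {
  dates <- as.Date(dates)
  if (length(values) != length(dates) || length(values) < 2)
    stop("need >= 2 surveys with matching dates", call. = FALSE)
  dd <- as.numeric(diff(dates))
  if (any(dd == 0)) stop("duplicate survey dates", call. = FALSE)
  if (any(dd < 0)) stop("dates must be strictly increasing", call. = FALSE)
  months <- dd / 30.4375
  out <- data.frame(timestep = seq_along(months),
                    start_date = dates[-length(dates)],
                    end_date = dates[-1],
                    months = months,
                    rate = diff(values) / months)
  class(out) <- c("rate_series", "data.frame")
  out
}

#' Detect community-type transitions in a regime label series
#'
#' Records every change between consecutive survey labels. Timestep `t` is
#' the interval ending at survey `t + 1`.
#'
#' @param labels Per-survey regime labels (>= 2 surveys).
#' @return A `transition_record`: data frame of (`from`, `to`, `timestep`)
#'   plus `n_transitions`.
#' @export
detect_transitions <- function(labels) {
  if (length(labels) < 2) stop("need >= 2 surveys", call. = FALSE)
  labels <- as.character(labels)
  chg <- which(labels[-1] != labels[-length(labels)])
  trans <- data.frame(from = labels[chg], to = labels[chg + 1],
                      timestep = chg)
  structure(list(transitions = trans, n_transitions = nrow(trans),
                 labels = labels),
            class = "transition_record")
}

#' @export
print.transition_record <- function(x, ...) {
  cat(sprintf("Transitions: %d over %d surveys (%s)\n", x$n_transitions,
              length(x$labels), paste(x$labels, collapse = " -> ")))
  invisible(x)
}

#' Geometry of an ordination trajectory
#'
#' Summarizes a site's path through ordination space across surveys: total
#' path length (sum of consecutive Euclidean steps), net displacement
#' (first to last), and directionality `net / path` in `[0, 1]` (1 for a
#' straight directional path, 0 for a closed loop; defined as 0 when the
#' path length is 0).
#'
#' @param coords Matrix/data frame of per-survey ordination coordinates
#'   (rows in survey order, >= 2 rows).
#' @return A list: `path`, `net`, `directionality`.
#' @export
trajectory_geometry <- function(coords) {
  m <- as.matrix(coords)
  if (nrow(m) < 2) stop("need >= 2 surveys with coordinates", call. = FALSE)
  steps <- sqrt(rowSums(diff(m)^2))
  path <- sum(steps)
  net <- sqrt(sum((m[nrow(m), ] - m[1, ])^2))
  list(path = path, net = net,
       directionality = if (path > 0) net / path else 0)
}

#' Permutation comparison of change rates between groupings
#'
#' Quantifies how much of the variance in per-timestep monthly rates a
#' grouping (community regime or island) explains, as
#' `eta^2 = SS_between / SS_total`, with a permutation p-value obtained by
#' reassigning group labels across sites - a site's full rate series moves
#' as a unit, respecting the repeated-measures structure. Calling it once
#' per grouping makes "regime explains more than island" a direct
#' comparison of the two eta^2 values.
#'
#' @param rates Data frame with columns `site`, `group`, `rate` (one row
#'   per site x timestep; a single timestep is fine).
#' @param n_permutations Default 999.
#' @param seed Integer seed.
#' @return A `rate_comparison`: `eta_sq`, `p_value`, group means, and the
#'   permutation count.
#' @export
group_rate_comparison <- function(rates, n_permutations = 999, seed = 1) {
  stopifnot(all(c("site", "group", "rate") %in% names(rates)))
  site_group <- unique(rates[c("site", "group")])
  if (anyDuplicated(site_group$site))
    stop("each site must belong to exactly one group", call. = FALSE)
  sizes <- table(site_group$group)
  if (length(sizes) < 2 || any(sizes < 2))
    stop("need >= 2 groups with >= 2 sites each", call. = FALSE)

  eta_sq <- function(g) {
    mu <- mean(rates$rate)
    ssb <- sum(tapply(rates$rate, g, function(v) length(v) * (mean(v) - mu)^2))
    sst <- sum((rates$rate - mu)^2)
    if (sst == 0) return(0)
    ssb / sst
  }
  obs <- eta_sq(rates$group)

  set.seed(as.integer(seed))
  g_site <- site_group$group
  exceed <- 0L
  for (b in seq_len(n_permutations)) {
    perm <- stats::setNames(sample(g_site), site_group$site)
    if (eta_sq(perm[as.character(rates$site)]) >= obs - 1e-12)
      exceed <- exceed + 1L
  }
  structure(list(eta_sq = obs,
                 p_value = (1 + exceed) / (1 + n_permutations),
                 group_means = tapply(rates$rate, rates$group, mean),
                 n_permutations = n_permutations),
            class = "rate_comparison")
}

#' @export
print.rate_comparison <- function(x, ...) {
  cat(sprintf("Rate comparison: eta^2 = %.4f, p = %.4g (%d permutations)\n",
              x$eta_sq, x$p_value, x$n_permutations))
  invisible(x)
}
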