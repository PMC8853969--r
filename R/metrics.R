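# Migration-path metrics: population center of mass, top-occupancy
# nodes, path statistics, and the availability-displacement relation.

#' Abundance-weighted population center of mass
#'
#' Weighted mean of node coordinates. For lon/lat grids the mean is
#' taken on the coordinates directly, which is adequate at continental
#' scale.
#'
#' @param ab abundance: vector per node, or a nodes x classes matrix
#'   (summed over classes).
#' @param coords data.frame or matrix with columns `x`, `y`.
#' @return numeric `c(x, y)`.
#' @export
center_of_mass <- function(ab, coords) {
  if (is.matrix(ab)) ab <- rowSums(ab)
  tot <- sum(ab)
  if (!(tot > 0)) stop("zero total abundance")
  c(sum(ab * coords[[1]]) / tot, sum(ab * coords[[2]]) / tot)
}

#' Most populous nodes of a day
#'
#' The `ceiling(pct * n)` nodes with the greatest abundance; ties are
#' broken by node id ascending.
#'
#' @param ab abundance vector per node.
#' @param pct fraction of nodes to keep (default 0.02).
#' @param node_id node identifiers (default 0-based positions).
#' @return vector of node ids.
#' @export
top_pct_nodes <- function(ab, pct = 0.02, node_id = seq_along(ab) - 1L) {
  stopifnot(length(ab) >= 1, pct > 0, pct <= 1)
  k <- ceiling(pct * length(ab))
  ord <- order(-ab, node_id)
  node_id[ord[seq_len(k)]]
}

#' Statistics of a center-of-mass track
#'
#' Mean consecutive-day displacement, north-south extent, and the nadir
#' (southernmost y/latitude) with its day.
#'
#' @param com matrix or data.frame of daily `c(x, y)` positions, in km
#'   (planar) or degrees.
#' @param planar if TRUE distances are Euclidean km; if FALSE
#'   consecutive displacements use the haversine (radius 6371 km).
#' @return list: `mean_step` (km or same units), `ns_extent`,
#'   `nadir_y`, `nadir_day`.
#' @export
path_statistics <- function(com, planar = TRUE) {
  com <- as.matrix(com)
  if (nrow(com) < 2) stop("need at least 2 days of positions")
  a <- com[-nrow(com), , drop = FALSE]
  b <- com[-1, , drop = FALSE]
  steps <- if (planar) sqrt(rowSums((b - a)^2))
           else geosphere::distHaversine(a, b, r = 6371000) / 1000
  y <- com[, 2]
  list(mean_step = mean(steps),
       ns_extent = if (planar) diff(range(y)) else diff(range(y)) * 111.19,
       nadir_y = min(y),
       nadir_day = which.min(y))
}

#' Displacement vs availability-variability relation across runs
#'
#' Ordinary least-squares fit of the mean daily center-of-mass
#' displacement against the standard deviation of the daily available
#' fraction, one point per run, with the adjusted R^2 of the
#' single-predictor model.
#'
#' @param sd_avail per-run SD of the daily available-habitat fraction.
#' @param mean_step per-run mean daily COM displacement.
#' @return list: `slope`, `intercept`, `adj_r2`, `fit` (the `lm`).
#' @export
availability_relation <- function(sd_avail, mean_step) {
  stopifnot(length(sd_avail) == length(mean_step))
  if (length(sd_avail) < 3) stop("need at least 3 runs")
  fit <- stats::lm(mean_step ~ sd_avail)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       adj_r2 = summary(fit)$adj.r.squared, fit = fit)
}
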