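# Departure probabilities, seasonal arrival weights, Cobb-Douglas
# attractiveness, the gamma movement kernel, and the redistribution step.

monod <- function(x, K, a) {
  x <- pmax(0, x)
  xa <- x^a
  r <- xa / (xa + pmax(0, K)^a)
  r[!is.finite(r)] <- 0       # degenerate half-saturation at x = 0
  r
}

#' Departure pressure from weather severity
#'
#' Monod curve in WSI with exponent 3 and half-saturation at the
#' availability threshold 7.5; mild weather (WSI <= 0) exerts no
#' departure pressure.
#'
#' @param wsi weather severity index (vectorised).
#' @param threshold half-saturation severity.
#' @param exponent Monod exponent.
#' @return probability in \[0, 1\].
#' @export
p_depart_wsi <- function(wsi, threshold = 7.5, exponent = 3) {
  monod(wsi, threshold, exponent)
}

#' Departure pressure from body condition
#'
#' Monod curve in the zero-based class index with exponent 8 and
#' half-saturation at `n_classes - 3`: the inflection is pronounced so
#' that essentially only birds in the top three classes feel strong
#' pressure to depart.
#'
#' @param class_j 1-based condition class index (1 = dead).
#' @param n_classes number of classes.
#' @param exponent Monod exponent.
#' @return probability in \[0, 1\].
#' @export
p_depart_bc <- function(class_j, n_classes = 21, exponent = 8) {
  monod(class_j - 1, n_classes - 3, exponent)
}

#' Departure pressure from distance to the breeding grounds
#'
#' Monod curve in the distance to the nearest breeding node with
#' exponent 5 and half-saturation at the cohort's flight range.
#'
#' @param db distance to nearest breeding node, km.
#' @param range flight range, km (> 0).
#' @param exponent Monod exponent.
#' @return probability in \[0, 1\].
#' @export
p_depart_db <- function(db, range, exponent = 5) {
  if (any(range <= 0)) stop("flight range must be positive")
  if (any(db < 0)) stop("negative breeding distance")
  monod(db, range, exponent)
}

#' Departure pressure from the local rate of daily gain
#'
#' Linear decreasing function `1 - (DG + 1)/5`, clamped to \[0, 1\].
#' With the default `"kj"` form, DG is the daily gain in kJ/day: the
#' component is 0.8 where nothing can be gained, falls linearly, and is
#' 0 wherever at least 4 kJ/day can be deposited — an essentially
#' binary "can I refuel here?" signal. The `"normalized"` form applies
#' the same expression to the min-max normalised daily gain instead
#' (0.8 at the worst node of the day down to 0.6 at the best), a
#' smoother alternative that presses every bird to move every day.
#'
#' @param dg daily gain: kJ/day (`"kj"` form; may be negative) or
#'   normalised to \[0, 1\] across the day's landscape (`"normalized"`).
#' @param form which reading of the departure expression to use.
#' @return probability in \[0, 1\].
#' @export
p_depart_dg <- function(dg, form = c("kj", "normalized")) {
  form <- match.arg(form)
  if (form == "normalized")
    stopifnot(all(dg >= -1e-9 & dg <= 1 + 1e-9))
  pmin(1, pmax(0, 1 - (dg + 1) / 5))
}

#' Combine the four departure components
#'
#' The default rule is the arithmetic mean of the four components,
#' which preserves their ordering and is a valid probability (a raw sum
#' of four probabilities can exceed 1). A clamped sum is selectable.
#'
#' @param wsi,bc,db,dg component probabilities (conformable arrays).
#' @param rule `"mean"` or `"sum"` (sum clamped at 1).
#' @return combined departure probability in \[0, 1\].
#' @export
combine_departure <- function(wsi, bc, db, dg, rule = c("mean", "sum")) {
  rule <- match.arg(rule)
  s <- wsi + bc + db + dg
  if (rule == "mean") s / 4 else pmin(1, s)
}

#' Seasonal weights of the arrival attractiveness components
#'
#' A shape sequence `c_d` runs piecewise-linearly from 1 on day 1 down
#' to 0.1 on the (randomly drawn) midwinter inflection day and back to 1
#' on day `n`. The forage, air-density and roosting weights are
#' quadratics in `c_d` centred on the inflection value 0.1 and peaking
#' at 0.45, 0.30 and 0.20 respectively; the gamma-kernel weight is
#' constant at 0.05 and the breeding-distance weight takes up the
#' remainder, so the five weights sum to 1 every day. Early and late in
#' the season the quadratics go negative and breeding-ground proximity
#' dominates arrival.
#'
#' @param d day index (1-based; vectorised).
#' @param n season length in days.
#' @param inflection inflection day index (see [draw_inflection_day()]).
#' @return data.frame with columns `day`, `c`, `wf`, `wa`, `wr`, `wg`, `wb`.
#' @export
arrival_weights <- function(d, n, inflection) {
  stopifnot(all(d >= 1 & d <= n), inflection >= 1, inflection <= n)
  cd <- ifelse(d <= inflection,
               1 - 0.9 * (d - 1) / max(1, inflection - 1),
               0.1 + 0.9 * (d - inflection) / max(1, n - inflection))
  wf <- -0.9 * (cd - 0.1)^2 + 0.45
  wa <- -0.6 * (cd - 0.1)^2 + 0.30
  wr <- -0.4 * (cd - 0.1)^2 + 0.20
  wg <- rep(0.05, length(d))
  wb <- 1 - (wf + wa + wr + wg)
  data.frame(day = d, c = cd, wf = wf, wa = wa, wr = wr, wg = wg, wb = wb)
}

#' Draw the midwinter inflection day of the weight schedule
#'
#' Uniform over the 31 December - 31 January window (days 122-153 of a
#' season starting 1 September), drawn once per run from the run seed.
#'
#' @param n season length in days.
#' @return integer day index.
#' @export
draw_inflection_day <- function(n) {
  lo <- min(122L, n); hi <- min(153L, n)
  if (lo >= hi) return(as.integer(ceiling(n / 2)))
  sample(lo:hi, 1)
}

#' Gamma movement-kernel score per node
#'
#' For each node, the mean over all other nodes of the gamma upper-tail
#' probability of a flight covering the pairwise distance — a measure of
#' how reachable a node is from the rest of the landscape — min-max
#' normalised to \[0, 1\].
#'
#' @param dist pairwise distance matrix, km.
#' @param shape,scale gamma parameters (scale in km; the default scale
#'   is half a typical flight range, set by the caller).
#' @return numeric vector of scores in \[0, 1\].
#' @export
gamma_score <- function(dist, shape = 2, scale = 650) {
  if (shape <= 0 || scale <= 0) stop("gamma shape and scale must be positive")
  n <- nrow(dist)
  if (n == 1) return(1)
  up <- 1 - pgamma(dist, shape = shape, scale = scale)
  g <- unname((colSums(up) - diag(up)) / (n - 1))
  rng <- range(g)
  if (diff(rng) < 1e-12) rep(1, n) else (g - rng[1]) / diff(rng)
}

minmax01 <- function(x) {
  rng <- range(x)
  if (!is.finite(diff(rng)) || diff(rng) < 1e-12) return(rep(1, length(x)))
  (x - rng[1]) / diff(rng)
}

#' Cobb-Douglas node attractiveness and arrival distribution
#'
#' Each component (forage, air density, roosting quality, breeding
#' proximity, gamma score) is min-max normalised to \[0, 1\] and floored
#' at 1e-6 (weights can be negative off-peak, so zero bases must be
#' avoided); breeding distance enters as proximity `1 - normalised
#' distance` so nodes nearer the breeding grounds are more attractive.
#' Attractiveness is the weighted product `F^wf * AD^wa * R^wr *
#' DBprox^wb * G^wg`, zeroed outside the availability (and optional
#' reachability) mask and normalised to a probability distribution.
#'
#' @param F forage per node, kJ.
#' @param AD air density per node.
#' @param R roosting quality per node.
#' @param DB distance to nearest breeding node, km.
#' @param G gamma kernel score per node.
#' @param w one row of [arrival_weights()].
#' @param avail logical availability mask.
#' @param reach optional additional logical mask.
#' @param eps floor applied to normalised component bases.
#' @return list with `A` (raw attractiveness, zero where masked) and
#'   `p` (arrival probabilities summing to 1), or `NULL` if no node is
#'   permitted.
#' @export
attractiveness <- function(F, AD, R, DB, G, w, avail, reach = NULL,
                           eps = 1e-6) {
  permitted <- avail
  if (!is.null(reach)) permitted <- permitted & reach
  if (!any(permitted)) return(NULL)
  base <- function(x) pmax(eps, minmax01(x))
  A <- base(F)^w$wf * base(AD)^w$wa * base(R)^w$wr *
    base(1 - minmax01(DB))^w$wb * base(G)^w$wg
  A[!permitted] <- 0
  tot <- sum(A)
  if (tot <= 0 || !is.finite(tot)) return(NULL)
  list(A = A, p = A / tot)
}

#' Precompute per-class movement tables
#'
#' The pairwise distance matrix is static, so the reachability mask
#' (distance within the class's fat-limited flight range) and the
#' post-flight destination class of every (origin, destination) pair are
#' computed once per run for each condition class.
#'
#' @param dist pairwise distance matrix, km.
#' @param schedule condition schedule from [build_schedule()].
#' @param cost flight cost of the reference bird, kg fat per km.
#' @param starvation passed to the class floor rule.
#' @return list per class with `range` (km), `reach` (logical matrix)
#'   and `flat` (integer matrix of `(dest, post-flight class)` flat
#'   indices into a nodes x classes matrix).
#' @export
movement_tables <- function(dist, schedule, cost, starvation = TRUE) {
  n_nodes <- nrow(dist)
  n_classes <- nrow(schedule)
  fat <- schedule$fat
  destcol <- col(dist)
  lapply(seq_len(n_classes), function(j) {
    if (j == 1) return(NULL)          # dead birds do not fly
    rng <- fat[j] / cost
    reach <- dist <= rng
    newfat <- fat[j] - dist * cost
    dest <- matrix(class_of_fat(newfat, fat, starvation), n_nodes, n_nodes)
    flat <- destcol + (dest - 1L) * n_nodes
    list(range = rng, reach = reach, flat = flat, all_reach = all(reach))
  })
}

#' One redistribution (departure + arrival) step
#'
#' Departing abundance per node and class is `ab * p_depart`. Each
#' departing cohort lands according to the day's arrival distribution
#' restricted to destinations within the cohort's flight range from its
#' origin (renormalised per origin), and drops condition classes by the
#' quantized fat cost of the distance flown. Cohorts with no permitted
#' reachable destination stay put in their origin class. Abundance is
#' conserved exactly.
#'
#' @param ab abundance matrix, nodes x classes.
#' @param p_depart departure probability matrix, nodes x classes.
#' @param A raw attractiveness vector (zero where not permitted).
#' @param tables per-class tables from [movement_tables()].
#' @return next abundance matrix.
#' @export
redistribute <- function(ab, p_depart, A, tables) {
  n_nodes <- nrow(ab); n_classes <- ncol(ab)
  dep <- ab * p_depart
  dep[, 1] <- 0
  out <- ab - dep
  if (is.null(A) || sum(A) <= 0) return(out + dep)  # nowhere to go: all stay
  for (j in seq_len(n_classes)[-1]) {
    # cohorts below a negligible mass (< 1e-9 birds) stay rather than fly
    live <- which(dep[, j] > 1e-9)
    skipped <- dep[, j] > 0 & dep[, j] <= 1e-9
    if (any(skipped)) out[skipped, j] <- out[skipped, j] + dep[skipped, j]
    if (length(live) == 0) next
    dj <- dep[live, j]
    tab <- tables[[j]]
    if (tab$all_reach) {
      # range covers the whole grid: one shared arrival distribution
      flow <- outer(dj, A / sum(A))
    } else {
      W <- tab$reach[live, , drop = FALSE] * rep(A, each = length(live))
      rs <- rowSums(W)
      stuck <- rs <= 0
      if (any(stuck)) {               # everything in range is masked: stay
        out[live[stuck], j] <- out[live[stuck], j] + dj[stuck]
        if (all(stuck)) next
        W <- W[!stuck, , drop = FALSE]
        rs <- rs[!stuck]
        live <- live[!stuck]
        dj <- dj[!stuck]
      }
      flow <- W * (dj / rs)           # rows: origins; cols: destinations
    }
    sums <- rowsum(as.vector(flow),
                   as.vector(tab$flat[live, , drop = FALSE]))
    dst <- as.integer(rownames(sums))
    out[dst] <- out[dst] + sums[, 1]
  }
  out
}
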