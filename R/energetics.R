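# Body-condition classes, survivorship schedule, forage decay and
# rationing, basal metabolism, daily gain, and condition transitions.

FAT_ENERGY_KJ_KG <- 39700  # energy density of body fat

#' Build the body-condition class schedule
#'
#' Body condition is binned into `n_classes` classes by fat proportion
#' of a reference body mass. Class 1 is the dead/starved class (zero
#' fat, zero survivorship); fat proportion rises evenly from class 1 to
#' `f_max` at the top class. Daily survivorship interpolates linearly in
#' class index from `s_min` (class 2) to `s_max` (top class). Classes
#' whose fat mass exceeds the optimal fat load `fat_opt` (heavy birds
#' carry elevated predation risk, per optimal body mass theory) have
#' survivorship capped at the second-best value.
#'
#' @param n_classes number of classes (>= 3; default 21).
#' @param f_max maximum fat proportion (default 0.11; the sensitivity
#'   alternatives are 0.08 and 0.14).
#' @param M reference body mass, kg.
#' @param s_min,s_max daily survivorship at class 2 and the top class.
#' @param fat_opt optimal fat mass, kg (~0.134, the fat load of a
#'   1.625 kg bird at the default fat proportion).
#' @return data.frame `flyway_schedule` with columns `class`, `f`
#'   (fat proportion), `fat` (kg) and `s` (daily survivorship).
#' @export
build_schedule <- function(n_classes = 21, f_max = 0.11, M = 1.2,
                           s_min = 0.99620, s_max = 0.99984,
                           fat_opt = 0.134) {
  if (n_classes < 3) stop("need at least 3 condition classes")
  if (!(s_min > 0 && s_min <= s_max && s_max <= 1))
    stop("invalid survivorship bounds: need 0 < s_min <= s_max <= 1")
  if (!(f_max > 0 && f_max < 1)) stop("f_max must lie in (0, 1)")
  j <- seq_len(n_classes)
  f <- f_max * (j - 1) / (n_classes - 1)
  s <- c(0, s_min + (s_max - s_min) * (j[-1] - 2) / (n_classes - 2))
  fat <- f * M
  over <- fat > fat_opt
  over[1] <- FALSE
  s[over] <- pmin(s[over], s[n_classes - 1])
  structure(data.frame(class = j, f = f, fat = fat, s = s),
            class = c("flyway_schedule", "data.frame"),
            M = M, f_max = f_max, fat_opt = fat_opt)
}

#' One day of natural forage decay
#'
#' Each cover class retains a fraction `r` of its forage per day
#' (Shoreline 0.9998, crops 0.9970, woody wetlands 0.9965, herbaceous
#' wetlands 0.9910 by default), so after `i` days without consumption
#' `F_i = F_0 * r^i`.
#'
#' @param F forage, kJ (vector or matrix; columns = cover classes).
#' @param r daily retention weight(s) in (0, 1], recycled over columns.
#' @return decayed forage of the same shape.
#' @export
decay_forage <- function(F, r) {
  if (any(r <= 0 | r > 1)) stop("retention weights must lie in (0, 1]")
  if (any(F < 0)) stop("negative forage")
  if (is.matrix(F)) F * rep(r, each = nrow(F)) else F * r
}

#' Default forage retention weights per cover class
#' @return named numeric vector of daily retention weights.
#' @export
default_decay_weights <- function() {
  c(shoreline = 0.9998, crops = 0.9970, woody_wetland = 0.9965,
    herbaceous_wetland = 0.9910, urban = 1.0, other = 1.0)
}

#' Temperature-dependent metabolic cost charged against daily gain
#'
#' Allometric baseline `bmr0_coef * M^bmr0_exp` (kJ/day) plus a linear
#' thermoregulatory increase of `slope` kJ/day per degC below the lower
#' critical temperature `t_lc`. The functional form and defaults are
#' package-level modelling choices for a mallard-sized waterbird.
#' Called standalone the default baseline is the full non-passerine
#' allometric basal rate; the season engine defaults the baseline to
#' zero instead, because fuel deposition rates are measured as realised
#' (net-of-maintenance) fat gain in free-living birds, and charges only
#' the thermoregulatory surcharge below `t_lc` (see `sim_config()`).
#'
#' @param T_air air temperature, degC (vectorised).
#' @param M body mass, kg.
#' @param bmr0_coef,bmr0_exp allometric coefficients (kJ/day, kg).
#' @param t_lc lower critical temperature, degC.
#' @param slope thermoregulatory cost, kJ/day per degC below `t_lc`.
#' @return basal metabolic rate, kJ/day.
#' @export
bmr <- function(T_air, M = 1.2, bmr0_coef = 308, bmr0_exp = 0.73,
                t_lc = 10, slope = 15) {
  stopifnot(bmr0_coef >= 0, M > 0, slope >= 0)
  bmr0_coef * M^bmr0_exp + pmax(0, t_lc - T_air) * slope
}

#' Potential daily intake and net daily gain
#'
#' Intake capacity is the fuel deposition rate (a fraction `fdr_coef` of
#' body mass in fat per day, converted to kJ via the energy density of
#' fat), discounted by urban disturbance and gated by habitat
#' availability: snow and ice cover impede access to calories, so birds
#' in unavailable nodes (WSI at or above threshold) ingest nothing.
#' The realised intake is further rationed when node-level demand
#' exceeds the forage on offer (see [allocate_forage()]). Net daily
#' gain subtracts temperature-dependent basal metabolism.
#'
#' @param T_air air temperature, degC.
#' @param available logical: is the node's habitat available today?
#' @param disturbance urban/disturbance proportion in \[0, 1\].
#' @param ration realised fraction of demanded intake in \[0, 1\].
#' @param M body mass, kg.
#' @param fdr_coef fuel deposition rate as a fraction of body mass/day.
#' @param fat_energy energy density of fat, kJ/kg.
#' @param ... passed to [bmr()].
#' @return list with `intake` (kJ/day, before rationing when
#'   `ration = 1`) and `gain` (kJ/day, net of metabolism).
#' @export
daily_gain <- function(T_air, available = TRUE, disturbance = 0,
                       ration = 1, M = 1.2, fdr_coef = 0.011,
                       fat_energy = FAT_ENERGY_KJ_KG, ...) {
  stopifnot(all(disturbance >= 0 & disturbance <= 1),
            all(ration >= 0 & ration <= 1), fdr_coef > 0)
  intake <- fdr_coef * M * fat_energy * (1 - disturbance) *
    as.numeric(available) * ration
  list(intake = intake, gain = intake - bmr(T_air, M, ...))
}

#' Proportional forage rationing
#'
#' When the summed intake demand in a node exceeds its standing forage,
#' every individual receives the same fraction of its demand; forage
#' never goes negative.
#'
#' @param demand total demanded intake in the node, kJ.
#' @param F forage available in the node, kJ.
#' @return list with `fraction` (per-capita ration in \[0, 1\]) and
#'   `consumed` (kJ removed from the node).
#' @export
allocate_forage <- function(demand, F) {
  stopifnot(all(demand >= 0), all(F >= 0))
  fraction <- ifelse(demand > 0, pmin(1, F / demand), 1)
  list(fraction = fraction, consumed = fraction * demand)
}

#' Move abundance between condition classes after an energy change
#'
#' Each class's occupants gain or lose fat (`delta_fat`, kg; energy
#' changes convert at the energy density of fat, flight losses are
#' distance x cost) and land in the class whose fat mass is nearest at
#' or below their new fat (floor quantization). Birds falling below the
#' class-2 fat mass starve into the dead class 1 (unless starvation is
#' disabled, in which case class 2 is the floor); fat above the top
#' class stays in the top class. Total abundance is conserved exactly.
#'
#' @param slice abundance vector over classes (one node), or a matrix
#'   nodes x classes with `delta_fat` a per-node vector or a matrix.
#' @param delta_fat fat change in kg: scalar, per-class vector (single
#'   node), per-node vector (matrix input), or full matrix.
#' @param schedule a [build_schedule()] table.
#' @param starvation if FALSE, transitions cannot enter the dead class.
#' @return reallocated abundance of the same shape as `slice`.
#' @export
transition_classes <- function(slice, delta_fat, schedule,
                               starvation = TRUE) {
  fat <- schedule$fat
  n <- length(fat)
  if (is.matrix(slice)) {
    nd <- nrow(slice)
    dm <- if (is.matrix(delta_fat)) delta_fat
          else matrix(delta_fat, nd, n)
    newfat <- dm + rep(fat, each = nd)
    newfat[, 1] <- fat[1]              # the dead class does not feed or fly
    dest <- matrix(class_of_fat(newfat, fat, starvation), nd, n)
    out <- matrix(0, nd, n)
    idx <- (dest - 1L) * nd + row(dest)  # flat index (node, dest class)
    keep <- slice != 0
    flat <- rowsum(slice[keep], idx[keep])
    out[as.integer(rownames(flat))] <- flat
    out
  } else {
    newfat <- fat + rep(delta_fat, length.out = n)
    newfat[1] <- fat[1]
    dest <- class_of_fat(newfat, fat, starvation)
    out <- numeric(n)
    for (j in seq_len(n)) out[dest[j]] <- out[dest[j]] + slice[j]
    out
  }
}

# floor quantization of fat mass onto the class ladder
class_of_fat <- function(newfat, fat, starvation = TRUE) {
  dest <- findInterval(newfat + 1e-12, fat)   # tolerate float fuzz at bounds
  dest[dest < 1L] <- 1L
  dest[dest > length(fat)] <- length(fat)
  if (!starvation) dest[dest < 2L] <- 2L
  dest
}
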