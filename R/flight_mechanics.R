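# Pennycuick-style flight performance: mechanical and chemical power,
# maximum-range speed, fat cost per km, and fat-limited flight range.

#' Aerodynamic and metabolic constants for the flight model
#'
#' Defaults follow the published Pennycuick (2008) formulation as
#' implemented in the Flight program family: induced power factor 1.2,
#' body drag coefficient 0.1, profile power constant 8.4 (divided by
#' wing aspect ratio), body frontal area `0.00813 * M^0.666`,
#' fat-to-mechanical conversion efficiency 0.23, respiration/circulation
#' overhead factor 1.1, and a basal metabolic add-on
#' `3.79 * M^0.723` W (non-passerine), switchable via `include_bmr`.
#' Candidate flight speeds are evaluated on the true-air-speed domain
#' `v_range` (default 10-25 m/s, the range over which the performance
#' curves are defined for this model).
#'
#' @param k induced power factor.
#' @param cdb body drag coefficient.
#' @param cpro profile power constant.
#' @param eta conversion efficiency, mechanical from chemical.
#' @param resp respiration and circulation overhead factor.
#' @param include_bmr add basal metabolism into chemical power?
#' @param bmr_coef,bmr_exp basal metabolic rate `bmr_coef * M^bmr_exp` W.
#' @param g gravitational acceleration, m s^-2.
#' @param fat_energy energy density of fat, kJ per kg.
#' @param v_range evaluated true-air-speed interval, m/s.
#' @param vmr_band plausibility band for the maximum-range speed, m/s.
#' @param cost_band plausibility band for flight cost, kg fat per km.
#' @return list of constants used by the flight functions.
#' @export
flight_params <- function(k = 1.2, cdb = 0.1, cpro = 8.4, eta = 0.23,
                          resp = 1.1, include_bmr = TRUE,
                          bmr_coef = 3.79, bmr_exp = 0.723, g = 9.81,
                          fat_energy = 39700, v_range = c(10, 25),
                          vmr_band = c(15, 35),
                          cost_band = c(1e-5, 3e-4)) {
  stopifnot(k > 0, cdb > 0, cpro > 0, eta > 0, eta <= 1, resp >= 1,
            fat_energy > 0, length(v_range) == 2, v_range[1] > 0,
            v_range[2] > v_range[1])
  list(k = k, cdb = cdb, cpro = cpro, eta = eta, resp = resp,
       include_bmr = include_bmr, bmr_coef = bmr_coef, bmr_exp = bmr_exp,
       g = g, fat_energy = fat_energy, v_range = v_range,
       vmr_band = vmr_band, cost_band = cost_band)
}

check_morph <- function(M, Ws, Wa, AD) {
  if (any(c(M, Ws, Wa, AD) <= 0))
    stop("mass, wingspan, wing area and air density must be positive")
}

#' Mechanical power components of level flight
#'
#' Returns induced, parasite and profile power (W) separately, so that
#' their individual scalings (induced ~ 1/(rho V), parasite ~ rho V^3,
#' profile independent of V) can be inspected and tested.
#'
#' @param M body mass, kg.
#' @param Ws wingspan, m.
#' @param Wa wing area, m^2.
#' @param AD air density, kg m^-3.
#' @param V true air speed, m/s (vectorised).
#' @param params constants from [flight_params()].
#' @return list of numeric vectors `induced`, `parasite`, `profile`.
#' @export
power_components <- function(M, Ws, Wa, AD, V, params = flight_params()) {
  check_morph(M, Ws, Wa, AD)
  if (any(V <= 0)) stop("speed must be positive")
  p <- params
  sd_disk <- pi * Ws^2 / 4
  sb <- 0.00813 * M^0.666
  induced <- p$k * (M * p$g)^2 / (2 * AD * V * sd_disk)
  parasite <- 0.5 * AD * V^3 * sb * p$cdb
  # absolute minimum power, then profile power as a fixed fraction of it
  p_am <- 1.05 * p$k^0.75 * (M * p$g)^1.5 * sb^0.25 * p$cdb^0.25 /
    (sqrt(AD) * Ws^1.5)
  aspect <- Ws^2 / Wa
  profile <- rep(p$cpro / aspect * p_am, length.out = length(V))
  list(induced = induced, parasite = parasite, profile = profile)
}

#' Chemical power of level flight
#'
#' Mechanical power converted to the rate of fuel energy use: the sum of
#' the mechanical components divided by the conversion efficiency, plus
#' (by default) basal metabolism, all inflated by the respiration and
#' circulation overhead factor.
#'
#' @inheritParams power_components
#' @return chemical power, W (vectorised over `V`).
#' @export
chemical_power <- function(M, Ws, Wa, AD, V, params = flight_params()) {
  p <- params
  pc <- power_components(M, Ws, Wa, AD, V, p)
  mech <- pc$induced + pc$parasite + pc$profile
  bmr <- if (p$include_bmr) p$bmr_coef * M^p$bmr_exp else 0
  p$resp * (mech / p$eta + bmr)
}

#' Maximum-range speed
#'
#' The true air speed minimising chemical energy per unit distance,
#' `P(V)/V` (the tangent from the origin to the power curve), found by
#' golden-section search on the evaluated speed domain to a tolerance
#' of 1e-3 m/s.
#'
#' @inheritParams power_components
#' @return maximum-range speed, m/s.
#' @export
vmr <- function(M, Ws, Wa, AD, params = flight_params()) {
  check_morph(M, Ws, Wa, AD)
  opt <- stats::optimize(function(v) chemical_power(M, Ws, Wa, AD, v, params) / v,
                         interval = params$v_range, tol = 1e-3)
  if (!is.finite(opt$minimum)) stop("maximum-range speed search failed")
  opt$minimum
}

#' Flight cost in kg of fat per km
#'
#' Chemical power at the maximum-range speed, divided by that speed
#' (energy per metre) and by the energy density of fat.
#'
#' @inheritParams power_components
#' @return cost, kg fat per km.
#' @export
cost_per_km <- function(M, Ws, Wa, AD, params = flight_params()) {
  v <- vmr(M, Ws, Wa, AD, params)
  j_per_m <- chemical_power(M, Ws, Wa, AD, v, params) / v
  j_per_m * 1000 / (params$fat_energy * 1000)
}

#' Fat-limited flight range
#'
#' @param fat_available fat mass available for flight, kg.
#' @param cost flight cost, kg fat per km.
#' @param flight_fraction fraction of fat metabolizable for powered
#'   flight (default 1: flight draws on lipids exclusively).
#' @return range, km.
#' @export
flight_range <- function(fat_available, cost, flight_fraction = 1) {
  if (any(cost <= 0)) stop("flight cost must be positive")
  if (any(fat_available < 0)) stop("fat mass must be nonnegative")
  fat_available * flight_fraction / cost
}

#' Sweep flight performance over a morphometric and air-density grid
#'
#' @param M,Ws,Wa,AD numeric vectors of grid values for body mass (kg),
#'   wingspan (m), wing area (m^2) and air density (kg m^-3).
#' @param params constants from [flight_params()].
#' @return data.frame with one row per grid combination: the inputs,
#'   `vmr_ms`, `vmr_kmh` and `cost_kg_km`.
#' @export
flight_sweep <- function(M = seq(0.8, 1.3, length.out = 10),
                         Ws = seq(0.75, 1.15, length.out = 5),
                         Wa = seq(0.09, 0.11, length.out = 3),
                         AD = seq(0.95, 1.30, length.out = 8),
                         params = flight_params()) {
  g <- expand.grid(M = M, Ws = Ws, Wa = Wa, AD = AD, KEEP.OUT.ATTRS = FALSE)
  g$vmr_ms <- mapply(vmr, g$M, g$Ws, g$Wa, g$AD,
                     MoreArgs = list(params = params))
  g$vmr_kmh <- g$vmr_ms * 3.6
  g$cost_kg_km <- mapply(function(M, Ws, Wa, AD, v) {
    chemical_power(M, Ws, Wa, AD, v, params) / v * 1000 /
      (params$fat_energy * 1000)
  }, g$M, g$Ws, g$Wa, g$AD, g$vmr_ms)
  g
}
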