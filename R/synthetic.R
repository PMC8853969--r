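# Seeded synthetic landscapes and weather with the structure the model
# assumes: a planar node grid with a northern breeding band and
# spatially autocorrelated cover, and reanalysis-like daily temperature,
# snow and pressure fields with a latitudinal gradient, a seasonal
# cycle, AR(1) noise and stochastic snow events.

# separable 2-D smoothing of grid noise (simple repeated box blur)
smooth_grid <- function(z, n_x, n_y, passes = 2) {
  m <- matrix(z, n_x, n_y)
  for (p in seq_len(passes)) {
    m <- (m +
            rbind(m[1, , drop = FALSE], m[-n_x, , drop = FALSE]) +
            rbind(m[-1, , drop = FALSE], m[n_x, , drop = FALSE])) / 3
    m <- (m +
            cbind(m[, 1, drop = FALSE], m[, -n_y, drop = FALSE]) +
            cbind(m[, -1, drop = FALSE], m[, n_y, drop = FALSE])) / 3
  }
  as.vector(m)
}

#' Generate a synthetic landscape grid
#'
#' A planar grid (km coordinates, y increasing north) with spatially
#' autocorrelated cover proportions, a wetland/shoreline fraction that
#' decays from south to north, and breeding nodes confined to a
#' northern band of rows.
#'
#' @param n_rows,n_cols grid dimensions (rows run south to north).
#' @param resolution node side, km.
#' @param breeding_rows integer vector of northern row indices flagged
#'   as breeding (default: the top two rows).
#' @param wetland_gradient multiplicative south-to-north decay applied
#'   to shoreline/wetland cover (0 = none at the north edge).
#' @param seed RNG seed; identical seeds give identical grids.
#' @return a `flyway_grid` with cover columns, breeding flags, roosting
#'   quality `R` and urban disturbance filled in.
#' @export
synth_landscape <- function(n_rows = 20, n_cols = 30, resolution = 32.19,
                            breeding_rows = (n_rows - 1):n_rows,
                            wetland_gradient = 0.5, seed = 1) {
  if (any(breeding_rows < 1 | breeding_rows > n_rows))
    stop("breeding_rows outside the grid")
  set.seed(seed)
  grid <- build_grid(c(0, n_cols * resolution, 0, n_rows * resolution),
                     resolution, coords = "planar")
  n <- nrow(grid$nodes)
  row_idx <- rep(seq_len(n_rows), each = n_cols)
  northness <- (row_idx - 1) / max(1, n_rows - 1)
  noise <- function(mu, sd) {
    z <- smooth_grid(rnorm(n, 0, 1), n_cols, n_rows)
    pmin(1, pmax(0, mu + sd * z / max(1e-9, stats::sd(z))))
  }
  south_fac <- 1 - wetland_gradient * northness
  cover <- data.frame(
    shoreline = noise(0.08, 0.05) * south_fac,
    crops = noise(0.30, 0.12),
    woody_wetland = noise(0.08, 0.05) * south_fac,
    herbaceous_wetland = noise(0.10, 0.06) * south_fac,
    urban = noise(0.04, 0.03)
  )
  tot <- rowSums(cover)
  over <- tot > 0.95
  cover[over, ] <- cover[over, ] * 0.95 / tot[over]
  cover$other <- pmax(0, 1 - rowSums(cover))
  grid$nodes[, COVER_CLASSES] <- cover[, COVER_CLASSES]
  grid$nodes$breeding <- row_idx %in% breeding_rows
  grid$nodes$R <- roosting_quality(cover)
  grid
}

#' Parameters of the synthetic weather generator
#'
#' @param base_temp daily-mean temperature at the south edge away from
#'   midwinter, degC.
#' @param lapse latitudinal cooling, degC per 100 km northward.
#' @param amplitude depth of the midwinter seasonal dip, degC.
#' @param midwinter_day day index (from 1 September) of the coldest
#'   point of the seasonal cycle.
#' @param ar_sd,ar_coef AR(1) temperature noise: innovation SD (degC)
#'   and autocorrelation in \[0, 1).
#' @param snow_prob daily snowfall probability when below freezing.
#' @param snow_mean mean depth of a snowfall event, cm.
#' @param melt_rate snowmelt, cm per day per degC above 0.
#' @param severity multiplier on the cold terms (lapse + seasonal dip);
#'   mild < 1 < severe.
#' @param pressure_base sea-level-equivalent surface pressure, Pa.
#' @param pressure_sd static per-node pressure spread (synthetic
#'   elevation), Pa.
#' @return list of generator parameters.
#' @export
weather_gen_params <- function(base_temp = 22, lapse = 2.0, amplitude = 12,
                               midwinter_day = 137, ar_sd = 2.5,
                               ar_coef = 0.6, snow_prob = 0.35,
                               snow_mean = 4, melt_rate = 0.8,
                               severity = 1.0, pressure_base = 87000,
                               pressure_sd = 1000) {
  stopifnot(ar_sd >= 0, ar_coef >= 0, ar_coef < 1, severity > 0,
            snow_prob >= 0, snow_prob <= 1, snow_mean >= 0, melt_rate >= 0)
  list(base_temp = base_temp, lapse = lapse, amplitude = amplitude,
       midwinter_day = midwinter_day, ar_sd = ar_sd, ar_coef = ar_coef,
       snow_prob = snow_prob, snow_mean = snow_mean, melt_rate = melt_rate,
       severity = severity, pressure_base = pressure_base,
       pressure_sd = pressure_sd)
}

#' Generate synthetic daily weather over a grid
#'
#' Temperature is `base - severity * (lapse * northward_km/100 +
#' amplitude * seasonal dip)` plus per-node AR(1) noise; the seasonal
#' dip is a raised-cosine bump centred on the midwinter day. Snow
#' accumulates by random events while below freezing and melts above
#' 0 degC; pressure is static per node (synthetic elevation spread).
#'
#' @param grid a `flyway_grid` with planar coordinates.
#' @param params a [weather_gen_params()] list.
#' @param n_days number of days (default 273, 1 Sep - 31 May).
#' @param seed RNG seed.
#' @return a `flyway_weather` (see [derive_weather()]).
#' @export
synth_weather <- function(grid, params = weather_gen_params(),
                          n_days = 273, seed = 1) {
  stopifnot(n_days >= 1)
  set.seed(seed)
  p <- params
  n <- nrow(grid$nodes)
  y <- grid$nodes$y
  dy <- (y - min(y)) / 100                   # northward distance, 100 km
  day <- seq_len(n_days)
  half_width <- 120
  dip <- 0.5 * (1 + cos(pi * pmin(1, abs(day - p$midwinter_day) / half_width)))
  clim <- outer(dip, dy, function(dd, yy)
    p$base_temp - p$severity * (p$lapse * yy + p$amplitude * dd))
  eps <- matrix(rnorm(n_days * n, 0, p$ar_sd), n_days, n)
  noise <- matrix(0, n_days, n)
  noise[1, ] <- eps[1, ]
  for (k in 2:max(2, n_days))
    if (k <= n_days) noise[k, ] <- p$ar_coef * noise[k - 1, ] + eps[k, ]
  T_air <- clim + noise

  S <- matrix(0, n_days, n)
  depth <- rep(0, n)
  for (k in day) {
    cold <- T_air[k, ] < 0
    fall <- cold & (runif(n) < p$snow_prob)
    depth <- depth + ifelse(fall, stats::rexp(n, 1 / max(1e-9, p$snow_mean)), 0)
    depth <- pmax(0, depth - ifelse(cold, 0, p$melt_rate * pmax(0, T_air[k, ])))
    S[k, ] <- depth
  }
  press <- p$pressure_base +
    pmax(-2 * p$pressure_sd,
         pmin(2 * p$pressure_sd, rnorm(n, 0, p$pressure_sd)))
  P <- matrix(press, n_days, n, byrow = TRUE)
  derive_weather(T_air, S, P)
}

#' Mild / baseline / severe weather presets
#'
#' Three fully specified generator parameter sets differing only in the
#' severity multiplier (0.7, 1.0, 1.4).
#'
#' @param ... overrides applied to all three presets.
#' @return named list of [weather_gen_params()] lists.
#' @export
weather_presets <- function(...) {
  list(mild = weather_gen_params(severity = 0.7, ...),
       baseline = weather_gen_params(severity = 1.0, ...),
       severe = weather_gen_params(severity = 1.4, ...))
}
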