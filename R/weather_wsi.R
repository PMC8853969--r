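# Weather state, snow/freeze streak counters, the weather severity index
# (WSI), air density, and the available-habitat mask.

#' Advance snow and freeze streak counters by one day
#'
#' A snow streak counts consecutive days with snow depth >= 2.54 cm
#' (one inch); a freeze streak counts consecutive days with air
#' temperature strictly below 0 degC. Counters reset to zero the first
#' day the condition fails. All arguments are vectorised over nodes.
#'
#' @param S snow depth today, cm.
#' @param T_air air temperature today, degC.
#' @param prev_sdays,prev_tfreeze yesterday's counters (0 on 1 September).
#' @return list with integer vectors `S_days` and `T_freeze`.
#' @export
update_streaks <- function(S, T_air, prev_sdays = 0L, prev_tfreeze = 0L) {
  stopifnot(all(S >= 0), all(prev_sdays >= 0), all(prev_tfreeze >= 0))
  list(S_days   = ifelse(S >= 2.54, prev_sdays + 1L, 0L),
       T_freeze = ifelse(T_air < 0, prev_tfreeze + 1L, 0L))
}

#' Weather severity index
#'
#' `WSI = S * 0.394 + S_days - T + T_freeze`. The 0.394 factor converts
#' snow depth from cm to inches, so snow enters the index in inch units;
#' it is kept as a literal constant. The index is negative in mild
#' weather (warm, snow-free days).
#'
#' @param S snow depth, cm.
#' @param S_days consecutive days with snow depth >= 2.54 cm.
#' @param T_air air temperature, degC.
#' @param T_freeze consecutive days with temperature < 0 degC.
#' @return numeric WSI, dimensionless.
#' @export
compute_wsi <- function(S, S_days, T_air, T_freeze) {
  S * 0.394 + S_days - T_air + T_freeze
}

#' Available-habitat mask
#'
#' A node is available on a day iff its WSI is strictly below the
#' threshold (default 7.5, the empirical severity at which local
#' waterfowl abundance switches from growing to shrinking).
#'
#' @param wsi numeric vector or matrix of WSI values.
#' @param threshold severity threshold.
#' @return logical object of the same shape: TRUE = available.
#' @export
available_mask <- function(wsi, threshold = 7.5) {
  if (length(wsi) == 0) stop("empty WSI field")
  wsi < threshold
}

#' Seasonal availability statistics
#'
#' Mean, standard deviation and minimum of the daily available-habitat
#' fraction over a season.
#'
#' @param masks logical matrix, days x nodes (or a list of daily masks).
#' @return list with `mean`, `sd`, `min` and the daily `fraction` series.
#' @export
availability_stats <- function(masks) {
  if (is.list(masks)) masks <- do.call(rbind, masks)
  if (length(masks) == 0) stop("empty mask series")
  frac <- rowMeans(masks)
  list(mean = mean(frac), sd = stats::sd(frac), min = min(frac),
       fraction = frac)
}

#' Air density from pressure and temperature
#'
#' Ideal-gas relation `AD = P / (R_specific * (T + 273.15))` with
#' `R_specific = 287.05` J kg^-1 K^-1 for dry air.
#'
#' @param P surface pressure, Pa.
#' @param T_air air temperature, degC.
#' @return air density, kg m^-3.
#' @export
air_density <- function(P, T_air) {
  if (any(T_air <= -273.15)) stop("temperature at or below absolute zero")
  P / (287.05 * (T_air + 273.15))
}

#' Derive the full daily weather state from raw fields
#'
#' Runs the streak counters forward from 1 September (both start at 0),
#' then computes WSI, air density and the availability mask for every
#' day and node. Missing values are forward-filled along time for up to
#' three days; longer gaps are an error.
#'
#' @param T_air,S matrices, days x nodes: temperature (degC), snow (cm).
#' @param P matrix of surface pressure (Pa), or NULL to skip air density.
#' @param threshold WSI availability threshold.
#' @return `flyway_weather` list of matrices: `T_air`, `S`, `S_days`,
#'   `T_freeze`, `WSI`, `AD` (NULL if no pressure), `avail`.
#' @export
derive_weather <- function(T_air, S, P = NULL, threshold = 7.5) {
  stopifnot(is.matrix(T_air), is.matrix(S), all(dim(T_air) == dim(S)))
  T_air <- fill_gaps(T_air); S <- fill_gaps(S)
  if (!is.null(P)) P <- fill_gaps(P)
  n_days <- nrow(T_air); n_nodes <- ncol(T_air)
  sd_mat <- tf_mat <- matrix(0L, n_days, n_nodes)
  prev_s <- prev_t <- rep(0L, n_nodes)
  for (k in seq_len(n_days)) {
    st <- update_streaks(S[k, ], T_air[k, ], prev_s, prev_t)
    sd_mat[k, ] <- prev_s <- st$S_days
    tf_mat[k, ] <- prev_t <- st$T_freeze
  }
  wsi <- compute_wsi(S, sd_mat, T_air, tf_mat)
  ad <- if (is.null(P)) NULL else air_density(P, T_air)
  structure(list(T_air = T_air, S = S, P = P, S_days = sd_mat,
                 T_freeze = tf_mat, WSI = wsi, AD = ad,
                 avail = available_mask(wsi, threshold),
                 threshold = threshold),
            class = "flyway_weather")
}

# forward-fill NAs along columns, at most max_gap consecutive days
fill_gaps <- function(m, max_gap = 3L) {
  if (!anyNA(m)) return(m)
  for (j in seq_len(ncol(m))) {
    x <- m[, j]
    if (!anyNA(x)) next
    run <- 0L
    for (k in seq_along(x)) {
      if (is.na(x[k])) {
        run <- run + 1L
        if (run > max_gap || k == 1L)
          stop("weather gap longer than ", max_gap, " days (node column ", j, ")")
        x[k] <- x[k - 1L]
      } else run <- 0L
    }
    m[, j] <- x
  }
  m
}
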