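# Shared fixtures and independent brute-force oracles. Everything is
# generated in code; no files are read.

cover_classes <- c("shoreline", "crops", "woody_wetland",
                   "herbaceous_wetland", "urban", "other")

# a tiny hand-specified planar grid (one column of nodes running north)
toy_grid <- function(n_nodes = 3, spacing = 100, shoreline = 0.2,
                     breeding_last = TRUE) {
  g <- build_grid(c(0, spacing, 0, n_nodes * spacing), spacing, "planar")
  g$nodes$shoreline <- rep(shoreline, n_nodes)
  g$nodes$crops <- 0.3
  g$nodes$other <- 1 - g$nodes$shoreline - 0.3
  g$nodes$breeding <- c(rep(FALSE, n_nodes - 1), breeding_last)
  g$nodes$R <- g$nodes$shoreline
  g
}

# constant benign weather over a grid
toy_weather <- function(n_days, n_nodes, T_air = 15, S = 0, P = 101325) {
  derive_weather(matrix(T_air, n_days, n_nodes),
                 matrix(S, n_days, n_nodes),
                 matrix(P, n_days, n_nodes))
}

# brute-force streak recount from a raw daily series (independent of
# update_streaks: recounts the run length ending at each day)
recount_streaks <- function(S_series, T_series) {
  n <- length(S_series)
  sdays <- tfreeze <- integer(n)
  for (k in seq_len(n)) {
    r <- 0L
    for (b in k:1) { if (S_series[b] >= 2.54) r <- r + 1L else break }
    sdays[k] <- r
    r <- 0L
    for (b in k:1) { if (T_series[b] < 0) r <- r + 1L else break }
    tfreeze[k] <- r
  }
  list(S_days = sdays, T_freeze = tfreeze)
}

# scalar floor quantization onto a fat ladder (independent of
# class_of_fat): largest class whose fat is <= x
scalar_class <- function(x, fat, starvation = TRUE) {
  j <- max(which(fat <= x + 1e-12), 1L)
  if (!starvation) j <- max(j, 2L)
  j
}

# Independent one-day enumeration of the full daily update
# (forage -> departure -> arrival -> mortality) with explicit scalar
# loops, mirroring the model definition but sharing no code with
# sim_step. All masks/weights are taken as plain vectors.
brute_force_day <- function(ab, forage, T_air, wsi, avail, ad,
                            dist, db, R, G, w, sched, cfg) {
  n_nodes <- nrow(ab); n_classes <- ncol(ab)
  fat <- sched$fat
  fp <- flight_params(fat_energy = cfg$fat_energy)
  cost <- cost_per_km(cfg$body_mass, cfg$wingspan, cfg$wing_area,
                      cfg$ref_air_density, fp)
  ## forage + gains
  dg <- numeric(n_nodes)
  for (i in seq_len(n_nodes)) {
    intake_pc <- cfg$fdr_coef * cfg$body_mass * cfg$fat_energy *
      (1 - 0) * (if (avail[i]) 1 else 0)
    alive <- sum(ab[i, -1])
    Fi <- sum(forage[i, ])
    demand <- intake_pc * alive
    frac <- if (demand > 0) min(1, Fi / demand) else 1
    consumed <- frac * demand
    if (Fi > 0) forage[i, ] <- forage[i, ] * max(0, 1 - consumed / Fi)
    forage[i, ] <- forage[i, ] * cfg$decay_weights[colnames(forage)]
    thermo <- cfg$bmr0_coef * cfg$body_mass^cfg$bmr0_exp +
      max(0, cfg$t_lc - T_air[i]) * cfg$therm_slope
    dg[i] <- intake_pc * frac - thermo
    ## condition transitions from the day's gain
    newab <- numeric(n_classes)
    newab[1] <- ab[i, 1]
    for (j in 2:n_classes) {
      dest <- scalar_class(fat[j] + dg[i] / cfg$fat_energy, fat,
                           cfg$starvation)
      newab[dest] <- newab[dest] + ab[i, j]
    }
    ab[i, ] <- newab
  }
  ## departure probabilities
  p_dep <- matrix(0, n_nodes, n_classes)
  for (i in seq_len(n_nodes)) for (j in 2:n_classes) {
    mono <- function(x, K, a) {
      x <- max(0, x)
      if (K <= 0) as.numeric(x > 0) else x^a / (x^a + K^a)
    }
    pw <- mono(wsi[i], cfg$wsi_threshold, cfg$wsi_exponent)
    pb <- mono(j - 1, n_classes - 3, cfg$bc_exponent)
    pd <- mono(db[i], fat[j] / cost, cfg$db_exponent)
    pg <- min(1, max(0, 1 - (dg[i] + 1) / 5))
    p_dep[i, j] <- (pw + pb + pd + pg) / 4
  }
  ## arrival attractiveness
  mm <- function(x) {
    if (max(x) - min(x) < 1e-12) rep(1, length(x))
    else (x - min(x)) / (max(x) - min(x))
  }
  fl <- function(x) pmax(1e-6, x)
  A <- fl(mm(rowSums(forage)))^w$wf * fl(mm(ad))^w$wa * fl(mm(R))^w$wr *
    fl(mm(1 - mm(db)))^w$wb * fl(mm(G))^w$wg
  A[!avail] <- 0
  ## redistribution with per-origin reachability
  out <- ab
  if (sum(A) > 0) {
    for (j in 2:n_classes) for (o in seq_len(n_nodes)) {
      dj <- ab[o, j] * p_dep[o, j]
      if (dj <= 1e-9) next
      reach_w <- numeric(n_nodes)
      for (dd in seq_len(n_nodes))
        if (dist[o, dd] <= fat[j] / cost) reach_w[dd] <- A[dd]
      tot <- sum(reach_w)
      out[o, j] <- out[o, j] - dj
      if (tot <= 0) { out[o, j] <- out[o, j] + dj; next }
      for (dd in seq_len(n_nodes)) {
        if (reach_w[dd] <= 0) next
        dest <- scalar_class(fat[j] - dist[o, dd] * cost, fat,
                             cfg$starvation)
        out[dd, dest] <- out[dd, dest] + dj * reach_w[dd] / tot
      }
    }
  }
  ## mortality
  deaths <- 0
  for (i in seq_len(n_nodes)) for (j in seq_len(n_classes)) {
    d <- out[i, j] * (1 - sched$s[j])
    deaths <- deaths + d
    out[i, j] <- out[i, j] - d
  }
  list(ab = out, forage = forage, deaths = deaths, dg = dg)
}
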