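# Orchestration of the daily loop: forage -> departure -> arrival ->
# mortality, plus whole-season runs and per-period summaries.

#' Simulation configuration
#'
#' Central container of model parameters with their default study
#' values: initial population 19,856,514; WSI availability threshold
#' 7.5; 21 condition classes with fat proportion up to 0.11 of a 1.2 kg
#' reference bird; daily survivorship from 0.99620 to 0.99984; fuel
#' deposition coefficient 0.011 of body mass per day; fat energy density
#' 39,700 kJ/kg; season 1 September - 31 May.
#'
#' @param ... named overrides of any default listed below.
#' @return a validated `flyway_config` list.
#' @export
sim_config <- function(...) {
  cfg <- list(
    n0 = 19856514,
    season_start = "09-01",
    season_end = "05-31",
    wsi_threshold = 7.5,
    n_classes = 21,
    f_max = 0.11,
    body_mass = 1.2,
    wingspan = 0.95,
    wing_area = 0.1,
    fat_opt = 0.134,
    s_min = 0.99620,
    s_max = 0.99984,
    fdr_coef = 0.011,
    fat_energy = 39700,
    bmr0_coef = 0,
    bmr0_exp = 0.73,
    t_lc = 10,
    therm_slope = 15,
    combine_rule = "mean",
    dg_form = "kj",
    wsi_exponent = 3,
    bc_exponent = 8,
    db_exponent = 5,
    roost_rule = "shoreline",
    decay_order = "consume_then_decay",
    starvation = TRUE,
    gamma_shape = 2,
    gamma_scale = NULL,       # default: half the top-class flight range
    flight_cost = NULL,       # default: reference bird at mean air density
    ref_air_density = 1.225,
    access_efold = 16,
    forage_density = c(shoreline = 1e6, crops = 2.5e6, woody_wetland = 1.5e6,
                       herbaceous_wetland = 3e6, urban = 0, other = 0),
    decay_weights = default_decay_weights(),
    seed = 1L,
    scenario = "baseline"
  )
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(cfg))
    if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
    for (nm in names(over)) cfg[nm] <- list(over[[nm]])  # keeps NULLs
  }
  for (nm in c("forage_density", "decay_weights"))      # lists from YAML/JSON
    if (is.list(cfg[[nm]])) cfg[[nm]] <- unlist(cfg[[nm]])
  validate_config(cfg)
  structure(cfg, class = "flyway_config")
}

validate_config <- function(cfg) {
  with(cfg, {
    stopifnot(n0 > 0, wsi_threshold > 0 || TRUE, n_classes >= 3,
              f_max > 0, f_max < 1, body_mass > 0,
              s_min > 0, s_min <= s_max, s_max <= 1,
              fdr_coef > 0, fdr_coef <= 0.05, fat_energy > 0,
              combine_rule %in% c("mean", "sum"),
              dg_form %in% c("kj", "normalized"),
              roost_rule %in% c("shoreline", "shoreline_wetland"),
              decay_order %in% c("consume_then_decay", "decay_then_consume"),
              gamma_shape > 0, access_efold > 0,
              all(forage_density >= 0))
  })
  invisible(cfg)
}

#' Apply daily condition-dependent mortality
#'
#' Every class's abundance is multiplied by its daily survivorship;
#' the dead class (survivorship 0, holding today's starvation losses)
#' is flushed into cumulative deaths, so it is empty at the start of
#' each day.
#'
#' @param ab abundance matrix, nodes x classes.
#' @param schedule condition schedule from [build_schedule()].
#' @return list with `ab` (survivors) and `deaths` (today's total).
#' @export
apply_mortality <- function(ab, schedule) {
  surv <- ab * rep(schedule$s, each = nrow(ab))
  list(ab = surv, deaths = sum(ab) - sum(surv))
}

# assemble the static per-run context shared by every daily step
build_run_context <- function(land, cfg) {
  nodes <- land$nodes
  schedule <- build_schedule(cfg$n_classes, cfg$f_max, cfg$body_mass,
                             cfg$s_min, cfg$s_max, cfg$fat_opt)
  fp <- flight_params(fat_energy = cfg$fat_energy)
  cost <- cfg$flight_cost %||%
    cost_per_km(cfg$body_mass, cfg$wingspan, cfg$wing_area,
                cfg$ref_air_density, fp)
  dist <- land$dist %||% distance_matrix(land)
  db <- land$db %||% breeding_distance(land, dist)
  top_range <- max(schedule$fat) / cost
  gscale <- cfg$gamma_scale %||% (top_range / 2)
  G <- gamma_score(dist, cfg$gamma_shape, gscale)
  R <- nodes$R %||% roosting_quality(nodes, cfg$roost_rule)
  tables <- movement_tables(dist, schedule, cost, cfg$starvation)
  ranges <- c(NA_real_, vapply(tables[-1], `[[`, numeric(1), "range"))
  list(schedule = schedule, cost = cost, dist = dist, db = db, G = G,
       R = R, tables = tables, ranges = ranges,
       disturbance = nodes$urban %||% rep(0, nrow(nodes)),
       area = nodes$area, gamma_scale = gscale, flight = fp)
}

#' Advance the simulation by one day
#'
#' Executes the daily order of operations: (1) forage — natural decay
#' and rationed consumption move energy from the landscape into body
#' fat, shifting condition classes; (2) departure — the four Monod /
#' linear pressures are combined into a departure probability per node
#' and class; (3) arrival — departing cohorts land according to
#' Cobb-Douglas attractiveness over available, reachable nodes, paying
#' the quantized fat cost of the flight; (4) mortality. Abundance plus
#' cumulative deaths is conserved exactly.
#'
#' @param state list with `ab`, `forage` (nodes x cover classes kJ),
#'   `deaths`, `day`.
#' @param wx_day list of today's per-node weather: `T_air`, `WSI`,
#'   `AD`, `avail`.
#' @param w_arr one row of [arrival_weights()] for today.
#' @param ctx static run context from the season runner.
#' @param cfg a [sim_config()].
#' @return list with the next `state` and a one-row `metrics`
#'   data.frame.
#' @export
sim_step <- function(state, wx_day, w_arr, ctx, cfg) {
  ab <- state$ab
  n_nodes <- nrow(ab); n_classes <- ncol(ab)
  sched <- ctx$schedule
  alive <- rowSums(ab[, -1, drop = FALSE])

  ## (1) forage: rationed intake, then decay (or the reverse, by config)
  decay_first <- cfg$decay_order == "decay_then_consume"
  if (decay_first) state$forage <- decay_forage(state$forage,
                                                cfg$decay_weights[colnames(state$forage)])
  intake_pc <- cfg$fdr_coef * cfg$body_mass * cfg$fat_energy *
    (1 - ctx$disturbance) * as.numeric(wx_day$avail)
  F_node <- rowSums(state$forage)
  demand <- intake_pc * alive
  ration <- allocate_forage(demand, F_node)
  # remove consumption proportionally across cover classes
  shrink <- ifelse(F_node > 0, pmax(0, 1 - ration$consumed / F_node), 1)
  state$forage <- state$forage * shrink
  if (!decay_first) state$forage <- decay_forage(state$forage,
                                                 cfg$decay_weights[colnames(state$forage)])
  bmr_node <- bmr(wx_day$T_air, cfg$body_mass, cfg$bmr0_coef,
                  cfg$bmr0_exp, cfg$t_lc, cfg$therm_slope)
  dg_node <- intake_pc * ration$fraction - bmr_node
  dfat_node <- dg_node / cfg$fat_energy
  ab <- transition_classes(ab, dfat_node, sched, cfg$starvation)

  ## (2) departure pressure per node x class
  p_wsi <- p_depart_wsi(wx_day$WSI, cfg$wsi_threshold, cfg$wsi_exponent)
  p_bc <- p_depart_bc(seq_len(n_classes), n_classes, cfg$bc_exponent)
  p_dg <- if (cfg$dg_form == "kj") p_depart_dg(dg_node, "kj")
          else p_depart_dg(minmax01(dg_node), "normalized")
  p_db <- outer(ctx$db, ctx$ranges, function(d, r) {
    ifelse(is.na(r), 0, monod(d, r, cfg$db_exponent))
  })
  p_dep <- combine_departure(matrix(p_wsi, n_nodes, n_classes),
                             matrix(p_bc, n_nodes, n_classes, byrow = TRUE),
                             p_db,
                             matrix(p_dg, n_nodes, n_classes),
                             cfg$combine_rule)

  ## (3) arrival over available nodes, then redistribution
  att <- attractiveness(rowSums(state$forage), wx_day$AD, ctx$R, ctx$db,
                        ctx$G, w_arr, wx_day$avail)
  ab <- redistribute(ab, p_dep, if (is.null(att)) NULL else att$A,
                     ctx$tables)

  ## (4) mortality
  m <- apply_mortality(ab, sched)
  state$ab <- m$ab
  state$deaths <- state$deaths + m$deaths

  total <- sum(state$ab)
  com <- if (total > 0) center_of_mass(state$ab, ctx$coords) else c(NA, NA)
  metrics <- data.frame(
    day = state$day,
    total_abundance = total,
    deaths_today = m$deaths,
    cumulative_deaths = state$deaths,
    avail_fraction = mean(wx_day$avail),
    com_x = com[1], com_y = com[2]
  )
  state$day <- state$day + 1L
  list(state = state, metrics = metrics)
}

#' Run a whole-season simulation
#'
#' Seeded and fully reproducible: the only random draw is the midwinter
#' inflection day of the arrival-weight schedule. Returns the daily
#' metric series (with the top-2% node sets), season and per-period
#' survivorship summaries, and the final state.
#'
#' @param land a `flyway_grid` (with cover columns; roosting quality
#'   and initial forage are derived if absent).
#' @param weather a `flyway_weather` from [derive_weather()] covering
#'   the season (days x nodes).
#' @param cfg a [sim_config()].
#' @param n0 initial population (defaults to `cfg$n0`).
#' @return `flyway_run` list: `metrics` (data.frame, one row per day),
#'   `top_nodes` (list of per-day top-2% node id vectors), `summary`,
#'   `state`, `ctx`, `cfg`, `inflection`.
#' @export
sim_run <- function(land, weather, cfg = sim_config(), n0 = cfg$n0) {
  n_days <- nrow(weather$WSI)
  n_nodes <- nrow(land$nodes)
  stopifnot(ncol(weather$WSI) == n_nodes)
  set.seed(cfg$seed)
  ctx <- build_run_context(land, cfg)
  ctx$coords <- land$nodes[, c("x", "y")]
  inflection <- draw_inflection_day(n_days)
  wts <- arrival_weights(seq_len(n_days), n_days, inflection)

  if (is.null(land$forage0)) {
    roost_dist <- ifelse(ctx$R > 0, 0, land$resolution)
    land$forage0 <- initial_forage(land$nodes[, COVER_CLASSES],
                                   land$nodes$area, cfg$forage_density,
                                   roost_dist, cfg$access_efold)
  }
  pop <- init_population(land, n0, cfg$n_classes, quality = ctx$R)
  state <- list(ab = pop$ab, forage = land$forage0, deaths = 0, day = 1L)

  metrics <- vector("list", n_days)
  top_nodes <- vector("list", n_days)
  if (is.null(weather$AD))
    weather$AD <- matrix(cfg$ref_air_density, n_days, n_nodes)
  for (k in seq_len(n_days)) {
    wx_day <- list(T_air = weather$T_air[k, ], WSI = weather$WSI[k, ],
                   AD = weather$AD[k, ], avail = weather$avail[k, ])
    res <- sim_step(state, wx_day, wts[k, ], ctx, cfg)
    state <- res$state
    metrics[[k]] <- res$metrics
    top_nodes[[k]] <- top_pct_nodes(rowSums(state$ab), 0.02,
                                    land$nodes$node_id)
  }
  metrics <- do.call(rbind, metrics)
  structure(list(metrics = metrics, top_nodes = top_nodes,
                 summary = season_summary(metrics, n0),
                 state = state, ctx = ctx, cfg = cfg,
                 inflection = inflection, n0 = n0),
            class = "flyway_run")
}

#' Season and per-period survivorship summary
#'
#' Periods follow the reporting windows of the non-breeding season:
#' autumn (days 1-91, 1 Sep - 30 Nov), winter (through 28/29 Feb) and
#' spring (through season end). Period survivorships multiply exactly
#' to the season survivorship.
#'
#' @param metrics daily metrics data.frame from [sim_run()].
#' @param n0 initial population.
#' @return list with `survivorship` (season) and a `periods` data.frame.
#' @export
season_summary <- function(metrics, n0) {
  n_days <- nrow(metrics)
  leap <- n_days >= 274
  bounds <- c(0, 91, if (leap) 182 else 181, n_days)
  bounds <- pmin(bounds, n_days)
  labels <- c("autumn", "winter", "spring")
  start_n <- c(n0, metrics$total_abundance[bounds[2:3]])
  end_n <- metrics$total_abundance[bounds[2:4]]
  periods <- data.frame(period = labels,
                        start_day = bounds[1:3] + 1,
                        end_day = bounds[2:4],
                        survivorship = end_n / start_n)
  list(survivorship = metrics$total_abundance[n_days] / n0,
       periods = periods)
}

#' @export
print.flyway_run <- function(x, ...) {
  cat(sprintf("<flyway_run> %d days, %d nodes, N0 = %.7g\n",
              nrow(x$metrics), nrow(x$state$ab), x$n0))
  cat(sprintf("  season survivorship %.4f (deaths %.5g)\n",
              x$summary$survivorship, x$state$deaths))
  print(x$summary$periods, row.names = FALSE)
  invisible(x)
}
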