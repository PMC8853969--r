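test_that("config carries the study defaults and rejects unknown keys", {
  cfg <- sim_config()
  expect_equal(cfg$n0, 19856514)
  expect_equal(cfg$wsi_threshold, 7.5)
  expect_equal(cfg$n_classes, 21)
  expect_equal(cfg$f_max, 0.11)
  expect_equal(cfg$fdr_coef, 0.011)
  expect_equal(c(cfg$s_min, cfg$s_max), c(0.99620, 0.99984))
  expect_equal(cfg$fat_energy, 39700)
  expect_error(sim_config(not_a_key = 1), "not_a_key")
  expect_error(sim_config(f_max = 2), "f_max")
})

test_that("mortality multiplies by class survivorship and flushes the dead", {
  sched <- build_schedule(n_classes = 4, s_min = 0.99620, s_max = 1)
  ab <- matrix(0, 2, 4)
  ab[1, 2] <- 1000; ab[2, 4] <- 500
  m <- apply_mortality(ab, sched)
  expect_equal(m$ab[1, 2], 996.2)             # s = 0.99620
  expect_equal(m$ab[2, 4], 500)               # s = 1
  expect_equal(m$deaths, 3.8)
  # the dead class is flushed entirely
  ab[1, 1] <- 77
  m <- apply_mortality(ab, sched)
  expect_equal(m$ab[1, 1], 0)
  expect_equal(m$deaths, 3.8 + 77)
  # with certain survival and an empty dead class, nothing dies
  s1 <- build_schedule(4, s_min = 1, s_max = 1)
  ab1 <- matrix(rep(c(0, 1, 1, 1), each = 2), 2, 4)
  expect_equal(apply_mortality(ab1, s1)$deaths, 0)
})

test_that("a single benign node is a fixed point of the daily step", {
  # one breeding node, certain survival, zero forage (so zero intake),
  # warm weather (no thermoregulatory cost): the state cannot change
  g <- toy_grid(1)
  cfg <- sim_config(s_min = 1, s_max = 1,
                    forage_density = c(shoreline = 0, crops = 0,
                                       woody_wetland = 0,
                                       herbaceous_wetland = 0,
                                       urban = 0, other = 0))
  wx <- toy_weather(3, 1, T_air = 20)
  run <- sim_run(g, wx, cfg, n0 = 1234)
  expect_equal(run$metrics$total_abundance, rep(1234, 3))
  expect_equal(run$state$ab[1, 21], 1234)
  expect_equal(run$state$deaths, 0)
})

test_that("one simulated day matches the brute-force enumeration oracle", {
  # 3-node, 3-class toy: the full forage -> departure -> arrival ->
  # mortality composition against independent scalar loops
  g <- toy_grid(3, spacing = 150)
  cfg <- sim_config(n_classes = 3)
  ctx <- flywaysim:::build_run_context(g, cfg)
  ctx$coords <- g$nodes[, c("x", "y")]
  w1 <- arrival_weights(40, 273, 140)
  forage0 <- initial_forage(g$nodes[, cover_classes], g$nodes$area,
                            cfg$forage_density,
                            ifelse(ctx$R > 0, 0, g$resolution))
  ab <- matrix(c(0, 0, 0,  40, 10, 5,  200, 120, 2000), 3, 3)
  # mixed weather: node 2 is frozen out
  wsi <- c(-5, 12, 3); avail <- wsi < 7.5
  T_air <- c(12, -6, 4); ad <- c(1.05, 1.22, 1.13)
  wx_day <- list(T_air = T_air, WSI = wsi, AD = ad, avail = avail)
  state <- list(ab = ab, forage = forage0, deaths = 0, day = 1L)
  got <- sim_step(state, wx_day, w1, ctx, cfg)
  oracle <- brute_force_day(ab, forage0, T_air, wsi, avail, ad,
                            ctx$dist, ctx$db, ctx$R, ctx$G, w1,
                            ctx$schedule, cfg)
  n0 <- sum(ab)
  expect_lt(max(abs(got$state$ab - oracle$ab)) / n0, 1e-10)
  expect_lt(abs(got$state$deaths - oracle$deaths) / n0, 1e-10)
  expect_lt(max(abs(got$state$forage - oracle$forage)) /
              max(oracle$forage), 1e-10)
})

test_that("runs are reproducible and internally consistent", {
  g <- synth_landscape(6, 5, seed = 3)
  wx <- synth_weather(g, n_days = 40, seed = 3)
  cfg <- sim_config(seed = 11)
  a <- sim_run(g, wx, cfg, n0 = 5000)
  b <- sim_run(g, wx, cfg, n0 = 5000)
  expect_identical(a$metrics, b$metrics)       # same seed, same series
  # accounting identity: final total equals N0 minus cumulative deaths
  expect_equal(a$metrics$total_abundance[40],
               5000 - a$metrics$cumulative_deaths[40], tolerance = 1e-9)
  # period survivorships multiply to the season survivorship
  full <- sim_run(g, synth_weather(g, n_days = 273, seed = 3), cfg,
                  n0 = 5000)
  expect_equal(prod(full$summary$periods$survivorship),
               full$summary$survivorship, tolerance = 1e-12)
})

test_that("uniform survivorship gives the closed-form season survival", {
  # single node, no starvation possible (zero gain), uniform s
  s <- 0.999
  g <- toy_grid(1)
  cfg <- sim_config(s_min = s, s_max = s,
                    forage_density = c(shoreline = 0, crops = 0,
                                       woody_wetland = 0,
                                       herbaceous_wetland = 0,
                                       urban = 0, other = 0))
  wx <- toy_weather(100, 1, T_air = 20)
  run <- sim_run(g, wx, cfg, n0 = 1e6)
  expect_equal(run$summary$survivorship, s^100, tolerance = 1e-12)
})
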