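test_that("departure components evaluate their Monod/linear forms", {
  # weather severity: half-saturation at the 7.5 threshold, exponent 3
  expect_equal(p_depart_wsi(7.5), 0.5)
  expect_equal(p_depart_wsi(-3), 0)
  expect_equal(p_depart_wsi(0), 0)
  expect_equal(p_depart_wsi(15), 3375 / 3796.875)
  # body condition: zero-based index, half-saturation at n - 3
  expect_equal(p_depart_bc(19, 21), 0.5)            # BC = 18 with n = 21
  expect_equal(p_depart_bc(1, 21), 0)               # dead class
  expect_equal(p_depart_bc(21, 21), 1 / (1 + 0.9^8))
  # breeding distance: half-saturation at the flight range
  expect_equal(p_depart_db(800, 800), 0.5)
  expect_equal(p_depart_db(0, 800), 0)
  expect_equal(p_depart_db(1600, 800), 32 / 33)
  expect_error(p_depart_db(100, 0), "positive")
  # daily gain, kJ form: 0.8 at zero gain, 0 beyond 4 kJ/day, 1 in deficit
  expect_equal(p_depart_dg(0), 0.8)
  expect_equal(p_depart_dg(4), 0)
  expect_equal(p_depart_dg(524), 0)
  expect_equal(p_depart_dg(-300), 1)
  # normalized form: linear from 0.8 down to 0.6
  expect_equal(p_depart_dg(0, "normalized"), 0.8)
  expect_equal(p_depart_dg(1, "normalized"), 0.6)
  dg <- seq(0, 1, by = 0.1)
  expect_true(all(diff(p_depart_dg(dg, "normalized")) < 0))
})

test_that("departure components are monotone in the stated directions", {
  expect_true(all(diff(p_depart_wsi(seq(0.5, 40, by = 0.5))) > 0))
  expect_true(all(diff(p_depart_bc(2:21, 21)) > 0))
  expect_true(all(diff(p_depart_db(seq(50, 3000, by = 50), 800)) > 0))
  expect_true(all(diff(p_depart_dg(seq(-5, 5, by = 0.5))) <= 0))
})

test_that("combined departure stays a probability under both rules", {
  expect_equal(combine_departure(0, 0, 0, 0), 0)
  expect_equal(combine_departure(0.5, 0.5, 0.5, 0.5), 0.5)
  expect_equal(combine_departure(1, 1, 1, 1), 1)
  expect_equal(combine_departure(1, 1, 1, 1, rule = "sum"), 1)
  expect_equal(combine_departure(0.9, 0.8, 0.9, 0.8, rule = "sum"), 1)
  set.seed(9)
  p <- replicate(4, runif(50))
  for (rule in c("mean", "sum")) {
    cmb <- combine_departure(p[, 1], p[, 2], p[, 3], p[, 4], rule)
    expect_true(all(cmb >= 0 & cmb <= 1))
  }
})

test_that("arrival weights hit the printed peaks and always sum to 1", {
  n <- 273
  w <- arrival_weights(1:n, n, inflection = 140)
  # at the inflection day c = 0.1: the printed input weights
  wi <- w[140, ]
  expect_equal(c(wi$wf, wi$wa, wi$wr, wi$wg), c(0.45, 0.30, 0.20, 0.05))
  expect_equal(wi$wb, 0, tolerance = 1e-12)
  # every day the five weights sum to 1 and wg is constant
  expect_equal(w$wf + w$wa + w$wr + w$wg + w$wb, rep(1, n))
  expect_equal(w$wg, rep(0.05, n))
  # at the season endpoints (c = 1) breeding distance dominates
  expect_equal(w$wf[1], -0.279)
  expect_equal(w$wb[1], 1.539)
  expect_equal(w$wf[n], -0.279)
  # the shape sequence runs 1 -> 0.1 -> 1
  expect_equal(w$c[c(1, 140, n)], c(1, 0.1, 1))
})

test_that("the inflection day is drawn inside the midwinter window", {
  set.seed(5)
  draws <- replicate(50, draw_inflection_day(273))
  expect_true(all(draws >= 122 & draws <= 153))
  set.seed(7); a <- draw_inflection_day(273)
  set.seed(7); b <- draw_inflection_day(273)
  expect_identical(a, b)
})

test_that("gamma kernel scores favour central nodes", {
  # five equally spaced nodes on a line: brute-force CDF means
  d <- as.matrix(dist(cbind(seq(0, 400, by = 100), 0)))
  g <- gamma_score(d, shape = 2, scale = 100)
  oracle <- sapply(1:5, function(j)
    mean(1 - pgamma(d[-j, j], 2, scale = 100)))
  oracle <- (oracle - min(oracle)) / diff(range(oracle))
  expect_equal(g, oracle, tolerance = 1e-12)
  expect_gte(g[3], g[1])                      # centre beats periphery
  expect_gte(g[3], g[5])
  # permutation invariance
  perm <- c(4, 2, 5, 1, 3)
  expect_equal(gamma_score(d[perm, perm], 2, 100), g[perm])
  # degenerate all-zero distances are guarded
  expect_equal(gamma_score(matrix(0, 3, 3), 2, 100), rep(1, 3))
  expect_error(gamma_score(d, shape = -1), "positive")
})

test_that("attractiveness reduces to known cases and a hand oracle", {
  w1 <- arrival_weights(140, 273, 140)        # the printed-weight day
  # identical components everywhere: uniform over permitted nodes
  att <- attractiveness(rep(5, 4), rep(1.1, 4), rep(0.2, 4), rep(100, 4),
                        rep(0.5, 4), w1, avail = c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(att$p, c(1, 1, 1, 0) / 3)
  # single-factor weights: ranking equals the forage ranking
  wF <- w1; wF$wf <- 1; wF$wa <- wF$wr <- wF$wg <- wF$wb <- 0
  F_v <- c(3, 9, 1, 5)
  att <- attractiveness(F_v, rep(1, 4), rep(1, 4), rep(1, 4), rep(1, 4),
                        wF, avail = rep(TRUE, 4))
  expect_equal(order(att$p), order(F_v))
  # three-node toy against an explicit Cobb-Douglas evaluation
  F_v <- c(100, 400, 250); AD <- c(1.0, 1.2, 1.1); R <- c(0.1, 0.4, 0.2)
  DB <- c(500, 0, 250); G <- c(0.2, 0.9, 0.5)
  mm <- function(x) (x - min(x)) / (max(x) - min(x))
  fl <- function(x) pmax(1e-6, x)
  a_or <- fl(mm(F_v))^w1$wf * fl(mm(AD))^w1$wa * fl(mm(R))^w1$wr *
    fl(mm(1 - mm(DB)))^w1$wb * fl(mm(G))^w1$wg
  att <- attractiveness(F_v, AD, R, DB, G, w1, avail = rep(TRUE, 3))
  expect_equal(att$p, a_or / sum(a_or), tolerance = 1e-12)
  # no permitted node signals the fallback
  expect_null(attractiveness(F_v, AD, R, DB, G, w1, avail = rep(FALSE, 3)))
})

test_that("redistribution swaps a 2-node toy and conserves abundance", {
  sched <- build_schedule(n_classes = 5, f_max = 0.11)
  d <- matrix(c(0, 500, 500, 0), 2, 2)
  cost <- 1e-5
  tabs <- movement_tables(d, sched, cost)
  # everyone departs node 1; arrival mass all on node 2
  ab <- matrix(0, 2, 5); ab[1, 5] <- 100
  p_dep <- matrix(1, 2, 5)
  out <- redistribute(ab, p_dep, A = c(0, 1), tabs)
  # top class fat 0.132, flight burns 0.005 -> floor class is 5 - 1
  drop_to <- findInterval(0.132 - 500 * cost + 1e-12, sched$fat)
  expect_equal(sum(out[2, ]), 100)
  expect_equal(out[2, drop_to], 100)
  # zero departure is the identity
  expect_equal(redistribute(ab, matrix(0, 2, 5), c(0, 1), tabs), ab)
  # no permitted destination: stay put
  expect_equal(redistribute(ab, p_dep, c(0, 0), tabs), ab)
})

test_that("redistribution conserves abundance on randomized fuzz days", {
  set.seed(21)
  g <- toy_grid(6, spacing = 120)
  d <- distance_matrix(g)
  sched <- build_schedule(n_classes = 7)
  tabs <- movement_tables(d, sched, 1e-4)
  worst <- 0
  for (day in 1:1000) {
    ab <- matrix(rexp(6 * 7), 6, 7) * 50
    p_dep <- matrix(runif(6 * 7), 6, 7)
    A <- runif(6); A[sample(6, sample(0:5, 1))] <- 0
    out <- redistribute(ab, p_dep, A, tabs)
    worst <- max(worst, abs(sum(out) - sum(ab)) / sum(ab))
    if (day %% 250 == 0) expect_true(all(out >= 0))
  }
  expect_lt(worst, 1e-10)
})
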