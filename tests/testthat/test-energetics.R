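test_that("condition schedule has the documented shape", {
  s <- build_schedule()
  expect_equal(nrow(s), 21)
  expect_equal(s$s[1], 0)                    # class 1 is the dead class
  expect_equal(s$s[2], 0.99620)
  expect_equal(s$s[21], 0.99984)
  expect_equal(s$f[1], 0)
  expect_equal(s$f[21], 0.11)
  expect_true(all(diff(s$f[-1]) > 0))        # fat strictly increasing
  expect_true(all(diff(s$s[-1]) >= 0))       # survivorship nondecreasing
  expect_true(all(s$s >= 0 & s$s <= 1))
  # degenerate 3-class case with certain survival
  s3 <- build_schedule(3, s_min = 1, s_max = 1)
  expect_equal(s3$s, c(0, 1, 1))
})

test_that("classes above the optimal fat mass get the survivorship cap", {
  # with the highest fat ceiling, top classes exceed ~0.134 kg of fat
  s <- build_schedule(f_max = 0.14)
  over <- s$fat > 0.134
  expect_true(any(over))
  expect_true(all(s$s[over] <= s$s[20]))
  # default ceiling (0.132 kg at the top) stays under the cap
  expect_equal(build_schedule()$s[21], 0.99984)
  expect_error(build_schedule(s_min = 0.9, s_max = 0.8), "bounds")
})

test_that("forage decays by the retention weight per day", {
  expect_equal(decay_forage(100, 0.9910), 99.10)   # herbaceous wetland
  expect_equal(decay_forage(123.4, 1), 123.4)
  # shoreline over 100 days from 100 kJ
  f <- 100
  for (i in 1:100) f <- decay_forage(f, 0.9998)
  expect_equal(f, 100 * 0.9998^100)
  expect_equal(round(f, 2), 98.02)
  # matrix input recycles weights over cover-class columns
  m <- matrix(100, 2, 2, dimnames = list(NULL, c("shoreline", "crops")))
  out <- decay_forage(m, c(0.9998, 0.9970))
  expect_equal(out[1, ], c(shoreline = 99.98, crops = 99.70))
  expect_error(decay_forage(100, 0), "\\(0, 1\\]")
  expect_error(decay_forage(100, 1.2), "\\(0, 1\\]")
})

test_that("daily gain combines deposition, disturbance, access and cost", {
  # fuel deposition of the reference bird: 0.011 * 1.2 * 39700
  g <- daily_gain(T_air = 15, available = TRUE, disturbance = 0)
  expect_equal(g$intake, 524.04)
  # full disturbance or an unavailable node zero the intake
  expect_equal(daily_gain(15, TRUE, disturbance = 1)$intake, 0)
  expect_equal(daily_gain(15, FALSE, 0)$intake, 0)
  # net gain is positive in benign conditions (standalone default
  # subtracts the full allometric basal rate)
  expect_gt(daily_gain(15, TRUE, 0, bmr0_coef = 308)$gain, 0)
  expect_equal(daily_gain(15, TRUE, 1)$gain, -bmr(15))
})

test_that("metabolic cost rises linearly below the critical temperature", {
  expect_equal(bmr(15) - bmr(20), 0)           # above T_lc: flat
  expect_equal(bmr(0) - bmr(10), 150)          # 10 degC below at 15 kJ/degC
  expect_equal(bmr(0, bmr0_coef = 0), 150)
})

test_that("forage rationing is proportional and never oversubscribes", {
  expect_equal(allocate_forage(100, 200)$fraction, 1)
  expect_equal(allocate_forage(100, 50)$fraction, 0.5)
  expect_equal(allocate_forage(100, 50)$consumed, 50)
  r0 <- allocate_forage(0, 50)
  expect_equal(r0$fraction, 1)
  expect_equal(r0$consumed, 0)
  expect_equal(allocate_forage(c(10, 0), c(2, 5))$fraction, c(0.2, 1))
})

test_that("class transitions quantize fat to the floor and conserve mass", {
  sched <- build_schedule()
  slice <- c(0, rep(10, 20))
  # no energy change: identity
  expect_equal(transition_classes(slice, 0, sched), slice)
  # a 500 km flight at 1e-4 kg/km drops 0.05 kg of fat: the top class
  # (0.132 kg) lands at 0.082 kg, the floor class on the ladder (13)
  out <- transition_classes(c(rep(0, 20), 100), -0.05, sched)
  expect_equal(out[13], 100)
  expect_equal(sum(out), 100)
  # large positive gain from the top stays at the top
  out <- transition_classes(c(rep(0, 20), 7), +1, sched)
  expect_equal(out[21], 7)
  # starvation: falling below the class-2 fat mass lands in class 1,
  # unless starvation transitions are disabled
  out <- transition_classes(c(0, 5, rep(0, 19)), -0.001, sched)
  expect_equal(out[1], 5)
  out <- transition_classes(c(0, 5, rep(0, 19)), -0.001, sched,
                            starvation = FALSE)
  expect_equal(out[2], 5)
})

test_that("matrix transitions conserve abundance over random states", {
  sched <- build_schedule()
  set.seed(4)
  for (rep in 1:20) {
    ab <- matrix(runif(8 * 21) * 100, 8, 21)
    dfat <- runif(8, -0.05, 0.05)
    out <- transition_classes(ab, dfat, sched)
    expect_equal(sum(out), sum(ab), tolerance = 1e-12)
    expect_true(all(out >= 0))
    # the dead class never loses mass to transitions
    expect_gte(out[1, 1] + 1e-12, ab[1, 1])
  }
})
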