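wt <- wt_params()

test_that("logistic biomass honours its fixed points and oracle value", {
  # fixed point: starting at carrying capacity stays there
  p_sat <- kinetic_params(mu_max = 0.45, X_max = 9.41, X0 = 9.41)
  expect_equal(logistic_biomass(c(0, 3, 50), p_sat), rep(9.41, 3))
  # initial condition
  expect_equal(logistic_biomass(0, wt), wt$X0)
  # frozen RK4 oracle value (scipy solve_ivp, rtol 1e-12)
  expect_equal(logistic_biomass(12, wt), 8.709048145848833, tolerance = 1e-8)
  # saturation and monotonicity
  x <- logistic_biomass(seq(0, 60, by = 0.5), wt)
  expect_true(all(diff(x) >= 0))
  expect_equal(x[length(x)], wt$X_max, tolerance = 1e-6)
})

test_that("parameter validation rejects inconsistent sets", {
  expect_error(kinetic_params(mu_max = 0.45, X_max = 9.41, X0 = 10),
               "X0")
  expect_error(kinetic_params(mu_max = 0.45, X_max = -1),
               "X_max")
  expect_error(kinetic_params(mu_max = 0.45, X_max = 9.41, Y_XS = 0),
               "Y_XS")
  expect_error(logistic_biomass(-1, wt), "non-negative")
})

test_that("biomass integral matches quadrature and its defining properties", {
  expect_equal(biomass_integral(0, wt), 0)
  # constant-integrand limit: X0 = X_max gives X_max * t
  p_sat <- kinetic_params(mu_max = 0.45, X_max = 9.41, X0 = 9.41)
  expect_equal(biomass_integral(c(1, 7), p_sat), 9.41 * c(1, 7))
  # mu_max = 0 short-circuit
  p0 <- kinetic_params(mu_max = 0, X_max = 9.41, X0 = 0.5)
  expect_equal(biomass_integral(5, p0), 2.5)
  # frozen adaptive-quadrature oracle (scipy quad, 1e-12)
  expect_equal(biomass_integral(12, wt), 53.16629752728653, tolerance = 1e-8)
  # derivative of the integral is the integrand (central differences)
  h <- 1e-5
  for (tt in c(1, 4, 9)) {
    num <- (biomass_integral(tt + h, wt) - biomass_integral(tt - h, wt)) /
      (2 * h)
    expect_equal(num, logistic_biomass(tt, wt), tolerance = 1e-8)
  }
})

test_that("product titer follows Luedeking-Piret closed form", {
  # no production
  p_none <- kinetic_params(mu_max = 0.45, X_max = 9.41, alpha = 0, beta = 0,
                           P0 = 0.3)
  expect_equal(product_titer(c(0, 5, 12), p_none), rep(0.3, 3))
  # purely growth-associated limit
  ts <- seq(0, 12, by = 1.5)
  expect_equal(product_titer(ts, wt) - wt$P0,
               wt$alpha * (logistic_biomass(ts, wt) - wt$X0))
  # frozen coupled-RK4 oracle value at day 12
  expect_equal(product_titer(12, wt), 0.12313572218773246, tolerance = 1e-8)
  expect_equal(product_titer(0, wt), wt$P0)
})

test_that("sugar residual follows the consumption closed form", {
  expect_equal(suppressWarnings(sugar_residual(0, wt)), wt$S0)
  # no-maintenance limit
  p_nm <- kinetic_params(mu_max = 0.45, X_max = 9.41, Y_XS = 0.63,
                         M_s = 0, S0 = 35)
  ts <- seq(0, 12, by = 2)
  expect_equal(sugar_residual(ts, p_nm),
               35 - (logistic_biomass(ts, p_nm) - 0.5) / 0.63)
  # frozen RK4 oracle value
  expect_equal(suppressWarnings(sugar_residual(12, wt)),
               15.589809144581452, tolerance = 1e-8)
  # exhaustion past zero warns but is not clamped
  p_hot <- kinetic_params(mu_max = 0.6, X_max = 12, Y_XS = 0.4, M_s = 0.3,
                          S0 = 10)
  expect_warning(s <- sugar_residual(c(0, 20), p_hot), "negative")
  expect_lt(s[2], 0)
})

test_that("peak growth rate equals mu_max X_max / 4 below the inflection", {
  expect_equal(peak_growth_rate(wt), 0.45 * 9.41 / 4)
  expect_equal(peak_growth_rate(wt), 1.05, tolerance = 0.01)
  p0 <- kinetic_params(mu_max = 0, X_max = 9.41)
  expect_equal(peak_growth_rate(p0), 0)
  # grid-search oracle on random parameter sets, including X0 > X_max/2
  set.seed(11)
  for (i in 1:10) {
    p <- random_params_near_wt()
    if (i > 7) p$X0 <- p$X_max * 0.8  # start past the inflection point
    grid <- seq(0, 40, by = 1e-3)
    x <- logistic_biomass(grid, p)
    dmax <- max(p$mu_max * x * (1 - x / p$X_max))
    expect_equal(peak_growth_rate(p), dmax, tolerance = 1e-5)
  }
})

test_that("simulate: closed form and ODE integration agree", {
  ts <- 0:12
  a <- simulate_timecourse(wt, ts, method = "closed_form")
  b <- simulate_timecourse(wt, ts, method = "ode")
  for (col in c("X", "S", "P")) {
    expect_equal(a[[col]], b[[col]], tolerance = 1e-6)
  }
  expect_error(simulate_timecourse(wt, ts, method = "rk45"), "arg")
  one <- simulate_timecourse(wt, 0)
  expect_identical(nrow(one), 1L)
  expect_equal(unlist(one[1, c("X", "S", "P")], use.names = FALSE),
               c(wt$X0, wt$S0, wt$P0))
})

test_that("oracle equivalence holds across random parameter sets", {
  set.seed(42)
  ts <- seq(0, 12, by = 3)
  for (i in 1:25) {
    p <- random_params_near_wt()
    cf <- simulate_timecourse(p, ts, method = "closed_form")
    rk <- oracle_rk4(p, ts)
    expect_equal(cf$X, rk$X, tolerance = 1e-6)
    expect_equal(cf$S, rk$S, tolerance = 1e-6)
    expect_equal(cf$P, rk$P, tolerance = 1e-6)
  }
})

test_that("trajectory invariants: monotone X up, S down, P up", {
  set.seed(7)
  ts <- seq(0, 12, by = 0.5)
  for (i in 1:20) {
    p <- random_params_near_wt()
    tc <- suppressWarnings(simulate_timecourse(p, ts))
    expect_true(all(diff(tc$X) >= -1e-12))
    expect_true(all(diff(tc$S) <= 1e-12))
    expect_true(all(diff(tc$P) >= -1e-12))
    # conservation: P - P0 decomposes exactly into its two terms
    expect_equal(tc$P - p$P0,
                 p$alpha * (tc$X - p$X0) + p$beta * biomass_integral(ts, p))
  }
})

test_that("simulated peak finite-difference rate approaches V_max", {
  tc <- simulate_timecourse(wt, seq(0, 12, by = 0.01))
  fd <- max(diff(tc$X) / diff(tc$time))
  expect_equal(fd, 0.45 * 9.41 / 4, tolerance = 1e-3)
  expect_equal(fd, 1.05, tolerance = 0.01)  # printed V_max
})
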