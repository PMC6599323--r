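wt <- wt_params()
daily <- 0:12

test_that("goodness_of_fit matches hand-computed arithmetic", {
  g <- goodness_of_fit(c(1, 2, 3, 4), c(1.1, 1.9, 3.2, 3.8), n_params = 1)
  # SSE = 0.10, SST = 5, SSR = 4.9 -> r2 = 0.98, F = 4.9/(0.1/2) = 98
  expect_equal(g$sse, 0.10)
  expect_equal(g$sst, 5)
  expect_equal(g$r2, 0.98)
  expect_equal(g$f_value, 98)
  # perfect and null predictions
  expect_equal(goodness_of_fit(1:4, 1:4, 1)$r2, 1)
  expect_identical(goodness_of_fit(1:4, 1:4, 1)$f_value, Inf)
  expect_equal(goodness_of_fit(1:4, rep(2.5, 4), 1)$r2, 0)
  expect_error(goodness_of_fit(rep(2, 5), rep(2, 5), 1), "degenerate")
  expect_error(goodness_of_fit(1:3, 1:3, 2), "n_params \\+ 2")
})

test_that("fit_biomass recovers generating parameters from noiseless data", {
  tc <- simulate_timecourse(wt, daily)
  fb <- fit_biomass(tc, fit_config(n_starts = 8, seed = 1))
  expect_lt(rel_err(fb$params$mu_max, 0.45), 1e-4)
  expect_lt(rel_err(fb$params$X_max, 9.41), 1e-4)
  expect_lt(rel_err(fb$params$X0, 0.5), 1e-3)
  expect_gt(fb$r2$X, 1 - 1e-10)
  expect_true(fb$converged)
})

test_that("fit_biomass matches a brute-force grid search on 5 points", {
  p <- kinetic_params(mu_max = 0.6, X_max = 8, X0 = 0.4)
  ts <- c(0, 2, 4, 7, 10)
  y <- logistic_biomass(ts, p)
  fb <- fit_biomass(timecourse(ts, X = y),
                    fit_config(n_starts = 8, fix = list(X0 = 0.4)))
  # 200 x 200 lattice oracle over (mu, X_max)
  mus <- seq(0.2, 1.2, length.out = 200)
  xms <- seq(5, 12, length.out = 200)
  sse <- outer(mus, xms, Vectorize(function(m, xm) {
    xt <- xm * 0.4 * exp(m * ts) / (xm - 0.4 + 0.4 * exp(m * ts))
    sum((y - xt)^2)
  }))
  idx <- which(sse == min(sse), arr.ind = TRUE)[1, ]
  expect_lt(abs(fb$params$mu_max - mus[idx[1]]), diff(mus[1:2]) * 1.5)
  expect_lt(abs(fb$params$X_max - xms[idx[2]]), diff(xms[1:2]) * 1.5)
  expect_lte(fb$sse$X, min(sse))
})

test_that("fit_biomass flags degenerate and underdetermined inputs", {
  expect_error(fit_biomass(timecourse(0:5, X = rep(2, 6))), "degenerate")
  expect_error(fit_biomass(timecourse(c(0, 1, 2), X = c(1, 2, 3))),
               "underdetermined")
  # stationary culture with X0 fixed at the constant level is legitimate
  fb <- fit_biomass(timecourse(0:5, X = rep(2, 6)),
                    fit_config(fix = list(X0 = 2)))
  expect_equal(fb$params$mu_max, 0)
  expect_equal(fb$sse$X, 0)
})

test_that("conditional product fit equals the normal-equations solution", {
  p <- kinetic_params(mu_max = 0.45, X_max = 9.41, alpha = 0.02,
                      beta = 0.004, P0 = 0.05)
  ts <- seq(0, 12, by = 0.5)
  tc <- simulate_timecourse(p, ts)
  fp <- fit_product(tc, p, fit_config())
  expect_equal(fp$params$alpha, 0.02, tolerance = 1e-8)
  expect_equal(fp$params$beta, 0.004, tolerance = 1e-8)
  # independent linear-algebra oracle: solve the normal equations directly
  A <- cbind(logistic_biomass(ts, p) - p$X0, biomass_integral(ts, p))
  ab <- solve(t(A) %*% A, t(A) %*% (tc$P - p$P0))
  expect_equal(fp$params$alpha, ab[1], tolerance = 1e-8)
  expect_equal(fp$params$beta, ab[2], tolerance = 1e-8)
})

test_that("fit_product respects the beta >= 0 constraint and P contract", {
  tc <- simulate_timecourse(wt, daily)  # generated with beta = 0
  fp <- fit_product(tc, wt, fit_config())
  expect_equal(fp$params$alpha, 0.015, tolerance = 1e-6)
  expect_lt(fp$params$beta, 1e-6)
  expect_gte(fp$params$beta, 0)
  # constant product: no production at all
  flat <- timecourse(daily, P = rep(wt$P0, 13))
  fp0 <- fit_product(flat, wt, fit_config())
  expect_equal(fp0$params$alpha, 0)
  expect_equal(fp0$params$beta, 0)
  expect_error(fit_product(timecourse(daily, X = daily + 1), wt,
                           fit_config()), "missing-response")
})

test_that("fit_sugar recovers yield and maintenance coefficients", {
  tc <- simulate_timecourse(wt, daily)
  fs <- fit_sugar(tc, wt, fit_config())
  expect_equal(fs$params$Y_XS, 0.63, tolerance = 1e-6)
  expect_equal(fs$params$M_s, 0.12, tolerance = 1e-6)
  # linear-regression oracle on consumed sugar
  A <- cbind(logistic_biomass(daily, wt) - wt$X0,
             biomass_integral(daily, wt))
  cf <- solve(t(A) %*% A, t(A) %*% (wt$S0 - tc$S))
  expect_equal(1 / fs$params$Y_XS, cf[1], tolerance = 1e-8)
  expect_equal(fs$params$M_s, cf[2], tolerance = 1e-8)
  # unidentifiable: nothing consumed, nothing grown
  p_flat <- kinetic_params(mu_max = 0, X_max = 2, X0 = 2, M_s = 0, S0 = 20)
  still <- suppressWarnings(simulate_timecourse(p_flat, daily))
  expect_error(fit_sugar(still, p_flat, fit_config()), "degenerate")
})

test_that("fit_full recovers all six parameters and honours partial data", {
  tc <- simulate_timecourse(wt, daily)
  ff <- fit_full(tc, fit_config(n_starts = 8, seed = 1))
  truth <- c(mu_max = 0.45, X_max = 9.41, alpha = 0.015,
             Y_XS = 0.63, M_s = 0.12)
  for (nm in names(truth)) {
    expect_lt(rel_err(ff$params[[nm]], truth[[nm]]), 1e-3)
  }
  expect_lt(ff$params$beta, 1e-6)
  expect_equal(ff$r2$pooled, 1, tolerance = 1e-9)
  # partial data: no product column -> no P entry in the r2 map
  ff2 <- fit_full(tc[, c("time", "X", "S")], fit_config(n_starts = 4))
  expect_false("P" %in% names(ff2$r2))
  expect_true(all(c("X", "S") %in% names(ff2$r2)))
})

test_that("joint and sequential strategies agree on noiseless data", {
  tc <- simulate_timecourse(wt, daily)
  fs <- fit_full(tc, fit_config("sequential", n_starts = 6, seed = 2))
  fj <- fit_full(tc, fit_config("joint", n_starts = 6, seed = 2))
  for (nm in c("mu_max", "X_max", "alpha", "Y_XS", "M_s")) {
    expect_lt(abs(fj$params[[nm]] - fs$params[[nm]]) /
                max(abs(fs$params[[nm]]), 1e-3), 1e-3)
  }
})

test_that("parameter recovery holds across random generating sets", {
  set.seed(99)
  for (i in 1:12) {
    p <- random_params_near_wt()
    tc <- suppressWarnings(simulate_timecourse(p, daily))
    ff <- fit_full(tc, fit_config(n_starts = 6, seed = i))
    for (nm in c("mu_max", "X_max", "Y_XS", "M_s", "alpha", "beta")) {
      truth <- p[[nm]]
      if (truth > 1e-6) {
        expect_lt(rel_err(ff$params[[nm]], truth), 1e-3)
      } else {
        expect_lt(abs(ff$params[[nm]] - truth), 1e-5)
      }
    }
  }
})

test_that("enlarging the start budget never worsens the best fit", {
  p <- random_params_near_wt()
  set.seed(3)
  tc <- generate_timecourse(wt, daily,
                            noise_spec("proportional", 0.08, seed = 3))
  sse <- vapply(c(3L, 6L, 12L), function(k) {
    fit_biomass(tc, fit_config(n_starts = k, seed = 5))$sse$X
  }, numeric(1))
  expect_true(all(diff(sse) <= 1e-9))
})
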