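#' Configuration for kinetic model fitting
#'
#' @param strategy `"sequential"` (default) fits biomass first, then the
#'   product and sugar equations conditional on the fitted growth curve,
#'   exploiting the fact that (alpha, beta) and (1/Y_XS, M_s) enter
#'   linearly once X(t) is known. `"joint"` minimises a single weighted
#'   least-squares criterion over all parameters at once.
#' @param bounds Optional named list of `c(lower, upper)` pairs overriding
#'   the default parameter bounds.
#' @param n_starts Number of seeded random starts for the nonlinear stages
#'   (>= 1). Starts are drawn sequentially from the seeded stream, so
#'   enlarging `n_starts` only appends starts and can never lose the best
#'   solution found with fewer.
#' @param seed Integer seed for the start stream.
#' @param tolerance Convergence tolerance passed to the optimiser.
#' @param fix Named list of parameters to hold fixed (e.g.
#'   `list(X0 = 0.5)`).
#' @return A `fit_config` list.
#' @export
fit_config <- function(strategy = c("sequential", "joint"), bounds = NULL,
                       n_starts = 20L, seed = 0L, tolerance = 1e-10,
                       fix = list()) {
  strategy <- match.arg(strategy)
  stopifnot(n_starts >= 1L, is.list(fix))
  if (!is.null(bounds)) {
    ok <- vapply(bounds, function(b) length(b) == 2L && b[1] <= b[2],
                 logical(1))
    if (!all(ok)) stop("fit_config: each bound must be c(lower, upper)",
                       call. = FALSE)
  }
  structure(list(strategy = strategy, bounds = bounds,
                 n_starts = as.integer(n_starts), seed = as.integer(seed),
                 tolerance = tolerance, fix = fix),
            class = "fit_config")
}

#' Goodness of fit of a predicted series
#'
#' Computes the coefficient of determination R^2 = 1 - SSE/SST and a
#' regression F statistic F = (SSR/p) / (SSE/(n - p - 1)) with
#' SSR = SST - SSE and p the number of fitted parameters. A perfect fit
#' (SSE = 0) reports `f_value = Inf`.
#'
#' @param observed,predicted Numeric vectors of equal length
#'   >= `n_params + 2`.
#' @param n_params Number of fitted parameters p.
#' @return List with `r2`, `f_value`, `sse`, `sst`, `n`.
#' @examples
#' goodness_of_fit(c(1, 2, 3, 4), c(1.1, 1.9, 3.2, 3.8), n_params = 1)
#' @export
goodness_of_fit <- function(observed, predicted, n_params) {
  if (length(observed) != length(predicted)) {
    stop("goodness_of_fit: series lengths differ", call. = FALSE)
  }
  n <- length(observed)
  if (n < n_params + 2) {
    stop("goodness_of_fit: need at least n_params + 2 observations",
         call. = FALSE)
  }
  sst <- sum((observed - mean(observed))^2)
  if (sst == 0) {
    stop("degenerate-statistic: observations are constant (SST = 0)",
         call. = FALSE)
  }
  sse <- sum((observed - predicted)^2)
  ssr <- sst - sse
  f <- if (sse == 0) Inf else (ssr / n_params) / (sse / (n - n_params - 1))
  list(r2 = 1 - sse / sst, f_value = f, sse = sse, sst = sst, n = n)
}

# ---- internal fitting machinery ------------------------------------------

# logistic curve without object validation (hot loop)
logistic_xt <- function(t, mu, Xmax, X0) {
  e <- exp(-mu * t)
  Xmax * X0 / (X0 + (Xmax - X0) * e)
}

integral_xt <- function(t, mu, Xmax, X0) {
  if (mu == 0) return(X0 * t)
  e <- exp(-mu * t)
  # optimisers probe just outside the feasible box; clamp the log argument
  arg <- pmax((X0 + (Xmax - X0) * e) / Xmax, .Machine$double.xmin)
  (Xmax / mu) * (mu * t + log(arg))
}

# default box bounds; data-driven X_max cap per design convention
default_bounds <- function(data, cfg) {
  xmax_obs <- if (!is.null(data$X) && any(is.finite(data$X))) {
    max(data$X, na.rm = TRUE)
  } else 10
  b <- list(mu_max = c(1e-6, 5),
            X_max = c(1e-6, 5 * max(xmax_obs, 1e-3)),
            X0 = c(1e-9, max(xmax_obs, 1e-3)),
            alpha = c(0, 10),
            beta = c(0, 10),
            Y_XS = c(1e-6, 100),
            M_s = c(0, 10))
  if (!is.null(cfg$bounds)) b[names(cfg$bounds)] <- cfg$bounds
  b
}

# seeded stream of uniform starts within bounds; start k is independent of
# n_starts so enlarging the budget only appends candidates
start_stream <- function(bounds_mat, n, seed, heuristic = NULL) {
  set.seed(seed)
  starts <- vector("list", n)
  i <- 1L
  if (!is.null(heuristic)) {
    starts[[1L]] <- pmin(pmax(heuristic, bounds_mat[, 1L]), bounds_mat[, 2L])
    i <- 2L
  }
  while (i <= n) {
    u <- stats::runif(nrow(bounds_mat))
    starts[[i]] <- bounds_mat[, 1L] + u * (bounds_mat[, 2L] - bounds_mat[, 1L])
    i <- i + 1L
  }
  starts
}

run_multistart <- function(objective, starts, lower, upper, tolerance) {
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      stats::optim(s, objective, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(factr = max(tolerance / 1e-15, 10),
                                  maxit = 1000)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) {
    stop("optimisation failed from every start", call. = FALSE)
  }
  # Nelder-Mead polish then a final bounded refinement
  pol <- tryCatch(
    stats::optim(best$par, objective, control = list(reltol = 1e-14,
                                                     maxit = 2000)),
    error = function(e) NULL)
  if (!is.null(pol) && pol$value < best$value) {
    pol$par <- pmin(pmax(pol$par, lower), upper)
    ref <- tryCatch(
      stats::optim(pol$par, objective, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(factr = 10, maxit = 1000)),
      error = function(e) pol)
    if (ref$value <= pol$value) best <- ref else best <- pol
  }
  best
}

# two-variable non-negative least squares by active set enumeration:
# minimise ||A c - y||^2 subject to c >= 0 (A has 2 columns)
nnls2 <- function(A, y) {
  candidates <- list()
  sol_unc <- tryCatch(qr.solve(crossprod(A), crossprod(A, y)),
                      error = function(e) NULL)
  if (!is.null(sol_unc) && all(sol_unc >= 0)) {
    candidates <- c(candidates, list(as.numeric(sol_unc)))
  }
  for (j in 1:2) {
    a <- A[, j]
    cj <- if (sum(a^2) > 0) max(0, sum(a * y) / sum(a^2)) else 0
    c_try <- c(0, 0); c_try[j] <- cj
    candidates <- c(candidates, list(c_try))
  }
  candidates <- c(candidates, list(c(0, 0)))
  sse <- vapply(candidates,
                function(cc) sum((y - A %*% cc)^2), numeric(1))
  as.numeric(candidates[[which.min(sse)]])
}

# observed tables are validated; model-generated timecourses may carry a
# (warned-about) negative predicted sugar and are taken as-is
coerce_timecourse <- function(data) {
  if (inherits(data, "timecourse")) return(data)
  as_timecourse(as.data.frame(data))
}

response_series <- function(data, col) {
  keep <- is.finite(data[[col]])
  list(t = data$time[keep], y = data[[col]][keep], n = sum(keep))
}

new_fit_result <- function(params, r2, f_value, sse, sst, n_obs,
                           converged, n_starts_used, seed, strategy,
                           se = NULL) {
  structure(list(params = params, se = se, r2 = r2, f_value = f_value,
                 sse = sse, sst = sst, n_obs = n_obs, converged = converged,
                 n_starts_used = n_starts_used, seed = seed,
                 strategy = strategy),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("Kinetic model fit (", x$strategy, " strategy)\n", sep = "")
  est <- unlist(x$params[vapply(x$params, is.numeric, logical(1))])
  cat("Estimates:\n")
  print(round(est, 6))
  cat("R-squared per response:\n")
  print(vapply(x$r2, function(v) round(v, 4), numeric(1)))
  cat("Converged:", x$converged, " (", x$n_starts_used, "starts )\n")
  invisible(x)
}

# ---- biomass fit ---------------------------------------------------------

#' Fit the logistic growth parameters to biomass data
#'
#' Estimates (mu_max, X_max, X0) by multi-start bounded least squares on
#' the closed-form logistic curve. X0 may be held fixed via
#' `cfg$fix$X0`.
#'
#' @param data A [timecourse()] with a biomass column `X`.
#' @param cfg A [fit_config()].
#' @return A `fit_result` whose `params` holds `mu_max`, `X_max`, `X0`.
#' @examples
#' tc <- simulate_timecourse(wt_params(), 0:12)
#' fit_biomass(tc, fit_config())
#' @export
fit_biomass <- function(data, cfg = fit_config()) {
  data <- coerce_timecourse(data)
  if (is.null(data$X)) stop("missing-response: no biomass column 'X'",
                            call. = FALSE)
  obs <- response_series(data, "X")
  if (length(unique(obs$t)) < 4L) {
    stop("underdetermined: need >= 4 distinct time points with biomass",
         call. = FALSE)
  }
  if (diff(range(obs$y)) == 0) {
    x0_fix <- cfg$fix$X0
    if (!is.null(x0_fix) && isTRUE(all.equal(x0_fix, obs$y[1]))) {
      params <- c(mu_max = 0, X_max = obs$y[1], X0 = obs$y[1])
      return(new_fit_result(as.list(params),
                            r2 = list(X = NA_real_),
                            f_value = list(X = NA_real_),
                            sse = list(X = 0), sst = list(X = 0),
                            n_obs = list(X = obs$n), converged = TRUE,
                            n_starts_used = 0L, seed = cfg$seed,
                            strategy = cfg$strategy))
    }
    stop("degenerate-data: biomass is constant over time", call. = FALSE)
  }
  b <- default_bounds(data, cfg)
  fixed_x0 <- cfg$fix$X0

  par_names <- c("mu_max", "X_max", if (is.null(fixed_x0)) "X0")
  bm <- do.call(rbind, b[par_names])
  objective <- function(par) {
    mu <- par[1]; Xmax <- par[2]
    X0 <- if (is.null(fixed_x0)) par[3] else fixed_x0
    if (X0 > Xmax) return(1e10 * (1 + (X0 - Xmax)^2))
    sum((obs$y - logistic_xt(obs$t, mu, Xmax, X0))^2)
  }
  heur <- biomass_heuristic_start(obs)
  starts <- start_stream(bm, cfg$n_starts, cfg$seed,
                         heuristic = heur[par_names])
  best <- run_multistart(objective, starts, bm[, 1], bm[, 2], cfg$tolerance)

  mu <- best$par[1]; Xmax <- best$par[2]
  X0 <- if (is.null(fixed_x0)) best$par[3] else fixed_x0
  pred <- logistic_xt(obs$t, mu, Xmax, X0)
  gof <- safe_gof(obs$y, pred, n_params = length(par_names))
  new_fit_result(list(mu_max = mu, X_max = Xmax, X0 = X0),
                 r2 = list(X = gof$r2), f_value = list(X = gof$f_value),
                 sse = list(X = gof$sse), sst = list(X = gof$sst),
                 n_obs = list(X = obs$n), converged = is.finite(best$value),
                 n_starts_used = cfg$n_starts, seed = cfg$seed,
                 strategy = cfg$strategy)
}

biomass_heuristic_start <- function(obs) {
  xmax0 <- 1.05 * max(obs$y)
  # slope of log X over the earliest three distinct times approximates mu
  ts <- sort(unique(obs$t))[1:min(3L, length(unique(obs$t)))]
  sel <- obs$t %in% ts & obs$y > 0
  mu0 <- if (sum(sel) >= 2) {
    cf <- stats::coef(stats::lm(log(obs$y[sel]) ~ obs$t[sel]))[2]
    max(min(as.numeric(cf), 4.9), 0.01)
  } else 0.3
  x00 <- max(min(obs$y[obs$t == min(obs$t)]), 1e-6)
  c(mu_max = mu0, X_max = xmax0, X0 = x00)
}

safe_gof <- function(observed, predicted, n_params) {
  tryCatch(goodness_of_fit(observed, predicted, n_params),
           error = function(e) list(r2 = NA_real_, f_value = NA_real_,
                                    sse = sum((observed - predicted)^2),
                                    sst = sum((observed - mean(observed))^2),
                                    n = length(observed)))
}

# ---- conditionally linear fits ------------------------------------------

#' Fit the Luedeking-Piret product parameters given the growth curve
#'
#' With the biomass curve known, the product equation is linear in
#' (alpha, beta): P - P0 = alpha (X(t) - X0) + beta int_0^t X. Estimates
#' are the non-negative least-squares solution.
#'
#' @param data A [timecourse()] with a product column `P`.
#' @param growth A [kinetic_params()] (or fitted growth result converted to
#'   one) supplying mu_max, X_max, X0 and P0.
#' @param cfg A [fit_config()]; `cfg$fix$P0` overrides the initial titer.
#' @return A `fit_result` whose `params` holds `alpha`, `beta`.
#' @export
fit_product <- function(data, growth, cfg = fit_config()) {
  data <- coerce_timecourse(data)
  if (is.null(data$P)) stop("missing-response: no product column 'P'",
                            call. = FALSE)
  obs <- response_series(data, "P")
  P0 <- if (!is.null(cfg$fix$P0)) cfg$fix$P0 else growth$P0
  cf <- conditional_linear_fit(obs, growth, P0)
  pred <- P0 + cf$A %*% cf$coef
  gof <- safe_gof(obs$y, as.numeric(pred), n_params = 2L)
  new_fit_result(list(alpha = cf$coef[1], beta = cf$coef[2], P0 = P0),
                 r2 = list(P = gof$r2), f_value = list(P = gof$f_value),
                 sse = list(P = gof$sse), sst = list(P = gof$sst),
                 n_obs = list(P = obs$n), converged = TRUE,
                 n_starts_used = 0L, seed = cfg$seed,
                 strategy = cfg$strategy)
}

#' Fit the sugar consumption parameters given the growth curve
#'
#' The consumed sugar S0 - S is linear in (1/Y_XS, M_s):
#' S0 - S = (X(t) - X0)/Y_XS + M_s int_0^t X, both coefficients
#' constrained non-negative.
#'
#' @inheritParams fit_product
#' @return A `fit_result` whose `params` holds `Y_XS`, `M_s`.
#' @export
fit_sugar <- function(data, growth, cfg = fit_config()) {
  data <- coerce_timecourse(data)
  if (is.null(data$S)) stop("missing-response: no sugar column 'S'",
                            call. = FALSE)
  obs <- response_series(data, "S")
  S0 <- if (!is.null(cfg$fix$S0)) cfg$fix$S0 else growth$S0
  obs_cons <- list(t = obs$t, y = S0 - obs$y, n = obs$n)
  cf <- conditional_linear_fit(obs_cons, growth, 0)
  y_xs <- if (cf$coef[1] > 0) 1 / cf$coef[1] else Inf
  pred_S <- S0 - as.numeric(cf$A %*% cf$coef)
  gof <- safe_gof(obs$y, pred_S, n_params = 2L)
  new_fit_result(list(Y_XS = y_xs, M_s = cf$coef[2], S0 = S0),
                 r2 = list(S = gof$r2), f_value = list(S = gof$f_value),
                 sse = list(S = gof$sse), sst = list(S = gof$sst),
                 n_obs = list(S = obs$n), converged = TRUE,
                 n_starts_used = 0L, seed = cfg$seed,
                 strategy = cfg$strategy)
}

conditional_linear_fit <- function(obs, growth, offset) {
  mu <- growth$mu_max; Xmax <- growth$X_max; X0 <- growth$X0
  dx <- logistic_xt(obs$t, mu, Xmax, X0) - X0
  ix <- integral_xt(obs$t, mu, Xmax, X0)
  A <- cbind(dx, ix)
  # dx == 0 everywhere means the growth-associated coefficient multiplies
  # nothing: alpha / 1/Y_XS are unidentifiable from such data
  if (all(abs(dx) < 1e-12)) {
    stop("degenerate-data: biomass curve is constant, ",
         "product/sugar parameters unidentifiable", call. = FALSE)
  }
  coef <- nnls2(A, obs$y - offset)
  list(coef = coef, A = A)
}

# ---- full fit ------------------------------------------------------------

#' Fit the full six-parameter kinetic model
#'
#' Sequential strategy (default): fit the logistic growth parameters to
#' the biomass series, then solve the conditionally linear product and
#' sugar equations. Joint strategy: minimise a single weighted sum of
#' squares over all responses, each response weighted by 1/SST so the
#' criterion is scale-free; initialised at the sequential solution plus
#' seeded random starts.
#'
#' Initial conditions S0 and P0 default to the mean observation at the
#' earliest sampled time (overridable through `cfg$fix`).
#'
#' @param data A [timecourse()]. Responses absent from the data are
#'   skipped; at least `X` is required.
#' @param cfg A [fit_config()].
#' @return A `fit_result`; `params` is a full [kinetic_params()] and `r2`,
#'   `f_value`, `sse`, `sst`, `n_obs` are per-response maps plus a
#'   `pooled` R-squared.
#' @examples
#' tc <- simulate_timecourse(wt_params(), 0:12)
#' fit_full(tc)
#' @export
fit_full <- function(data, cfg = fit_config()) {
  data <- coerce_timecourse(data)
  if (is.null(data$X)) stop("missing-response: biomass 'X' is required",
                            call. = FALSE)
  have_P <- !is.null(data$P) && any(is.finite(data$P))
  have_S <- !is.null(data$S) && any(is.finite(data$S))

  seq_fit <- fit_sequential(data, cfg, have_P, have_S)
  if (cfg$strategy == "sequential") return(seq_fit)
  fit_joint(data, cfg, have_P, have_S, seq_fit)
}

initial_level <- function(data, col, fix) {
  if (!is.null(fix)) return(fix)
  keep <- is.finite(data[[col]])
  t0 <- min(data$time[keep])
  mean(data[[col]][keep & data$time == t0])
}

fit_sequential <- function(data, cfg, have_P, have_S) {
  fb <- fit_biomass(data, cfg)
  S0 <- if (have_S) initial_level(data, "S", cfg$fix$S0) else 0
  P0 <- if (have_P) initial_level(data, "P", cfg$fix$P0) else 0
  growth <- list(mu_max = fb$params$mu_max, X_max = fb$params$X_max,
                 X0 = fb$params$X0, S0 = S0, P0 = P0)

  params <- list(mu_max = growth$mu_max, X_max = growth$X_max,
                 alpha = 0, beta = 0, Y_XS = 1, M_s = 0,
                 X0 = growth$X0, S0 = S0, P0 = P0)
  r2 <- fb$r2; fv <- fb$f_value; sse <- fb$sse; sst <- fb$sst
  n_obs <- fb$n_obs
  if (have_P) {
    fp <- fit_product(data, growth, cfg)
    params$alpha <- fp$params$alpha; params$beta <- fp$params$beta
    r2$P <- fp$r2$P; fv$P <- fp$f_value$P
    sse$P <- fp$sse$P; sst$P <- fp$sst$P; n_obs$P <- fp$n_obs$P
  }
  if (have_S) {
    fs <- fit_sugar(data, growth, cfg)
    params$Y_XS <- fs$params$Y_XS; params$M_s <- fs$params$M_s
    r2$S <- fs$r2$S; fv$S <- fs$f_value$S
    sse$S <- fs$sse$S; sst$S <- fs$sst$S; n_obs$S <- fs$n_obs$S
  }
  r2$pooled <- pooled_r2(sse, sst)
  kp <- try_kinetic_params(params)
  new_fit_result(kp, r2 = r2, f_value = fv, sse = sse, sst = sst,
                 n_obs = n_obs, converged = TRUE,
                 n_starts_used = cfg$n_starts, seed = cfg$seed,
                 strategy = "sequential")
}

fit_joint <- function(data, cfg, have_P, have_S, seq_fit) {
  obs_X <- response_series(data, "X")
  obs_P <- if (have_P) response_series(data, "P")
  obs_S <- if (have_S) response_series(data, "S")
  S0 <- if (have_S) initial_level(data, "S", cfg$fix$S0) else 0
  P0 <- if (have_P) initial_level(data, "P", cfg$fix$P0) else 0

  w_X <- 1 / max(sum((obs_X$y - mean(obs_X$y))^2), .Machine$double.eps)
  w_P <- if (have_P) 1 / max(sum((obs_P$y - mean(obs_P$y))^2),
                             .Machine$double.eps)
  w_S <- if (have_S) 1 / max(sum((obs_S$y - mean(obs_S$y))^2),
                             .Machine$double.eps)

  b <- default_bounds(data, cfg)
  par_names <- c("mu_max", "X_max", "X0",
                 if (have_P) c("alpha", "beta"),
                 if (have_S) c("Y_XS", "M_s"))
  bm <- do.call(rbind, b[par_names])
  objective <- function(par) {
    names(par) <- par_names
    mu <- par[["mu_max"]]; Xmax <- par[["X_max"]]; X0 <- par[["X0"]]
    if (X0 > Xmax) return(1e10 * (1 + (X0 - Xmax)^2))
    sse <- w_X * sum((obs_X$y - logistic_xt(obs_X$t, mu, Xmax, X0))^2)
    if (have_P) {
      pr <- P0 + par[["alpha"]] * (logistic_xt(obs_P$t, mu, Xmax, X0) - X0) +
        par[["beta"]] * integral_xt(obs_P$t, mu, Xmax, X0)
      sse <- sse + w_P * sum((obs_P$y - pr)^2)
    }
    if (have_S) {
      sr <- S0 - (logistic_xt(obs_S$t, mu, Xmax, X0) - X0) / par[["Y_XS"]] -
        par[["M_s"]] * integral_xt(obs_S$t, mu, Xmax, X0)
      sse <- sse + w_S * sum((obs_S$y - sr)^2)
    }
    if (!is.finite(sse)) return(1e12)
    sse
  }
  sp <- seq_fit$params
  heur <- unlist(sp[par_names])
  heur[!is.finite(heur)] <- 1
  starts <- start_stream(bm, cfg$n_starts, cfg$seed, heuristic = heur)
  best <- run_multistart(objective, starts, bm[, 1], bm[, 2], cfg$tolerance)
  par <- best$par; names(par) <- par_names

  params <- list(mu_max = par[["mu_max"]], X_max = par[["X_max"]],
                 alpha = if (have_P) par[["alpha"]] else 0,
                 beta = if (have_P) par[["beta"]] else 0,
                 Y_XS = if (have_S) par[["Y_XS"]] else 1,
                 M_s = if (have_S) par[["M_s"]] else 0,
                 X0 = par[["X0"]], S0 = S0, P0 = P0)
  kp <- try_kinetic_params(params)

  pred_X <- logistic_xt(obs_X$t, params$mu_max, params$X_max, params$X0)
  g_X <- safe_gof(obs_X$y, pred_X, 3L)
  r2 <- list(X = g_X$r2); fv <- list(X = g_X$f_value)
  sse <- list(X = g_X$sse); sst <- list(X = g_X$sst)
  n_obs <- list(X = obs_X$n)
  if (have_P) {
    pred_P <- P0 + params$alpha *
      (logistic_xt(obs_P$t, params$mu_max, params$X_max, params$X0) -
         params$X0) +
      params$beta * integral_xt(obs_P$t, params$mu_max, params$X_max,
                                params$X0)
    g <- safe_gof(obs_P$y, pred_P, 2L)
    r2$P <- g$r2; fv$P <- g$f_value; sse$P <- g$sse; sst$P <- g$sst
    n_obs$P <- obs_P$n
  }
  if (have_S) {
    pred_S <- S0 - (logistic_xt(obs_S$t, params$mu_max, params$X_max,
                                params$X0) - params$X0) / params$Y_XS -
      params$M_s * integral_xt(obs_S$t, params$mu_max, params$X_max,
                               params$X0)
    g <- safe_gof(obs_S$y, pred_S, 2L)
    r2$S <- g$r2; fv$S <- g$f_value; sse$S <- g$sse; sst$S <- g$sst
    n_obs$S <- obs_S$n
  }
  r2$pooled <- pooled_r2(sse, sst)
  new_fit_result(kp, r2 = r2, f_value = fv, sse = sse, sst = sst,
                 n_obs = n_obs, converged = is.finite(best$value),
                 n_starts_used = cfg$n_starts, seed = cfg$seed,
                 strategy = "joint")
}

pooled_r2 <- function(sse, sst) {
  tot_sse <- sum(unlist(sse)); tot_sst <- sum(unlist(sst))
  if (tot_sst == 0) NA_real_ else 1 - tot_sse / tot_sst
}

# a fitted parameter list may contain Inf Y_XS etc; fall back to plain list
try_kinetic_params <- function(params) {
  kp <- tryCatch(do.call(kinetic_params, params), error = function(e) NULL)
  if (is.null(kp)) {
    class(params) <- "kinetic_params_partial"
    params
  } else kp
}
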