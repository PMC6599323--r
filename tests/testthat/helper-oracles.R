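# Independent numerical oracles used across the tests. Deliberately coded
# without touching the package internals so that agreement is evidence.

# fixed-step RK4 over the coupled (X, S, P) system, written from the ODEs
oracle_rk4 <- function(p, times, n_steps = 4000L) {
  rhs <- function(y) {
    dX <- p$mu_max * y[1] * (1 - y[1] / p$X_max)
    c(dX, -(dX / p$Y_XS + p$M_s * y[1]), p$alpha * dX + p$beta * y[1])
  }
  t_end <- max(times)
  h <- t_end / n_steps
  grid_t <- seq(0, t_end, by = h)
  y <- matrix(NA_real_, nrow = length(grid_t), ncol = 3L)
  y[1L, ] <- c(p$X0, p$S0, p$P0)
  for (i in seq_len(length(grid_t) - 1L)) {
    yi <- y[i, ]
    k1 <- rhs(yi); k2 <- rhs(yi + h / 2 * k1)
    k3 <- rhs(yi + h / 2 * k2); k4 <- rhs(yi + h * k3)
    y[i + 1L, ] <- yi + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  idx <- vapply(times, function(tt) which.min(abs(grid_t - tt)), integer(1))
  list(X = y[idx, 1L], S = y[idx, 2L], P = y[idx, 3L])
}

# random parameter set within +/- frac of the wild-type reference values
random_params_near_wt <- function(frac = 0.5) {
  ref <- wt_params()
  jig <- function(v, lo_ok = 1e-6) {
    max(v * stats::runif(1, 1 - frac, 1 + frac), lo_ok)
  }
  kinetic_params(mu_max = jig(ref$mu_max),
                 X_max = jig(ref$X_max),
                 alpha = ref$alpha * stats::runif(1, 1 - frac, 1 + frac),
                 beta = 0.01 * stats::runif(1, 0, 1),
                 Y_XS = jig(ref$Y_XS),
                 M_s = ref$M_s * stats::runif(1, 1 - frac, 1 + frac),
                 X0 = jig(ref$X0), S0 = jig(ref$S0), P0 = 0)
}

rel_err <- function(est, truth) abs(est - truth) / abs(truth)
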