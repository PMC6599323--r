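#' Logistic biomass trajectory
#'
#' Closed-form solution of the logistic growth law
#' dX/dt = mu_max * X * (1 - X/X_max):
#' X(t) = X_max * X0 * exp(mu_max t) / (X_max - X0 + X0 * exp(mu_max t)).
#'
#' @param t Time(s) in days, >= 0. Vectorised.
#' @param p A [kinetic_params()] object.
#' @return Biomass dry weight (g DW/L), same length as `t`.
#' @examples
#' logistic_biomass(0:12, wt_params())
#' @export
logistic_biomass <- function(t, p) {
  validate_params(p)
  check_times(t)
  # exp(mu t) overflows for large t; rewrite with exp(-mu t) for stability
  e <- exp(-p$mu_max * t)
  p$X_max * p$X0 / (p$X0 + (p$X_max - p$X0) * e)
}

#' Time integral of the logistic biomass curve
#'
#' Computes \eqn{\int_0^t X(\tau) d\tau}, the cumulative biomass exposure
#' that drives the non-growth-associated product term (beta * X) and the
#' maintenance term (M_s * X). Closed form:
#' (X_max/mu_max) * log((X_max - X0 + X0 exp(mu_max t)) / X_max);
#' reduces to X0 * t when mu_max = 0.
#'
#' @inheritParams logistic_biomass
#' @return Integral in g DW day / L, same length as `t`.
#' @export
biomass_integral <- function(t, p) {
  validate_params(p)
  check_times(t)
  if (p$mu_max == 0) return(p$X0 * t)
  # log((Xmax - X0 + X0 e^{mu t})/Xmax) = mu t + log((X0 + (Xmax-X0)e^{-mu t})/Xmax)
  e <- exp(-p$mu_max * t)
  (p$X_max / p$mu_max) *
    (p$mu_max * t + log((p$X0 + (p$X_max - p$X0) * e) / p$X_max))
}

#' Product titer under Luedeking-Piret kinetics
#'
#' Integrates dP/dt = alpha dX/dt + beta X along the logistic biomass
#' curve: P(t) = P0 + alpha (X(t) - X0) + beta * int_0^t X.
#'
#' @inheritParams logistic_biomass
#' @return Product (total GA) titer in g/L.
#' @export
product_titer <- function(t, p) {
  validate_params(p)
  p$P0 + p$alpha * (logistic_biomass(t, p) - p$X0) +
    p$beta * biomass_integral(t, p)
}

#' Residual sugar under Luedeking-Piret-like consumption
#'
#' Integrates -dS/dt = (1/Y_XS) dX/dt + M_s X:
#' S(t) = S0 - (X(t) - X0)/Y_XS - M_s * int_0^t X. The closed form can go
#' negative when the batch runs past sugar exhaustion; a warning is issued
#' but values are never clamped.
#'
#' @inheritParams logistic_biomass
#' @return Residual sugar concentration in g/L.
#' @export
sugar_residual <- function(t, p) {
  validate_params(p)
  s <- p$S0 - (logistic_biomass(t, p) - p$X0) / p$Y_XS -
    p$M_s * biomass_integral(t, p)
  if (any(s < 0)) {
    warning("predicted residual sugar is negative at some times ",
            "(model run past sugar exhaustion); values not clamped",
            call. = FALSE)
  }
  s
}

#' Peak volumetric growth rate of the logistic law
#'
#' For the logistic model dX/dt is maximal at X = X_max/2, where it equals
#' mu_max * X_max / 4 (the V_max of the fitted model). If the culture
#' starts above X_max/2 the maximum over t >= 0 is attained at t = 0.
#'
#' @param p A [kinetic_params()] object.
#' @return Peak dX/dt in g DW/L/day.
#' @examples
#' peak_growth_rate(wt_params())  # 0.45 * 9.41 / 4
#' @export
peak_growth_rate <- function(p) {
  validate_params(p)
  if (p$X0 < p$X_max / 2) {
    p$mu_max * p$X_max / 4
  } else {
    p$mu_max * p$X0 * (1 - p$X0 / p$X_max)
  }
}

check_times <- function(t) {
  if (!is.numeric(t) || any(!is.finite(t)) || any(t < 0)) {
    stop("domain error: times must be finite, non-negative numbers",
         call. = FALSE)
  }
  invisible(t)
}
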