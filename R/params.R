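#' Kinetic parameter set for the batch fermentation model
#'
#' Bundles the six model constants of the unstructured kinetic model --
#' logistic biomass growth, Luedeking-Piret product formation and
#' Luedeking-Piret-like sugar consumption -- together with the initial
#' conditions of the batch.
#'
#' @param mu_max Maximum specific growth rate (day^-1). Must be >= 0.
#' @param X_max Carrying capacity: maximum biomass dry weight (g DW/L). > 0.
#' @param alpha Growth-associated product yield (g GA per g DW). >= 0.
#' @param beta Non-growth-associated production rate (g GA per g DW per
#'   day). >= 0.
#' @param Y_XS Biomass-on-sugar yield coefficient (g DW per g sugar). > 0.
#' @param M_s Maintenance coefficient (g sugar per g DW per day). >= 0.
#' @param X0 Initial biomass (g DW/L). Must satisfy 0 < X0 <= X_max.
#' @param S0 Initial sugar concentration (g/L). >= 0.
#' @param P0 Initial product titer (g/L). >= 0.
#'
#' @return An object of class `kinetic_params` (a named list).
#' @examples
#' p <- kinetic_params(mu_max = 0.45, X_max = 9.41, alpha = 0.015, beta = 0,
#'                     Y_XS = 0.63, M_s = 0.12, X0 = 0.5, S0 = 35, P0 = 0)
#' p
#' @export
kinetic_params <- function(mu_max, X_max, alpha = 0, beta = 0,
                           Y_XS = 1, M_s = 0,
                           X0 = 0.5, S0 = 35, P0 = 0) {
  p <- list(mu_max = as.numeric(mu_max), X_max = as.numeric(X_max),
            alpha = as.numeric(alpha), beta = as.numeric(beta),
            Y_XS = as.numeric(Y_XS), M_s = as.numeric(M_s),
            X0 = as.numeric(X0), S0 = as.numeric(S0), P0 = as.numeric(P0))
  class(p) <- "kinetic_params"
  validate_params(p)
  p
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("Kinetic parameters (logistic / Luedeking-Piret batch model)\n")
  cat(sprintf("  mu_max = %.4g day^-1   X_max = %.4g g/L\n", x$mu_max, x$X_max))
  cat(sprintf("  alpha  = %.4g g/g      beta  = %.4g g/g/day\n",
              x$alpha, x$beta))
  cat(sprintf("  Y_XS   = %.4g g/g      M_s   = %.4g g/g/day\n",
              x$Y_XS, x$M_s))
  cat(sprintf("  X0 = %.4g  S0 = %.4g  P0 = %.4g (g/L)\n", x$X0, x$S0, x$P0))
  invisible(x)
}

validate_params <- function(p) {
  stopifnot(inherits(p, "kinetic_params"))
  num1 <- function(v) is.numeric(v) && length(v) == 1L && is.finite(v)
  for (f in names(p)) {
    if (!num1(p[[f]])) {
      stop("invalid-parameter: '", f, "' must be a finite numeric scalar",
           call. = FALSE)
    }
  }
  if (p$mu_max < 0) stop("invalid-parameter: mu_max must be >= 0", call. = FALSE)
  if (p$X_max <= 0) stop("invalid-parameter: X_max must be > 0", call. = FALSE)
  if (p$X0 <= 0 || p$X0 > p$X_max) {
    stop("invalid-parameter: X0 must satisfy 0 < X0 <= X_max", call. = FALSE)
  }
  if (p$Y_XS <= 0) stop("invalid-parameter: Y_XS must be > 0", call. = FALSE)
  for (f in c("alpha", "beta", "M_s", "S0", "P0")) {
    if (p[[f]] < 0) {
      stop("invalid-parameter: ", f, " must be >= 0", call. = FALSE)
    }
  }
  invisible(p)
}

#' Published reference parameter sets for the two strains
#'
#' Parameter values reported for the wild-type (`wt_params`) and the
#' FPS-overexpressing transgenic (`fps_params`) strain of *Ganoderma
#' lucidum* in 12-day submerged batch culture. Initial conditions are not
#' part of the published estimates; the defaults (X0 = 0.5 g/L, S0 = 35
#' g/L, P0 = 0) are the package's stated convention for synthetic work.
#'
#' Note: the transgenic beta = 1.151 g/g/day is reproduced exactly as
#' published even though it is dimensionally inconsistent with the reported
#' final titer of 0.209 g/L over 12 days (beta * X * t would be orders of
#' magnitude larger); see the methods vignette.
#'
#' @param X0,S0,P0 Initial conditions (g/L).
#' @return A `kinetic_params` object.
#' @examples
#' wt_params()
#' fps_params()
#' @export
wt_params <- function(X0 = 0.5, S0 = 35, P0 = 0) {
  kinetic_params(mu_max = 0.45, X_max = 9.41, alpha = 0.015, beta = 0,
                 Y_XS = 0.63, M_s = 0.12, X0 = X0, S0 = S0, P0 = P0)
}

#' @rdname wt_params
#' @export
fps_params <- function(X0 = 0.5, S0 = 35, P0 = 0) {
  kinetic_params(mu_max = 0.49, X_max = 9.72, alpha = 0.026, beta = 1.151,
                 Y_XS = 0.70, M_s = 0.13, X0 = X0, S0 = S0, P0 = P0)
}
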