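#' Metabolite content summary record
#'
#' Mean +/- SD summary of a metabolite content measurement for one strain,
#' as reported in replicate shake-flask assays (content per 100 mg dry
#' weight; the unit string is carried, not interpreted).
#'
#' @param strain Strain label.
#' @param analyte Analyte label, e.g. "total_GA", "GA-T".
#' @param mean Mean content, >= 0.
#' @param sd Standard deviation, >= 0.
#' @param n Replicate count (>= 2 for significance testing).
#' @param unit Unit string, e.g. "mg/100mg DW".
#' @return A `content_record` list.
#' @export
content_record <- function(strain, analyte, mean, sd, n = 3L,
                           unit = "mg/100mg DW") {
  stopifnot(mean >= 0, sd >= 0, n >= 1)
  structure(list(strain = as.character(strain),
                 analyte = as.character(analyte),
                 mean = as.numeric(mean), sd = as.numeric(sd),
                 n = as.integer(n), unit = as.character(unit)),
            class = "content_record")
}

#' Published ganoderic acid content reference table
#'
#' The reported mean +/- SD contents (n = 3) of total GAs (mg/100 mg DW)
#' and of the individual acids GA-Mk, GA-T, GA-S and GA-Me (ug/100 mg DW)
#' in the wild-type strain and the FPS-overexpressing transformant FPS1.
#' These printed summaries are the inputs to the fold-change and t-test
#' reproductions.
#'
#' @return A data frame with columns strain, analyte, mean, sd, n, unit.
#' @examples
#' ga_content_reference()
#' @export
ga_content_reference <- function() {
  data.frame(
    strain = rep(c("WT", "FPS1"), each = 5L),
    analyte = rep(c("total_GA", "GA-Mk", "GA-T", "GA-S", "GA-Me"), 2L),
    mean = c(1.21, 2, 18, 8, 10,
             2.76, 4, 41, 21, 28),
    sd = c(0.09, 0, 1, 1, 1,
           0.38, 1, 2, 5, 1),
    n = 3L,
    unit = rep(c("mg/100mg DW", rep("ug/100mg DW", 4L)), 2L),
    stringsAsFactors = FALSE
  )
}

as_content_record <- function(x) {
  if (inherits(x, "content_record")) return(x)
  content_record(x$strain, x$analyte, x$mean, x$sd, x$n,
                 if (!is.null(x$unit)) x$unit else "mg/100mg DW")
}

#' Fold change of a content record relative to a control
#'
#' @param treated,control `content_record`s for the same analyte and unit.
#' @return Ratio treated/control (displayed to 2 decimals in reports; the
#'   raw value is returned).
#' @examples
#' ref <- ga_content_reference()
#' wt <- ref[ref$strain == "WT" & ref$analyte == "total_GA", ]
#' tr <- ref[ref$strain == "FPS1" & ref$analyte == "total_GA", ]
#' fold_change(as.list(tr), as.list(wt))  # 2.28
#' @export
fold_change <- function(treated, control) {
  treated <- as_content_record(as.list(treated))
  control <- as_content_record(as.list(control))
  if (treated$analyte != control$analyte || treated$unit != control$unit) {
    stop("fold_change: analyte/unit mismatch between records", call. = FALSE)
  }
  if (control$mean <= 0) {
    stop("undefined-ratio: control mean is zero", call. = FALSE)
  }
  treated$mean / control$mean
}

#' Volumetric productivity
#'
#' Final product titer divided by the batch duration; reproduces the
#' published productivity figures (e.g. 0.112 g/L over 12 days ~ 0.009
#' g/L/day).
#'
#' @param P_max Final (maximum) product titer, g/L.
#' @param duration Batch duration in days, > 0.
#' @return Productivity in g/L/day.
#' @export
productivity <- function(P_max, duration) {
  if (!is.numeric(duration) || duration <= 0) {
    stop("domain error: duration must be > 0", call. = FALSE)
  }
  if (P_max < 0) stop("domain error: P_max must be >= 0", call. = FALSE)
  P_max / duration
}

#' Percent increase of a value over a baseline
#'
#' 100 * (new - old) / old. Reports round to the nearest integer
#' (round-half-even, R's default), but the raw value is returned.
#'
#' @param new,old Numeric values; `old` must be > 0.
#' @return Percent increase (may be negative for decreases).
#' @examples
#' percent_increase(1.18, 1.05)  # ~12.4
#' @export
percent_increase <- function(new, old) {
  if (!is.numeric(old) || old <= 0) {
    stop("domain error: baseline must be > 0", call. = FALSE)
  }
  100 * (new - old) / old
}

#' Two-sample t test from summary statistics
#'
#' Student's two-sample t test computed from group means, SDs and sizes,
#' as needed when only mean +/- SD summaries are published. Default is the
#' pooled-variance Student test in a two-tailed analysis; Welch's
#' approximation is available via `var_equal = FALSE`.
#'
#' @param a,b `content_record`s (or lists with mean, sd, n).
#' @param var_equal Pool the variances (classical Student test, default).
#' @return List with `t`, `df`, `p` (two-tailed).
#' @examples
#' two_sample_t(content_record("FPS1", "total_GA", 2.76, 0.38),
#'              content_record("WT", "total_GA", 1.21, 0.09))
#' @export
two_sample_t <- function(a, b, var_equal = TRUE) {
  a <- as_content_record(as.list(a)); b <- as_content_record(as.list(b))
  if (a$n < 2L || b$n < 2L) {
    stop("two_sample_t: need n >= 2 in both groups", call. = FALSE)
  }
  if (!is.finite(a$sd) || !is.finite(b$sd)) {
    stop("two_sample_t: SDs must be finite", call. = FALSE)
  }
  if (a$sd == 0 && b$sd == 0) {
    if (a$mean == b$mean) return(list(t = 0, df = a$n + b$n - 2L, p = 1))
    return(list(t = Inf * sign(a$mean - b$mean), df = a$n + b$n - 2L, p = 0))
  }
  if (var_equal) {
    df <- a$n + b$n - 2L
    sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / df
    se <- sqrt(sp2 * (1 / a$n + 1 / b$n))
  } else {
    va <- a$sd^2 / a$n; vb <- b$sd^2 / b$n
    se <- sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (a$n - 1) + vb^2 / (b$n - 1))
  }
  t <- (a$mean - b$mean) / se
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Derived-metric comparison of two fitted strains
#'
#' Assembles the metrics by which a transgenic strain is compared with its
#' wild-type control: peak growth rate (V_max = mu_max X_max / 4), final
#' titer P_max at the stated duration, volumetric productivity, percent
#' increases of the kinetic parameters, and fold changes plus two-tailed t
#' tests of any supplied content records.
#'
#' @param fit_wt,fit_tr Fitted results ([fit_full()]) or
#'   [kinetic_params()] for control and treated strains.
#' @param contents Optional data frame in the layout of
#'   [ga_content_reference()] with exactly two strains; the control strain
#'   is taken to be `fit_wt`'s label or the strain named "WT".
#' @param duration Batch duration (days) used for P_max and productivity;
#'   default 12.
#' @return A `strain_comparison` list with elements `metrics` (per-strain
#'   V_max, P_max, productivity), `percent_increases`, `fold_changes`,
#'   `t_tests`.
#' @examples
#' compare_strains(wt_params(), fps_params(), ga_content_reference())
#' @export
compare_strains <- function(fit_wt, fit_tr, contents = NULL,
                            duration = 12) {
  pw <- comparison_params(fit_wt)
  pt_ <- comparison_params(fit_tr)
  if (duration <= 0) stop("domain error: duration must be > 0",
                          call. = FALSE)

  metric_row <- function(p) {
    v_max <- peak_growth_rate(p)
    p_max <- product_titer(duration, p)
    c(mu_max = p$mu_max, X_max = p$X_max, V_max = v_max,
      alpha = p$alpha, beta = p$beta, Y_XS = p$Y_XS, M_s = p$M_s,
      P_max = p_max, productivity = productivity(p_max, duration))
  }
  m_wt <- metric_row(pw); m_tr <- metric_row(pt_)
  pct <- vapply(names(m_wt), function(k) {
    if (m_wt[[k]] > 0) percent_increase(m_tr[[k]], m_wt[[k]]) else NA_real_
  }, numeric(1))

  folds <- NULL; tt <- NULL
  if (!is.null(contents)) {
    strains <- unique(contents$strain)
    if (length(strains) != 2L) {
      stop("validation error: contents must cover exactly two strains",
           call. = FALSE)
    }
    ctrl <- if ("WT" %in% strains) "WT" else strains[1L]
    trt <- setdiff(strains, ctrl)
    analytes <- unique(contents$analyte)
    folds <- numeric(0); tt <- list()
    for (an in analytes) {
      rc <- contents[contents$strain == ctrl & contents$analyte == an, ]
      rt <- contents[contents$strain == trt & contents$analyte == an, ]
      if (nrow(rc) != 1L || nrow(rt) != 1L) {
        stop("validation error: analyte '", an,
             "' not present once per strain", call. = FALSE)
      }
      folds[[an]] <- fold_change(as.list(rt), as.list(rc))
      tt[[an]] <- two_sample_t(as.list(rt), as.list(rc))
    }
  }
  structure(list(metrics = rbind(control = m_wt, treated = m_tr),
                 percent_increases = pct, fold_changes = folds,
                 t_tests = tt, duration = duration),
            class = "strain_comparison")
}

comparison_params <- function(x) {
  if (inherits(x, "fit_result")) x <- x$params
  if (inherits(x, "kinetic_params")) return(x)
  if (is.list(x)) {
    # partial fits (e.g. infinite Y_XS) still allow growth-based metrics
    defaults <- list(alpha = 0, beta = 0, Y_XS = 1, M_s = 0,
                     X0 = 0.5, S0 = 35, P0 = 0)
    for (nm in names(defaults)) {
      if (is.null(x[[nm]]) || !is.finite(x[[nm]])) x[[nm]] <- defaults[[nm]]
    }
    return(do.call(kinetic_params, x[c("mu_max", "X_max", "alpha", "beta",
                                       "Y_XS", "M_s", "X0", "S0", "P0")]))
  }
  stop("compare_strains: cannot interpret strain fit/parameters",
       call. = FALSE)
}

#' @export
print.strain_comparison <- function(x, ...) {
  cat("Strain comparison over", x$duration, "days\n\n")
  print(round(x$metrics, 4))
  cat("\nPercent increases (treated vs control):\n")
  print(round(x$percent_increases))
  if (!is.null(x$fold_changes)) {
    cat("\nContent fold changes:\n")
    print(round(x$fold_changes, 2))
    sig <- vapply(x$t_tests, function(z) z$p, numeric(1))
    cat("\nTwo-tailed t-test p-values:\n")
    print(signif(sig, 3))
  }
  invisible(x)
}
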