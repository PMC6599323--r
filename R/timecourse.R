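#' Construct a fermentation time course
#'
#' A `timecourse` is a data frame with one row per observation and columns
#' `time` (days), `X` (biomass g DW/L), `S` (residual sugar g/L), `P`
#' (total GA g/L), plus optional `replicate` (integer label) and `strain`
#' (character label). Any of `X`, `S`, `P` may be absent or NA; fitting
#' uses whatever responses exist. Rows are sorted by time (then replicate).
#'
#' @param time Sampling times in days, non-negative.
#' @param X,S,P Optional response vectors, same length as `time`; values
#'   must be non-negative where present.
#' @param replicate Optional integer replicate labels.
#' @param strain Optional strain label (recycled).
#' @return A data frame of class `timecourse`.
#' @examples
#' timecourse(time = 0:3, X = c(0.5, 0.8, 1.3, 2.0), strain = "WT")
#' @export
timecourse <- function(time, X = NULL, S = NULL, P = NULL,
                       replicate = NULL, strain = NULL) {
  if (!is.numeric(time) || length(time) == 0L) {
    stop("timecourse: 'time' must be a non-empty numeric vector",
         call. = FALSE)
  }
  check_times(time)
  n <- length(time)
  df <- data.frame(time = as.numeric(time))
  for (nm in c("X", "S", "P")) {
    v <- switch(nm, X = X, S = S, P = P)
    if (!is.null(v)) {
      if (length(v) != n) {
        stop("timecourse: '", nm, "' must have the same length as 'time'",
             call. = FALSE)
      }
      if (any(v < 0, na.rm = TRUE)) {
        stop("timecourse: '", nm, "' contains negative values", call. = FALSE)
      }
      df[[nm]] <- as.numeric(v)
    }
  }
  if (!is.null(replicate)) {
    if (length(replicate) != n) {
      stop("timecourse: 'replicate' must match 'time' in length",
           call. = FALSE)
    }
    df$replicate <- as.integer(replicate)
  }
  if (!is.null(strain)) df$strain <- as.character(strain)
  key <- if (!is.null(df$replicate)) order(df$time, df$replicate)
         else order(df$time)
  df <- df[key, , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("timecourse", "data.frame")
  df
}

#' Coerce a data frame to a timecourse
#' @param x A data frame with at least a `time` column.
#' @return A `timecourse` object.
#' @export
as_timecourse <- function(x) {
  stopifnot(is.data.frame(x))
  if (!"time" %in% names(x)) {
    stop("as_timecourse: missing 'time' column", call. = FALSE)
  }
  timecourse(time = x$time, X = x[["X"]], S = x[["S"]], P = x[["P"]],
             replicate = x[["replicate"]], strain = x[["strain"]])
}

# internal: build without the non-negativity check (model predictions may
# legitimately cross zero in S; observed data may not)
new_timecourse <- function(time, X = NULL, S = NULL, P = NULL,
                           replicate = NULL, strain = NULL) {
  df <- data.frame(time = as.numeric(time))
  if (!is.null(X)) df$X <- as.numeric(X)
  if (!is.null(S)) df$S <- as.numeric(S)
  if (!is.null(P)) df$P <- as.numeric(P)
  if (!is.null(replicate)) df$replicate <- as.integer(replicate)
  if (!is.null(strain)) df$strain <- as.character(strain)
  key <- if (!is.null(df$replicate)) order(df$time, df$replicate)
         else order(df$time)
  df <- df[key, , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("timecourse", "data.frame")
  df
}

#' @export
print.timecourse <- function(x, ...) {
  resp <- intersect(c("X", "S", "P"), names(x))
  cat(sprintf("Fermentation time course: %d observations, t in [%g, %g] days",
              nrow(x), min(x$time), max(x$time)))
  if (!is.null(x$strain)) {
    cat(sprintf(", strain(s): %s", paste(unique(x$strain), collapse = ", ")))
  }
  cat(sprintf("\nResponses present: %s\n", paste(resp, collapse = ", ")))
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("...", nrow(x) - 10, "more rows\n")
  invisible(x)
}
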