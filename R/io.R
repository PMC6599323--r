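#' Read a fermentation time course from CSV
#'
#' Expects a header with columns `time_days`, and any of `biomass_g_L`,
#' `sugar_g_L`, `ga` plus optional `replicate` and `strain`. The GA column
#' unit is declared by the caller; values declared `"mg/L"` are converted
#' to g/L on ingestion (all titers are g/L internally). Rows are sorted by
#' time. Parse failures name the offending row.
#'
#' @param path Path to a delimited text file (RFC-4180 CSV, "." decimal).
#' @param ga_unit `"g/L"` (default) or `"mg/L"`.
#' @return A [timecourse()].
#' @export
read_timecourse <- function(path, ga_unit = c("g/L", "mg/L")) {
  ga_unit <- match.arg(ga_unit)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"time_days" %in% names(raw)) {
    stop("parse error: missing required column 'time_days' in ", path,
         call. = FALSE)
  }
  if (nrow(raw) == 0L) {
    stop("parse error: ", path, " contains a header but no data rows",
         call. = FALSE)
  }
  num_col <- function(col) {
    if (!col %in% names(raw)) return(NULL)
    v <- raw[[col]]
    suppressWarnings(out <- as.numeric(v))
    bad <- which(!is.na(v) & v != "" & is.na(out))
    if (length(bad)) {
      stop("parse error: non-numeric value '", v[bad[1L]], "' in column '",
           col, "', row ", bad[1L], call. = FALSE)
    }
    out
  }
  tt <- num_col("time_days")
  if (anyNA(tt)) {
    stop("parse error: missing time value at row ", which(is.na(tt))[1L],
         call. = FALSE)
  }
  rep_id <- if ("replicate" %in% names(raw)) as.integer(raw$replicate)
  key <- if (is.null(rep_id)) tt else paste(tt, rep_id)
  if (anyDuplicated(key)) {
    stop("parse error: duplicate (time, replicate) pair at row ",
         which(duplicated(key))[1L], call. = FALSE)
  }
  P <- num_col("ga")
  if (!is.null(P) && ga_unit == "mg/L") P <- P / 1000
  timecourse(time = tt, X = num_col("biomass_g_L"),
             S = num_col("sugar_g_L"), P = P,
             replicate = rep_id,
             strain = if ("strain" %in% names(raw)) raw$strain)
}

#' Write a time course to CSV
#'
#' Inverse of [read_timecourse()]: columns `time_days`, `biomass_g_L`,
#' `sugar_g_L`, `ga` (always written in g/L), optional `replicate` and
#' `strain`. Round-trips at full double precision.
#'
#' @param tc A [timecourse()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_timecourse <- function(tc, path) {
  stopifnot(inherits(tc, "timecourse"))
  out <- data.frame(time_days = format_full(tc$time))
  if (!is.null(tc$X)) out$biomass_g_L <- format_full(tc$X)
  if (!is.null(tc$S)) out$sugar_g_L <- format_full(tc$S)
  if (!is.null(tc$P)) out$ga <- format_full(tc$P)
  if (!is.null(tc$replicate)) out$replicate <- tc$replicate
  if (!is.null(tc$strain)) out$strain <- tc$strain
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

format_full <- function(x) formatC(x, digits = 17, format = "g")

#' Serialize a fit result to JSON
#'
#' @param fit A `fit_result`.
#' @param path Optional output path; if NULL the JSON string is returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
fit_report_json <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "fit_result"))
  payload <- list(
    parameters = fit$params[!vapply(fit$params, is.null, logical(1))],
    r2 = fit$r2, f_value = fit$f_value, sse = fit$sse, sst = fit$sst,
    n_obs = fit$n_obs, converged = fit$converged,
    n_starts_used = fit$n_starts_used, seed = fit$seed,
    strategy = fit$strategy)
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                         null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Read kinetic parameters from a JSON file
#'
#' The file holds a flat object with any of the [kinetic_params()] fields;
#' missing fields take the constructor defaults.
#'
#' @param path JSON file path.
#' @return A [kinetic_params()].
#' @export
read_params_json <- function(path) {
  raw <- jsonlite::fromJSON(path)
  allowed <- c("mu_max", "X_max", "alpha", "beta", "Y_XS", "M_s",
               "X0", "S0", "P0")
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown)) {
    stop("parse error: unknown parameter field(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  do.call(kinetic_params, raw[intersect(allowed, names(raw))])
}
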