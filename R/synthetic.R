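#' Measurement-noise specification for the synthetic generator
#'
#' @param kind `"none"`, `"additive"` (Gaussian, sd in g/L) or
#'   `"proportional"` (Gaussian, sd as a fraction of the noiseless value).
#' @param sd Noise scale, >= 0.
#' @param n_replicates Number of replicate flasks per time point (>= 1);
#'   default 3, the usual shake-flask triplicate.
#' @param seed Integer seed; identical spec + parameters give identical
#'   output.
#' @param negative_clip Clip negative noisy draws to 0 (concentrations
#'   cannot be negative); default TRUE.
#' @return A `noise_spec` list.
#' @export
noise_spec <- function(kind = c("none", "additive", "proportional"),
                       sd = 0, n_replicates = 3L, seed = 0L,
                       negative_clip = TRUE) {
  kind <- match.arg(kind)
  if (!is.numeric(sd) || length(sd) != 1L || sd < 0) {
    stop("noise_spec: 'sd' must be a single non-negative number",
         call. = FALSE)
  }
  if (n_replicates < 1L) {
    stop("noise_spec: 'n_replicates' must be >= 1", call. = FALSE)
  }
  structure(list(kind = kind, sd = sd,
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed),
                 negative_clip = isTRUE(negative_clip)),
            class = "noise_spec")
}

#' Generate a synthetic fermentation time course
#'
#' Emulates replicate shake-flask sampling of a batch culture obeying the
#' logistic / Luedeking-Piret model: the closed-form trajectory is
#' evaluated on the sampling grid and perturbed per replicate with the
#' requested noise. With `kind = "none"` the output equals
#' [simulate_timecourse()] exactly (one replicate per time point).
#'
#' @param p A [kinetic_params()] object.
#' @param times Sampling days; default every 2 days over a 12-day batch.
#' @param noise A [noise_spec()].
#' @param strain Optional strain label.
#' @return A [timecourse()] with a `replicate` column when
#'   `n_replicates > 1` or noise is active.
#' @examples
#' generate_timecourse(wt_params(), noise = noise_spec("proportional", 0.05))
#' @export
generate_timecourse <- function(p, times = seq(0, 12, by = 2),
                                noise = noise_spec(), strain = NULL) {
  if (!inherits(noise, "noise_spec")) {
    stop("configuration error: 'noise' must be a noise_spec()",
         call. = FALSE)
  }
  validate_params(p)
  check_times(times)
  if (is.unsorted(times)) {
    stop("generate_timecourse: 'times' must be sorted", call. = FALSE)
  }
  clean <- simulate_timecourse(p, times, method = "closed_form")
  if (noise$kind == "none" && noise$n_replicates == 1L) {
    if (!is.null(strain)) clean$strain <- strain
    return(clean)
  }
  n_t <- length(times)
  n_rep <- noise$n_replicates
  rep_id <- rep(seq_len(n_rep), each = n_t)
  tt <- rep(times, times = n_rep)
  base <- list(X = rep(clean$X, n_rep), S = rep(clean$S, n_rep),
               P = rep(clean$P, n_rep))
  set.seed(noise$seed)
  noisy <- lapply(base, function(v) {
    out <- switch(noise$kind,
      none = v,
      additive = v + stats::rnorm(length(v), sd = noise$sd),
      proportional = v * (1 + stats::rnorm(length(v), sd = noise$sd)))
    if (noise$negative_clip) out <- pmax(out, 0)
    out
  })
  new_timecourse(time = tt, X = noisy$X, S = noisy$S, P = noisy$P,
                 replicate = rep_id, strain = strain)
}

#' Generate a wild-type / transgenic strain pair
#'
#' Two seeded [generate_timecourse()] calls with independent sub-seeds
#' derived from `noise$seed`, labelled `"WT"` and `"FPS"`. Defaults use
#' the published parameter columns for the two strains.
#'
#' @param wt,fps [kinetic_params()] for the two strains.
#' @param times Sampling days.
#' @param noise A [noise_spec()]; its seed is split deterministically
#'   between the strains.
#' @return A list with elements `wt` and `fps`, each a [timecourse()].
#' @examples
#' pair <- make_strain_pair()
#' sapply(pair, nrow)
#' @export
make_strain_pair <- function(wt = wt_params(), fps = fps_params(),
                             times = seq(0, 12, by = 2),
                             noise = noise_spec()) {
  if (!inherits(noise, "noise_spec")) {
    stop("configuration error: 'noise' must be a noise_spec()",
         call. = FALSE)
  }
  sub_seed <- function(k) (noise$seed * 2L + k) %% .Machine$integer.max
  n_wt <- noise; n_wt$seed <- sub_seed(0L)
  n_fps <- noise; n_fps$seed <- sub_seed(1L)
  list(wt = generate_timecourse(wt, times, n_wt, strain = "WT"),
       fps = generate_timecourse(fps, times, n_fps, strain = "FPS"))
}
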