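#' Configuration for the synthetic RSV generator
#'
#' Describes an hourly relative-search-volume series with known structure:
#' a unimodal diurnal cosine peaking at `acrophase`, a slow trend whose
#' period lies above the 32 h band edge, a high-frequency cosine with random
#' phase below the 4 h edge, and white observation noise. The defaults state
#' a 31-day month of night-peaking search interest, sized so the
#' diurnal:trend:noise mix resembles depression-query data: amplitude 15 RSV
#' units around a baseline of 55, a 20-unit trend at 72 h, a 3-unit 2 h
#' jitter, and white noise with SD 5. Baseline 55 keeps clipping at 0/100
#' inactive out to about three noise SDs.
#'
#' @param n_days Number of whole days (>= 2); series length is `n_days * 24`.
#' @param terms Character vector of query term labels.
#' @param baseline Mean level, RSV units.
#' @param diurnal_amplitude Amplitude `A` of the 24 h cosine, RSV units;
#'   peak-to-trough is `2A`.
#' @param acrophase Peak hour of day in \[0, 24).
#' @param trend_amplitude,trend_period Slow trend cosine; period must exceed
#'   32 h.
#' @param noise_hf_amplitude,noise_hf_period High-frequency cosine (random
#'   phase per term); period must be below 4 h. A fixed period rather than
#'   broadband noise gives band-rejection tests an exact target.
#' @param white_sd SD of i.i.d. Gaussian observation noise, RSV units.
#' @param renormalize Rescale each term so its maximum is 100, mimicking
#'   Google Trends normalization.
#' @param quantize Round to integers and clip to \[0, 100\] after any
#'   renormalization.
#' @param seed Integer RNG seed.
#' @param start First timestamp (parsed in UTC; hour 0 of a day).
#'
#' @return An object of class `synthetic_config`.
#' @seealso [generate_series()], [ground_truth_profile()]
#' @export
synthetic_config <- function(n_days = 31L,
                             terms = "depression",
                             baseline = 55,
                             diurnal_amplitude = 15,
                             acrophase = 2,
                             trend_amplitude = 20,
                             trend_period = 72,
                             noise_hf_amplitude = 3,
                             noise_hf_period = 2,
                             white_sd = 5,
                             renormalize = TRUE,
                             quantize = TRUE,
                             seed = 1L,
                             start = "2017-03-01") {
  fail <- function(msg) stop("invalid synthetic config: ", msg, call. = FALSE)
  if (!is.numeric(n_days) || n_days < 2) fail("n_days must be >= 2")
  if (!is.character(terms) || length(terms) < 1L) fail("terms must be labels")
  if (anyDuplicated(terms)) fail("duplicate term labels")
  if (diurnal_amplitude < 0) fail("diurnal_amplitude must be >= 0")
  if (acrophase < 0 || acrophase >= 24) fail("acrophase must be in [0, 24)")
  if (trend_amplitude > 0 && trend_period <= 32)
    fail("trend_period must exceed 32 h")
  if (noise_hf_amplitude > 0 && noise_hf_period >= 4)
    fail("noise_hf_period must be below 4 h")
  if (white_sd < 0) fail("white_sd must be >= 0")
  structure(
    list(n_days = as.integer(n_days), terms = terms, baseline = baseline,
         diurnal_amplitude = diurnal_amplitude, acrophase = acrophase,
         trend_amplitude = trend_amplitude, trend_period = trend_period,
         noise_hf_amplitude = noise_hf_amplitude,
         noise_hf_period = noise_hf_period, white_sd = white_sd,
         renormalize = isTRUE(renormalize), quantize = isTRUE(quantize),
         seed = as.integer(seed), start = start),
    class = "synthetic_config")
}

#' The six query terms of the motivating Finnish depression study
#' @return Character vector of length 6.
#' @export
depression_terms <- function() {
  c("masennus", "masennus oireet", "masennustesti", "masennus testi",
    "depression", "depression test")
}

#' Generate synthetic hourly RSV series with known ground truth
#'
#' Each term receives the same deterministic diurnal and trend components
#' and its own random high-frequency phase and white noise:
#' `value(t) = baseline + A cos(2 pi (t - acrophase) / 24)
#' + trend_amplitude cos(2 pi t / trend_period)
#' + noise_hf_amplitude cos(2 pi t / noise_hf_period + phi) + N(0, white_sd^2)`,
#' followed by optional per-term renormalization to max 100 and
#' integer quantization. The same config and seed give bit-identical output.
#'
#' @param config A [synthetic_config()].
#' @return A list with `series` (named list of [hourly_series()], one per
#'   term) and `truth` (class `ground_truth`): the 24-point diurnal
#'   component, the true peak and trough hours, per-term renormalization
#'   factors `rescale_factors` and per-term `true_pp_difference`
#'   (`2A` scaled by the renormalization factor).
#' @export
generate_series <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_days * 24L
  t <- seq_len(n) - 1
  ts <- seq(as.POSIXct(paste(config$start, "00:00:00"), tz = "UTC"),
            by = "hour", length.out = n)
  A <- config$diurnal_amplitude
  diurnal <- A * cos(2 * pi * (t - config$acrophase) / 24)
  trend <- if (config$trend_amplitude > 0)
    config$trend_amplitude * cos(2 * pi * t / config$trend_period) else 0

  set.seed(config$seed)
  series <- vector("list", length(config$terms))
  names(series) <- config$terms
  k <- stats::setNames(numeric(length(config$terms)), config$terms)
  for (i in seq_along(config$terms)) {
    phi <- stats::runif(1, 0, 2 * pi)
    hf <- if (config$noise_hf_amplitude > 0)
      config$noise_hf_amplitude *
        cos(2 * pi * t / config$noise_hf_period + phi) else 0
    eps <- if (config$white_sd > 0) stats::rnorm(n, 0, config$white_sd) else 0
    v <- config$baseline + diurnal + trend + hf + eps
    k[i] <- if (config$renormalize) 100 / max(v) else 1
    v <- v * k[i]
    if (config$quantize) v <- pmin(100, pmax(0, round(v)))
    # without quantization the signal is real-valued and may stray outside
    # [0,100]; only quantized output carries the raw-RSV contract
    series[[i]] <- hourly_series(config$terms[i], ts, v,
                                 is_reconstructed = !config$quantize)
  }

  hour_grid <- 0:23
  comp <- A * cos(2 * pi * (hour_grid - config$acrophase) / 24)
  truth <- structure(
    list(diurnal_component = stats::setNames(comp, hour_grid),
         true_peak_hour = hour_grid[which.max(comp)],
         true_trough_hour = hour_grid[which.min(comp)],
         rescale_factors = k,
         true_pp_difference = (max(comp) - min(comp)) * k),
    class = "ground_truth")
  list(series = series, truth = truth)
}

#' Analytic diurnal profile implied by a synthetic configuration
#'
#' The 24-point profile of the cosine component alone (no trend, noise,
#' renormalization or quantization), as a [mean_profile()]-compatible
#' `diurnal_profile`.
#'
#' @param config A [synthetic_config()].
#' @return A `diurnal_profile` object.
#' @export
ground_truth_profile <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  h <- 0:23
  m <- config$baseline + config$diurnal_amplitude *
    cos(2 * pi * (h - config$acrophase) / 24)
  new_diurnal_profile(m, term = "ground truth")
}
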