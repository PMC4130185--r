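#' Ground truth for a synthetic LTP series
#'
#' Latent parameters of a percent-of-baseline fEPSP series: baseline fixed at
#' 100% by construction, an early-phase potentiation level holding over the
#' first 40 min post-TBS, a late-phase level thereafter, an optional
#' post-tetanic transient of amplitude `ptp_amplitude` decaying with
#' `decay_constant` on top of the early plateau, and additive Gaussian noise.
#'
#' @param early_potentiation Early-phase level, percent of baseline (>= 0).
#' @param late_potentiation Late-phase level, percent of baseline (>= 0).
#' @param decay_constant Post-tetanic transient decay constant, min.
#' @param ptp_amplitude Post-tetanic transient amplitude, percent (default 0:
#'   plateau-only profile).
#' @param noise_sd Additive noise SD, percent.
#' @return A list of class `ltp_truth` (with `baseline_mean = 100`).
#' @export
ltp_truth <- function(early_potentiation = 200, late_potentiation = 150,
                      decay_constant = 5, ptp_amplitude = 0, noise_sd = 3) {
  if (early_potentiation < 0 || late_potentiation < 0)
    stop("potentiation levels must be >= 0")
  if (decay_constant <= 0) stop("`decay_constant` must be positive")
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  structure(list(baseline_mean = 100,
                 early_potentiation = early_potentiation,
                 late_potentiation = late_potentiation,
                 decay_constant = decay_constant,
                 ptp_amplitude = ptp_amplitude, noise_sd = noise_sd),
            class = "ltp_truth")
}

#' Recording cadence for a synthetic LTP experiment
#'
#' @param sample_interval_s Sweep spacing in seconds (default 20 s, the
#'   cadence implied by 0.05 Hz test stimulation).
#' @param baseline_duration_min Baseline length, minutes (>= 20 by default,
#'   matching stable-baseline practice).
#' @param post_duration_min Post-TBS recording length, minutes.
#' @return A list of class `ltp_protocol`.
#' @export
ltp_protocol <- function(sample_interval_s = 20, baseline_duration_min = 20,
                         post_duration_min = 80) {
  if (sample_interval_s <= 0) stop("`sample_interval_s` must be positive")
  if (baseline_duration_min <= 0 || post_duration_min <= 0)
    stop("durations must be positive")
  structure(list(sample_interval_s = sample_interval_s,
                 baseline_duration_min = baseline_duration_min,
                 post_duration_min = post_duration_min),
            class = "ltp_protocol")
}

#' Generate a ground-truthed percent-of-baseline LTP series
#'
#' Baseline sweeps fluctuate about 100%; post-TBS sweeps follow the truth
#' profile: `early_potentiation` over `[0, 40)` min, `late_potentiation` from
#' 40 min on, plus an optional post-tetanic transient
#' `ptp_amplitude * exp(-t / decay_constant)`. Window means over the standard
#' early (20-40 min) and late (40-80 min) windows therefore recover the two
#' potentiation parameters directly. Seeded Gaussian noise is added to every
#' sweep.
#'
#' @param truth An [ltp_truth()].
#' @param protocol An [ltp_protocol()]; its post-TBS duration must cover the
#'   requested analysis `windows`.
#' @param seed Integer seed.
#' @param windows Named list of analysis windows (min) the series must cover.
#' @return A list: `series` (a [fepsp_series()], already in percent units)
#'   and `truth`.
#' @export
gen_ltp_series <- function(truth = ltp_truth(), protocol = ltp_protocol(),
                           seed = 1L,
                           windows = list(early = c(20, 40),
                                          late = c(40, 80))) {
  stopifnot(inherits(truth, "ltp_truth"), inherits(protocol, "ltp_protocol"))
  wmax <- max(vapply(windows, function(w) w[2], numeric(1)))
  if (protocol$post_duration_min < wmax)
    stop(sprintf("post-TBS duration (%g min) shorter than analysis windows (to %g min)",
                 protocol$post_duration_min, wmax))
  dt <- protocol$sample_interval_s / 60
  t_base <- seq(-protocol$baseline_duration_min, -dt, by = dt)
  t_post <- seq(dt, protocol$post_duration_min, by = dt)
  profile <- ifelse(t_post < 40, truth$early_potentiation,
                    truth$late_potentiation) +
    truth$ptp_amplitude * exp(-t_post / truth$decay_constant)
  with_seed(seed, {
    amp <- c(rep(truth$baseline_mean, length(t_base)), profile)
    if (truth$noise_sd > 0)
      amp <- amp + rnorm(length(amp), 0, truth$noise_sd)
    series <- fepsp_series(c(t_base, t_post), amp,
                           baseline_window = c(-protocol$baseline_duration_min, 0),
                           condition = "synthetic")
    list(series = series, truth = truth)
  })
}
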