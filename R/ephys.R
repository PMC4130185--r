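#' Theta-burst stimulation schedule
#'
#' Builds the pulse-time bookkeeping for a theta-burst protocol: `trains`
#' bursts of `pulses_per_train` pulses at `intra_train_rate`, with
#' `inter_train_interval` between train onsets. Pulse k of train j (0-based)
#' falls at `j * inter_train_interval * 1000 + k / intra_train_rate * 1000`
#' ms. The default is the standard LTP-inducing protocol: eight trains of
#' eight pulses at 200 Hz, 2 s between trains (5 ms pulse spacing, 35 ms
#' onset-to-last-pulse train span).
#'
#' @param trains Number of trains.
#' @param pulses_per_train Pulses per train.
#' @param intra_train_rate Within-train pulse rate, Hz.
#' @param inter_train_interval Train onset-to-onset spacing, s.
#' @param baseline_stim_rate Baseline test-pulse rate, Hz (metadata; the
#'   0.05 Hz default implies one sweep every 20 s).
#' @return A list of class `stim_protocol`: `pulse_times` (ms), counts,
#'   rates, `train_span_ms` (onset to last pulse) and
#'   `inter_sweep_interval_s` (from the baseline rate).
#' @export
tbs_schedule <- function(trains = 8L, pulses_per_train = 8L,
                         intra_train_rate = 200, inter_train_interval = 2,
                         baseline_stim_rate = 0.05) {
  if (trains < 1 || pulses_per_train < 1)
    stop("`trains` and `pulses_per_train` must be positive")
  if (intra_train_rate <= 0 || inter_train_interval <= 0 ||
      baseline_stim_rate <= 0)
    stop("rates and intervals must be positive")
  span_s <- (pulses_per_train - 1) / intra_train_rate
  if (span_s >= inter_train_interval)
    stop("train duration exceeds the inter-train interval")
  j <- rep(seq_len(trains) - 1L, each = pulses_per_train)
  k <- rep(seq_len(pulses_per_train) - 1L, times = trains)
  structure(list(
    pulse_times = j * inter_train_interval * 1000 + k / intra_train_rate * 1000,
    trains = as.integer(trains),
    pulses_per_train = as.integer(pulses_per_train),
    intra_train_rate = intra_train_rate,
    inter_train_interval = inter_train_interval,
    baseline_stim_rate = baseline_stim_rate,
    train_span_ms = span_s * 1000,
    inter_sweep_interval_s = 1 / baseline_stim_rate
  ), class = "stim_protocol")
}

#' fEPSP amplitude series
#'
#' A sweep-by-sweep series of fEPSP response magnitudes relative to the
#' tetanus: timestamps in minutes with TBS at time 0, the baseline window
#' preceding it.
#'
#' @param time_min Increasing timestamps, minutes (TBS at 0).
#' @param amplitude Response magnitudes (arbitrary units or percent).
#' @param baseline_window `(start, end)` in minutes, end <= 0.
#' @param condition Free-text condition label.
#' @return A list of class `fepsp_series`.
#' @export
fepsp_series <- function(time_min, amplitude, baseline_window = c(-20, 0),
                         condition = "control") {
  if (length(time_min) != length(amplitude))
    stop("`time_min` and `amplitude` lengths differ")
  if (is.unsorted(time_min, strictly = TRUE))
    stop("`time_min` must be strictly increasing")
  if (baseline_window[2] > 0 || baseline_window[1] >= baseline_window[2])
    stop("`baseline_window` must precede the TBS at t = 0")
  structure(list(time_min = as.numeric(time_min),
                 amplitude = as.numeric(amplitude),
                 baseline_window = baseline_window, condition = condition),
            class = "fepsp_series")
}

#' Percent-of-baseline normalisation of an fEPSP series
#'
#' Divides every amplitude by the baseline-window mean and scales to percent,
#' then fills the standard summary windows where the series covers them:
#' early LTP (20-40 min), late LTP (40-80 min) and the first 10 min
#' post-TBS. Windows are half-open `[start, end)`.
#'
#' @param series A [fepsp_series()].
#' @param early,late,first10 Summary windows in minutes.
#' @return A list of class `ephys_features`: `time_min`, `percent_series`,
#'   `baseline_window`, `condition`, `early_mean`, `late_mean`,
#'   `first10_mean` (NA where the series does not cover the window).
#' @export
percent_of_baseline <- function(series, early = c(20, 40), late = c(40, 80),
                                first10 = c(0, 10)) {
  stopifnot(inherits(series, "fepsp_series"))
  base <- series$time_min >= series$baseline_window[1] &
    series$time_min < series$baseline_window[2]
  if (sum(base) < 2) stop("baseline window must contain at least 2 samples")
  bmean <- mean(series$amplitude[base])
  if (bmean <= 0) stop("baseline mean must be positive")
  ft <- structure(list(time_min = series$time_min,
                       percent_series = series$amplitude / bmean * 100,
                       baseline_window = series$baseline_window,
                       condition = series$condition),
                  class = "ephys_features")
  wm <- function(w) {
    ok <- ft$time_min >= w[1] & ft$time_min < w[2]
    if (any(ok)) mean(ft$percent_series[ok]) else NA_real_
  }
  ft$early_mean <- wm(early)
  ft$late_mean <- wm(late)
  ft$first10_mean <- wm(first10)
  ft
}

#' Mean percent-of-baseline over a time window
#'
#' Mean of the percent series over the half-open window `[start, end)`
#' minutes; a sample exactly at `end` is excluded.
#'
#' @param features An `ephys_features` from [percent_of_baseline()].
#' @param window `(start, end)` in minutes.
#' @return Mean percent of baseline.
#' @export
window_mean <- function(features, window) {
  stopifnot(inherits(features, "ephys_features"))
  if (length(window) != 2 || window[2] <= window[1])
    stop("`window` must be (start, end) with end > start")
  ok <- features$time_min >= window[1] & features$time_min < window[2]
  if (!any(ok)) stop("window contains no samples")
  mean(features$percent_series[ok])
}

#' Paired-pulse ratio
#'
#' Ratio of the second to the first response to two closely spaced stimuli
#' (50 ms apart in the standard protocol); a presynaptic release-probability
#' indicator.
#'
#' @param first,second Response amplitudes.
#' @return `second / first`.
#' @export
paired_pulse_ratio <- function(first, second) {
  if (any(first <= 0)) stop("`first` response must be positive")
  second / first
}
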