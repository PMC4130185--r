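#' Calcium-imaging acquisition protocol
#'
#' Frame rate and timing of a live-cell calcium imaging run. Frames are
#' timestamped `(frame_index - 1) / frame_rate` seconds from acquisition
#' start; the baseline window is the `baseline_duration` immediately before
#' `stimulus_onset`, excluding the onset frame itself.
#'
#' @param frame_rate Frames per second (Hz).
#' @param baseline_duration Baseline averaging window, s.
#' @param stimulus_onset Time of glutamate addition, s.
#' @param stimulus_offset Time of glutamate washout (or recording end), s.
#' @param total_duration Total recording length, s.
#' @return A list of class `calcium_protocol`.
#' @export
calcium_protocol <- function(frame_rate, baseline_duration, stimulus_onset,
                             stimulus_offset, total_duration) {
  if (frame_rate <= 0) stop("`frame_rate` must be positive")
  if (baseline_duration <= 0 || total_duration <= 0)
    stop("durations must be positive")
  if (baseline_duration > stimulus_onset)
    stop("`baseline_duration` cannot exceed `stimulus_onset`")
  if (stimulus_offset > total_duration)
    stop("`stimulus_offset` cannot exceed `total_duration`")
  structure(list(frame_rate = frame_rate,
                 baseline_duration = baseline_duration,
                 stimulus_onset = stimulus_onset,
                 stimulus_offset = stimulus_offset,
                 total_duration = total_duration,
                 n_frames = as.integer(round(total_duration * frame_rate))),
            class = "calcium_protocol")
}

#' Standard acquisition protocols
#'
#' `organotypic_protocol()`: CA1 imaging in organotypic slice cultures at two
#' frames per second; 20 s baseline (40 frames averaged for f0), glutamate at
#' 20 s remaining in the chamber for 105 s, 125 s total time-course.
#' `dissociated_protocol()`: mixed neuron-glial primary cultures at 1 Hz; 20 s
#' baseline, 90 s glutamate exposure then washout, 150 s total time-course.
#'
#' @return A [calcium_protocol()].
#' @export
organotypic_protocol <- function() {
  calcium_protocol(frame_rate = 2, baseline_duration = 20,
                   stimulus_onset = 20, stimulus_offset = 125,
                   total_duration = 125)
}

#' @rdname organotypic_protocol
#' @export
dissociated_protocol <- function() {
  calcium_protocol(frame_rate = 1, baseline_duration = 20,
                   stimulus_onset = 20, stimulus_offset = 110,
                   total_duration = 150)
}

#' Per-cell calcium fluorescence trace
#'
#' @param values Raw fluorescence per frame (arbitrary units); length must
#'   equal `round(total_duration * frame_rate)`.
#' @param protocol A [calcium_protocol()].
#' @param cell_id Identifier carried through to feature tables.
#' @return A list of class `calcium_trace` with a `time` vector in seconds.
#' @export
calcium_trace <- function(values, protocol, cell_id = 1L) {
  stopifnot(inherits(protocol, "calcium_protocol"))
  values <- as.numeric(values)
  if (length(values) != protocol$n_frames)
    stop(sprintf("trace has %d frames; protocol implies %d",
                 length(values), protocol$n_frames))
  structure(list(cell_id = cell_id, values = values, protocol = protocol,
                 time = (seq_along(values) - 1) / protocol$frame_rate),
            class = "calcium_trace")
}

#' f/f0 normalisation of a calcium trace
#'
#' f0 is the mean raw fluorescence over the baseline window (the
#' `baseline_duration` seconds strictly before stimulus onset); every frame is
#' divided by it, giving the dimensionless f/f0 series. The result is
#' invariant under multiplicative gain but not under additive offsets.
#'
#' @param trace A [calcium_trace()].
#' @return A list of class `trace_features` holding `f0`, `normalized`,
#'   `time`, `cell_id` and the protocol; quantification fields are filled by
#'   [trace_features()].
#' @export
f_over_f0 <- function(trace) {
  stopifnot(inherits(trace, "calcium_trace"))
  p <- trace$protocol
  base <- trace$time >= (p$stimulus_onset - p$baseline_duration) &
    trace$time < p$stimulus_onset
  if (!any(base)) stop("baseline window contains no frames")
  f0 <- mean(trace$values[base])
  if (!is.finite(f0) || f0 <= 0) stop("baseline mean f0 must be positive")
  structure(list(cell_id = trace$cell_id, f0 = f0,
                 normalized = trace$values / f0, time = trace$time,
                 protocol = p),
            class = "trace_features")
}

window_frames <- function(features, window) {
  if (length(window) != 2 || window[2] < window[1])
    stop("`window` must be (start, end) with end >= start")
  idx <- which(features$time >= window[1] & features$time <= window[2])
  if (!length(idx)) stop("window contains no frames")
  idx
}

#' Area under the baseline-subtracted f/f0 curve
#'
#' Trapezoidal integral of `f/f0 - 1` over a time window (seconds x
#' dimensionless units), the proxy used for total calcium entry. Subtracting
#' the baseline makes the AUC of a flat trace exactly zero and the statistic
#' additive over adjacent windows.
#'
#' @param features A `trace_features` from [f_over_f0()].
#' @param window `(start, end)` in seconds; default the full post-stimulus
#'   course, `c(stimulus_onset, total_duration)`.
#' @return Scalar AUC.
#' @export
response_auc <- function(features, window = NULL) {
  stopifnot(inherits(features, "trace_features"))
  p <- features$protocol
  if (is.null(window)) window <- c(p$stimulus_onset, p$total_duration)
  idx <- window_frames(features, window)
  tt <- features$time[idx]
  y <- features$normalized[idx] - 1
  if (length(idx) < 2) return(0)
  sum(diff(tt) * (y[-length(y)] + y[-1]) / 2)
}

#' Peak f/f0 in a window
#'
#' @param features A `trace_features` from [f_over_f0()].
#' @param window `(start, end)` in seconds; default the full post-stimulus
#'   course.
#' @return Maximum of the f/f0 series in the window.
#' @export
peak_response <- function(features, window = NULL) {
  stopifnot(inherits(features, "trace_features"))
  p <- features$protocol
  if (is.null(window)) window <- c(p$stimulus_onset, p$total_duration)
  max(features$normalized[window_frames(features, window)])
}

#' Full feature extraction for one trace
#'
#' Computes f0 and the f/f0 series, the post-stimulus peak, the AUC over
#' `auc_window` (default: full post-stimulus course), the plateau ratio
#' (mean f/f0 over the final third of the post-stimulus window divided by the
#' peak), and the cell class from [classify_trace()].
#'
#' @param trace A [calcium_trace()].
#' @param auc_window AUC window in seconds, `NULL` for full post-stimulus.
#' @param plateau_threshold,responder_threshold Passed to [classify_trace()].
#' @return A `trace_features` list with fields `f0`, `normalized`, `peak`,
#'   `auc`, `plateau_ratio`, `cell_class`.
#' @export
trace_features <- function(trace, auc_window = NULL, plateau_threshold = 0.6,
                           responder_threshold = 1.2) {
  ft <- f_over_f0(trace)
  p <- ft$protocol
  if (p$total_duration <= p$stimulus_onset)
    stop("trace ends at stimulus onset: no post-stimulus window")
  post <- c(p$stimulus_onset, p$total_duration)
  late <- c(p$stimulus_onset + 2 / 3 * diff(post), p$total_duration)
  ft$peak <- peak_response(ft, post)
  ft$auc <- response_auc(ft, auc_window)
  ft$plateau_ratio <- mean(ft$normalized[window_frames(ft, late)]) / ft$peak
  ft$cell_class <- classify_trace(ft, plateau_threshold, responder_threshold)
  ft
}

#' Classify a trace as neuron, non-neuron or non-responder
#'
#' Shape-based split of glutamate responses: neurons show a substantial and
#' prolonged (plateaued) calcium rise, non-neuronal cells a sharp transient
#' falling back toward baseline. Operationally: `non_responder` if the peak
#' f/f0 is below `responder_threshold`; otherwise `neuron` when the plateau
#' ratio (late-window mean / peak) is at least `plateau_threshold`, else
#' `non_neuron`. Both thresholds are explicit configuration, not fitted.
#'
#' @param features A `trace_features` with `peak` and `plateau_ratio` (as
#'   produced by [trace_features()]; if absent they are computed).
#' @param plateau_threshold Plateau-ratio cut, default 0.6.
#' @param responder_threshold Peak f/f0 cut, default 1.2.
#' @return One of `"neuron"`, `"non_neuron"`, `"non_responder"`.
#' @export
classify_trace <- function(features, plateau_threshold = 0.6,
                           responder_threshold = 1.2) {
  stopifnot(inherits(features, "trace_features"))
  p <- features$protocol
  if (p$total_duration <= p$stimulus_onset)
    stop("trace ends at stimulus onset: plateau window missing")
  if (is.null(features$peak)) {
    post <- c(p$stimulus_onset, p$total_duration)
    features$peak <- peak_response(features, post)
    late <- c(p$stimulus_onset + 2 / 3 * diff(post), p$total_duration)
    features$plateau_ratio <-
      mean(features$normalized[window_frames(features, late)]) / features$peak
  }
  if (features$peak < responder_threshold) return("non_responder")
  if (features$plateau_ratio >= plateau_threshold) "neuron" else "non_neuron"
}

#' Compare per-cell AUC between two groups
#'
#' Rank-based two-group comparison (Mann-Whitney U, see [mann_whitney()]) of
#' per-cell response AUCs, the test used for treatment effects on
#' glutamate-evoked calcium entry.
#'
#' @param control,treated Lists of `trace_features` (or numeric AUC vectors).
#' @return The [mann_whitney()] result, with group medians and sizes.
#' @export
group_auc_compare <- function(control, treated) {
  take_auc <- function(x, nm) {
    if (is.numeric(x)) return(x)
    if (!length(x)) stop(sprintf("`%s` group is empty", nm))
    vapply(x, function(f) {
      if (is.null(f$auc)) stop("features lack `auc`; use trace_features()")
      f$auc
    }, numeric(1))
  }
  a <- take_auc(control, "control")
  b <- take_auc(treated, "treated")
  if (!length(a) || !length(b)) stop("both groups must be non-empty")
  res <- mann_whitney(a, b)
  res$median_control <- median(a)
  res$median_treated <- median(b)
  res
}
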