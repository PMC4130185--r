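# Template f/f0 time-courses for the two response shapes.
#
# Neuron: smooth (sigmoidal) rise to the peak, brief hold, then settling onto
# a sustained plateau at plateau_fraction * peak, held through the end of the
# recording -- the "substantial and prolonged" response shape.
# Non-neuron: alpha-function transient (sharp rise, fall back toward the
# plateau level) -- with the default small plateau_fraction the trace returns
# to baseline. Plateau levels are floored at baseline (f/f0 = 1).
#
# Segment lengths (rise 4 s, hold 10 s, settle 20 s; alpha time constant 4 s)
# are fixed template constants chosen so the plateau is fully established
# well before the final third of the post-stimulus window at either standard
# frame rate.
smoothstep <- function(u) {
  u <- pmin(1, pmax(0, u))
  u * u * (3 - 2 * u)
}

neuron_template <- function(t, onset, peak, plateau_fraction,
                            t_rise = 4, t_hold = 10, t_settle = 20) {
  plateau <- max(1, plateau_fraction * peak)
  y <- rep(1, length(t))
  ph <- t >= onset
  u_rise <- (t - onset) / t_rise
  u_set <- (t - onset - t_rise - t_hold) / t_settle
  y[ph] <- (1 + (peak - 1) * smoothstep(u_rise[ph]))
  settle <- t >= onset + t_rise + t_hold
  y[settle] <- peak + (plateau - peak) * smoothstep(u_set[settle])
  y
}

non_neuron_template <- function(t, onset, peak, plateau_fraction, tau = 4) {
  plateau <- max(1, plateau_fraction * peak)
  y <- rep(1, length(t))
  ph <- t >= onset
  a <- ((t - onset) / tau) * exp(1 - (t - onset) / tau)
  y[ph] <- 1 + pmax((peak - 1) * a[ph], plateau - 1)
  y
}

#' Generate labelled synthetic calcium traces
#'
#' Draws per-cell response parameters, renders the class templates on the
#' protocol's frame grid, scales by a per-cell baseline fluorescence f0 (so
#' the downstream f/f0 step is exercised on raw-unit data) and adds seeded
#' Gaussian noise. A treatment attenuation multiplies the peak f/f0 elevation
#' multiplicatively, emulating reduced glutamate-evoked calcium influx.
#'
#' Default parameter ranges: neurons peak f/f0 2.2-3.0 with plateau fraction
#' 0.85-0.95; non-neuronal cells peak 2.0-2.8 with plateau fraction 0.1-0.3;
#' baseline fluorescence 80-120 arbitrary units; noise SD 0.05 f/f0 units.
#'
#' @param n_neuron,n_non_neuron Cell counts per class (>= 0).
#' @param protocol A [calcium_protocol()]; default [dissociated_protocol()].
#' @param attenuation Multiplicative peak attenuation in (0, 1], default 1.
#' @param noise_sd Gaussian noise SD in f/f0 units, default 0.05.
#' @param seed Integer seed.
#' @param neuron_peak,neuron_plateau,non_neuron_peak,non_neuron_plateau
#'   Length-2 sampling ranges overriding the defaults.
#' @param f0_range Range of baseline fluorescence, arbitrary units.
#' @return A list: `traces` (list of [calcium_trace()]) and `truth`
#'   (data.frame: cell_id, cell_class, peak_amplitude (attenuated, f/f0),
#'   plateau_fraction, onset_time, treatment_attenuation, noise_sd, f0,
#'   seed).
#' @export
gen_traces <- function(n_neuron, n_non_neuron,
                       protocol = dissociated_protocol(),
                       attenuation = 1, noise_sd = 0.05, seed = 1L,
                       neuron_peak = c(2.2, 3.0),
                       neuron_plateau = c(0.85, 0.95),
                       non_neuron_peak = c(2.0, 2.8),
                       non_neuron_plateau = c(0.1, 0.3),
                       f0_range = c(80, 120)) {
  stopifnot(inherits(protocol, "calcium_protocol"))
  if (n_neuron < 0 || n_non_neuron < 0) stop("cell counts must be >= 0")
  if (attenuation <= 0 || attenuation > 1)
    stop("`attenuation` must lie in (0, 1]")
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  n <- n_neuron + n_non_neuron
  with_seed(seed, {
    cls <- rep(c("neuron", "non_neuron"), c(n_neuron, n_non_neuron))
    peak0 <- numeric(n); plat <- numeric(n)
    is_nrn <- cls == "neuron"
    peak0[is_nrn] <- runif(n_neuron, neuron_peak[1], neuron_peak[2])
    plat[is_nrn] <- runif(n_neuron, neuron_plateau[1], neuron_plateau[2])
    peak0[!is_nrn] <- runif(n_non_neuron, non_neuron_peak[1],
                            non_neuron_peak[2])
    plat[!is_nrn] <- runif(n_non_neuron, non_neuron_plateau[1],
                           non_neuron_plateau[2])
    f0 <- runif(n, f0_range[1], f0_range[2])
    peak <- peak0 * attenuation
    tgrid <- (seq_len(protocol$n_frames) - 1) / protocol$frame_rate
    traces <- vector("list", n)
    for (i in seq_len(n)) {
      tmpl <- if (is_nrn[i])
        neuron_template(tgrid, protocol$stimulus_onset, peak[i], plat[i])
      else
        non_neuron_template(tgrid, protocol$stimulus_onset, peak[i], plat[i])
      raw <- tmpl * f0[i]
      if (noise_sd > 0)
        raw <- raw + rnorm(length(raw), 0, noise_sd * f0[i])
      traces[[i]] <- calcium_trace(raw, protocol, cell_id = i)
    }
    truth <- data.frame(
      cell_id = seq_len(n), cell_class = cls, peak_amplitude = peak,
      plateau_fraction = plat, onset_time = protocol$stimulus_onset,
      treatment_attenuation = attenuation, noise_sd = noise_sd, f0 = f0,
      seed = as.integer(seed)
    )
    list(traces = traces, truth = truth)
  })
}
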