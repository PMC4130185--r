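proto1 <- function() calcium_protocol(1, 10, 10, 40, 60)

test_that("f/f0 uses the pre-stimulus baseline and is gain-invariant", {
  p <- proto1()
  tr <- calcium_trace(rep(5, p$n_frames), p)
  expect_equal(f_over_f0(tr)$normalized, rep(1, p$n_frames))

  # baseline frames {2, 2}, later frame 3 -> 1.5
  p2 <- calcium_protocol(1, 2, 2, 3, 5)
  tr2 <- calcium_trace(c(2, 2, 3, 2, 2), p2)
  ft2 <- f_over_f0(tr2)
  expect_equal(ft2$f0, 2)
  expect_equal(ft2$normalized[3], 1.5)

  # multiplicative gain leaves f/f0 unchanged; additive offsets do not
  v <- 5 + runif(p$n_frames)
  norm0 <- f_over_f0(calcium_trace(v, p))$normalized
  expect_equal(f_over_f0(calcium_trace(3.7 * v, p))$normalized, norm0)
  expect_false(isTRUE(all.equal(
    f_over_f0(calcium_trace(v + 2, p))$normalized, norm0)))

  expect_error(f_over_f0(calcium_trace(c(-1, rep(1, p$n_frames - 1)) * 0, p)),
               "positive")
})

test_that("AUC is the trapezoidal integral of f/f0 - 1", {
  p <- proto1()
  flat <- f_over_f0(calcium_trace(rep(2, p$n_frames), p))
  expect_equal(response_auc(flat), 0)

  # triangular excursion +1 above baseline lasting 10 s -> area 5
  v <- rep(1, p$n_frames)
  tt <- (seq_len(p$n_frames) - 1)
  up <- tt >= 20 & tt <= 25
  dn <- tt > 25 & tt <= 30
  v[up] <- 1 + (tt[up] - 20) / 5
  v[dn] <- 2 - (tt[dn] - 25) / 5
  ft <- f_over_f0(calcium_trace(v, p))
  expect_equal(response_auc(ft, c(20, 30)), 5)

  # additivity and linearity
  set.seed(12)
  ft <- f_over_f0(calcium_trace(1 + runif(p$n_frames), p))
  expect_equal(response_auc(ft, c(10, 25)) + response_auc(ft, c(25, 50)),
               response_auc(ft, c(10, 50)))
  ft3 <- ft
  ft3$normalized <- 1 + 3 * (ft$normalized - 1)
  expect_equal(response_auc(ft3, c(10, 50)), 3 * response_auc(ft, c(10, 50)))

  expect_error(response_auc(ft, c(30, 20)), "window")
})

test_that("peak response is the window maximum", {
  p <- proto1()
  flat <- f_over_f0(calcium_trace(rep(4, p$n_frames), p))
  expect_equal(peak_response(flat), 1)

  g <- gen_traces(1, 0, protocol = dissociated_protocol(), noise_sd = 0,
                  seed = 2, neuron_peak = c(2.5, 2.5))
  ft <- f_over_f0(g$traces[[1]])
  expect_equal(peak_response(ft), 2.5)
  # full window dominates any subwindow
  expect_gte(peak_response(ft), peak_response(ft, c(30, 60)))
  expect_error(peak_response(ft, c(50, 40)), "window")
})

test_that("noiseless templates classify exactly and match their labels", {
  # flat trace -> non-responder
  p <- dissociated_protocol()
  flat <- trace_features(calcium_trace(rep(7, p$n_frames), p))
  expect_equal(flat$cell_class, "non_responder")

  g <- gen_traces(3, 3, noise_sd = 0, seed = 9)
  ft <- lapply(g$traces, trace_features)
  expect_equal(vapply(ft, `[[`, character(1), "cell_class"),
               g$truth$cell_class)
  # neuron plateau ratio equals the template plateau fraction exactly
  is_nrn <- g$truth$cell_class == "neuron"
  expect_equal(vapply(ft[is_nrn], `[[`, numeric(1), "plateau_ratio"),
               g$truth$plateau_fraction[is_nrn], tolerance = 1e-12)

  # trace ending at stimulus onset has no plateau window
  p0 <- calcium_protocol(1, 10, 20, 20, 20)
  expect_error(trace_features(calcium_trace(rep(1, 20), p0)), "onset")
})

test_that("attenuation halves the noiseless peak exactly", {
  full <- gen_traces(1, 0, attenuation = 1, noise_sd = 0, seed = 3)
  half <- gen_traces(1, 0, attenuation = 0.5, noise_sd = 0, seed = 3)
  pk <- function(g) peak_response(f_over_f0(g$traces[[1]]))
  expect_equal(pk(half) - 1, (full$truth$peak_amplitude / 2) - 1,
               tolerance = 1e-12)
  expect_equal(pk(half), pk(full) / 2, tolerance = 1e-12)
})

test_that("protocol bookkeeping matches the acquisition settings", {
  org <- organotypic_protocol()
  expect_equal(org$frame_rate * org$baseline_duration, 40)  # 40-frame f0
  expect_equal(org$total_duration, 125)
  expect_equal(org$n_frames, 250)
  dis <- dissociated_protocol()
  expect_equal(dis$total_duration, 150)
  expect_equal(dis$n_frames, 150)
  expect_equal(dis$baseline_duration + (dis$stimulus_offset -
               dis$stimulus_onset) + (dis$total_duration -
               dis$stimulus_offset), 150)  # 20 + 90 + 40 s
  expect_error(calcium_protocol(0, 20, 20, 110, 150), "frame_rate")
  expect_error(gen_traces(-1, 5), ">= 0")
})

test_that("classification accuracy on noisy labelled traces is high", {
  g <- gen_traces(100, 100, seed = 21)  # default noise
  cls <- vapply(lapply(g$traces, trace_features), `[[`, character(1),
                "cell_class")
  expect_gte(mean(cls == g$truth$cell_class), 0.95)
})

test_that("group AUC comparison delegates to the rank test", {
  g <- gen_traces(5, 5, noise_sd = 0, seed = 4)
  ft <- lapply(g$traces, trace_features)
  same <- group_auc_compare(ft, ft)
  expect_equal(same$p_value, 1)

  # treated all strictly below control: U (control over treated) = n^2
  ctl <- 11:20
  trt <- 1:10
  res <- group_auc_compare(ctl, trt)
  expect_equal(unname(res$statistic), bf_u_stat(ctl, trt))
  expect_equal(unname(res$statistic), 100)
  expect_error(group_auc_compare(list(), ft), "empty")
})
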