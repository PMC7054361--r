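# Small hand-built trace helpers: one neuron, one trial, explicit epochs.
make_trace <- function(intensity, labels, neuron_id = 1L, trial = 1L) {
  n <- length(intensity)
  list(traces = tibble::tibble(neuron_id = neuron_id, trial = trial,
                               frame = seq_len(n), intensity = intensity),
       epochs = tibble::tibble(trial = trial, frame = seq_len(n),
                               label = labels))
}

test_that("dF/F normalization is definitional and scale invariant", {
  labels <- rep(c("light", "dark"), each = 5)
  tr <- make_trace(c(rep(100, 5), 150, rep(100, 4)), labels)
  d <- compute_dff(tr$traces, tr$epochs, frame_rate_hz = 1)
  expect_equal(d$neurons$f0, 100)
  expect_equal(d$dff$dff[6], 0.5)
  expect_equal(d$dff$dff[1:5], rep(0, 5))
  expect_equal(d$neurons$s, 0)
  # positive rescaling of the raw trace leaves dF/F untouched
  tr2 <- make_trace(3.7 * c(rep(100, 5), 150, rep(100, 4)), labels)
  d2 <- compute_dff(tr2$traces, tr2$epochs, frame_rate_hz = 1)
  expect_equal(d2$dff$dff, d$dff$dff)
  expect_error(compute_dff(make_trace(rep(0, 10), labels)$traces, tr$epochs),
               "positive")
})

test_that("dF/F averages across trials by default", {
  labels <- rep(c("light", "dark"), each = 4)
  traces <- dplyr::bind_rows(
    tibble::tibble(neuron_id = 1L, trial = 1L, frame = 1:8,
                   intensity = c(rep(80, 4), rep(80, 4))),
    tibble::tibble(neuron_id = 1L, trial = 2L, frame = 1:8,
                   intensity = c(rep(120, 4), rep(200, 4))))
  epochs <- tibble::tibble(trial = rep(1:2, each = 8), frame = rep(1:8, 2),
                           label = rep(labels, 2))
  d <- compute_dff(traces, epochs, frame_rate_hz = 1)
  expect_equal(d$neurons$f0, 100)                 # mean of 80 and 120
  expect_equal(d$dff$dff[5], (140 - 100) / 100)   # mean of 80 and 200
  dt <- compute_dff(traces, epochs, frame_rate_hz = 1, average_trials = FALSE)
  expect_equal(nrow(dt$neurons), 2)
  expect_equal(dt$neurons$f0, c(80, 120))
})

test_that("responder rule needs three successive frames above 3S", {
  labels <- rep(c("light", "dark"), each = 10)
  set.seed(1)
  base <- rnorm(10, 100, 1)
  s_dff <- sd((base - mean(base)) / mean(base))
  f0 <- mean(base)
  bump3 <- f0 * (1 + 4 * s_dff)
  # three consecutive frames above threshold in the dark: OFF responder
  tr <- make_trace(c(base, bump3, bump3, bump3, rep(f0, 7)), labels)
  d <- compute_dff(tr$traces, tr$epochs, frame_rate_hz = 1)
  call <- classify_responders(d)
  expect_equal(call$class, "OFF")
  expect_equal(call$onset_frame, 11L)
  # only two consecutive frames, however large: no responder
  tr2 <- make_trace(c(base, f0 * (1 + 10 * s_dff), f0 * (1 + 10 * s_dff),
                      rep(f0, 8)), labels)
  d2 <- compute_dff(tr2$traces, tr2$epochs, frame_rate_hz = 1)
  expect_equal(classify_responders(d2)$class, "none")
})

test_that("onset epoch assigns OFF vs ON; relight responses are ON", {
  labels <- rep(c("light", "dark", "light"), each = 6)
  base <- rep(100, 6)
  quiet <- rep(100, 6)
  burst <- c(150, 150, 150, 120, 110, 105)
  tr_on <- make_trace(c(base, quiet, burst), labels)
  d_on <- compute_dff(tr_on$traces, tr_on$epochs, frame_rate_hz = 1)
  call_on <- classify_responders(d_on)
  expect_equal(call_on$class, "ON")
  expect_true(call_on$zero_baseline_sd)
  # an excursion confined to the baseline epoch stays unclassified
  tr_b <- make_trace(c(100, 150, 150, 150, 100, 100, quiet, base), labels)
  d_b <- compute_dff(tr_b$traces, tr_b$epochs, frame_rate_hz = 1)
  d_b$neurons$s <- 0.01 # hand-set so the baseline excursion clears 3S
  call_b <- classify_responders(d_b)
  expect_equal(call_b$class, "none")
  expect_equal(call_b$onset_frame, 2L)
})

test_that("half-max timing follows linear geometry and flags unreturned traces", {
  # peak 1.0 at 10 s after stimulus, linear decay to 0 at 30 s: half-max at 20 s
  labels <- c(rep("light", 5), rep("dark", 31))
  dark_dff <- c(seq(0, 1, length.out = 11), seq(0.95, 0, length.out = 20))
  tr <- make_trace(100 * (1 + c(rep(0, 5), dark_dff)), labels)
  d <- compute_dff(tr$traces, tr$epochs, frame_rate_hz = 1)
  d$neurons$s <- 0.01 # hand-set noise scale for a clean threshold
  call <- response_timing(d, classify_responders(d))
  expect_equal(call$class, "OFF")
  expect_equal(call$peak_dff, 1.0)
  # decay runs linearly from 0.95 one second after the peak to 0 at 30 s,
  # so dF/F crosses 0.5 at 25 s, i.e. 20 s after the light-off stimulus
  expect_equal(call$time_to_half_max_s, 20, tolerance = 1e-6)
  expect_true(call$returned_within_30s)
  # monotonically rising trace: never returns to half-max
  rise <- make_trace(100 * (1 + c(rep(0, 5), seq(0.1, 2, length.out = 31))),
                     labels)
  dr <- compute_dff(rise$traces, rise$epochs, frame_rate_hz = 1)
  dr$neurons$s <- 0.01
  cr <- response_timing(dr, classify_responders(dr))
  expect_false(cr$half_max_reached)
  expect_true(is.na(cr$time_to_half_max_s))
})

test_that("planted kernel timing matches the closed form rise + tau * log(2)", {
  cfg <- trace_config(n_neurons = 6, frac_off = 1, frac_on = 0, noise_sd = 0,
                      decay_tau_s = 20, rise_frames = 2, frame_rate_hz = 1,
                      epochs = data.frame(label = c("light", "dark"),
                                          duration_s = c(30, 90)),
                      n_trials = 1, seed = 4)
  cc <- generate_calcium_cohort(cfg)
  d <- compute_dff(cc$traces, cc$epochs, frame_rate_hz = 1)
  d$neurons$s <- 0.001
  calls <- response_timing(d, classify_responders(d))
  # the planted kernel peaks (rise_frames - 1) frames after the stimulus and
  # then decays exponentially, so half-max falls at rise + tau * ln 2
  expected <- (2 - 1) / 1 + 20 * log(2)
  expect_true(all(abs(calls$time_to_half_max_s - expected) <= 1))
})

test_that("raising a responder's amplitude never demotes it to none", {
  labels <- rep(c("light", "dark"), each = 8)
  set.seed(2)
  base <- rnorm(8, 100, 1)
  for (amp in c(0.2, 0.5, 1, 2, 5)) {
    tr <- make_trace(c(base, rep(100 * (1 + amp), 3), rep(100, 5)), labels)
    d <- compute_dff(tr$traces, tr$epochs, frame_rate_hz = 1)
    expect_equal(classify_responders(d)$class, "OFF")
  }
})

test_that("false-positive rate on pure noise matches the run-probability oracle", {
  # relaxed threshold (1 sd) so the event is common enough to estimate
  cfg <- trace_config(n_neurons = 600, frac_off = 0, frac_on = 0, noise_sd = 2,
                      frame_rate_hz = 1, n_trials = 1,
                      epochs = data.frame(label = c("light", "dark"),
                                          duration_s = c(30, 30)),
                      seed = 6)
  cc <- generate_calcium_cohort(cfg)
  d <- compute_dff(cc$traces, cc$epochs, frame_rate_hz = 1)
  calls <- classify_responders(d, n_sd = 1)
  emp <- mean(!is.na(calls$onset_frame))
  oracle <- run_prob_oracle(60, pnorm(-1), 3)
  expect_equal(emp, oracle, tolerance = 0.05 / oracle)
})

test_that("cohort summaries report responder fractions and OFF return rates", {
  calls <- tibble::tibble(
    neuron_id = 1:10,
    class = c(rep("OFF", 3), "ON", rep("none", 6)),
    returned_within_30s = c(TRUE, TRUE, FALSE, TRUE, rep(NA, 6)),
    time_to_half_max_s = c(10, 20, NA, 5, rep(NA, 6)))
  s <- cohort_response_summary(calls)
  expect_equal(s$pct_off, 30)
  expect_equal(s$pct_on, 10)
  expect_equal(s$frac_off_returned_30s, 2 / 3)
  expect_equal(s$mean_time_to_half_max_s, 15)
  none <- cohort_response_summary(tibble::tibble(neuron_id = 1:3, class = "none"))
  expect_equal(none$pct_off + none$pct_on, 0)
  expect_error(cohort_response_summary(calls[0, ]), "no responder")
  # the observed-cohort composition: 46 OFF of 299 prints as 15.4% at 1 dp
  frac <- cohort_response_summary(tibble::tibble(
    neuron_id = 1:299, class = rep(c("OFF", "ON", "none"), c(46, 14, 239))))
  expect_equal(round(frac$pct_off, 1), 15.4)
  expect_equal(round(frac$pct_on, 1), 4.7)
})
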