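test_that("per-cycle burst frequency follows the inverse-mean-ISI rule", {
  expect_equal(burst_frequency_per_cycle(c(100, 110, 120), c(0, 1000)), 100)
  expect_equal(burst_frequency_per_cycle(c(500), c(0, 1000)), 0) # one spike
  expect_equal(burst_frequency_per_cycle(numeric(0), c(0, 1000)), 0)
  expect_equal(burst_frequency_per_cycle(c(0, 10, 30), c(0, 1000)),
               1000 / mean(c(10, 20)))  # 66.67 Hz
  # spikes outside the window are ignored
  expect_equal(burst_frequency_per_cycle(c(5, 100, 110, 120, 990),
                                         c(50, 950)), 100)
  expect_error(burst_frequency_per_cycle(c(10, 5), c(0, 100)), "sorted")
})

test_that("burst averages are recomputable and exactly periodic trains have zero SD", {
  p <- published_individual("FF1")
  sim <- adex_simulate(p, sinusoid_protocol(6, 8.08))
  bm <- average_burst_frequency(sim, mode = "stabilized")
  expect_length(bm$per_cycle, 10)
  expect_equal(bm$mean, mean(bm$per_cycle))
  n <- length(bm$per_cycle)
  expect_equal(bm$sd, stats::sd(bm$per_cycle) * sqrt((n - 1) / n))
  # the steady-state response at this frequency is cycle-periodic to
  # solver precision
  expect_lt(bm$sd, 1e-3)
  # a constructed train with identical per-cycle patterns has SD = 0
  # exactly
  T_ms <- 1000 / 8
  fake <- structure(list(
    spikes = as.vector(outer(c(10, 28, 44), (0:39) * T_ms, "+")),
    protocol = sinusoid_protocol(6, 8, duration = 5000)),
    class = "adex_sim")
  bm0 <- average_burst_frequency(fake, mode = "stabilized")
  expect_identical(bm0$sd, 0)
  expect_equal(bm0$mean, 1000 / mean(c(18, 16)))
})

test_that("a too-short simulation is rejected with a protocol error", {
  p <- published_individual("FF1")
  sim <- adex_simulate(p, sinusoid_protocol(6, 0.58, duration = 5000))
  expect_error(average_burst_frequency(sim, mode = "stabilized"),
               "too short")
  expect_error(average_burst_frequency(adex_simulate(p, step_protocol(16)),
                                       mode = "initial"), "sinusoidal")
})

test_that("cycles with at most one spike zero out, per cycle or per point", {
  p <- published_individual("FF1")
  # far beyond the falling edge: at most one spike per cycle
  sim <- adex_simulate(p, sinusoid_protocol(
    6, 20, duration = burst_duration_needed(20)))
  bm <- average_burst_frequency(sim, mode = "stabilized")
  expect_identical(bm$mean, 0)
  expect_identical(max(bm$per_cycle), 0)
  # whole-point rule drops silent cycles instead of averaging them in
  sim2 <- adex_simulate(p, sinusoid_protocol(
    6, 8.08, duration = burst_duration_needed(8.08)))
  bm_pc <- average_burst_frequency(sim2, zero_rule = "per_cycle")
  bm_wp <- average_burst_frequency(sim2, zero_rule = "whole_point")
  expect_gte(bm_wp$mean, bm_pc$mean)
})

test_that("step responses count spikes over the stimulated second", {
  # printed contract: the FF2 reference model fires 30 spikes at 10 pA
  sr <- step_response(published_individual("FF2"), 10)
  expect_equal(sr$mean_frequency_Hz, 30)
  expect_equal(sr$mean_frequency_Hz, sr$n_spikes) # 1-s step: count = Hz
  expect_true(sr$latency_ms > 0 && sr$latency_ms <= 1001)
  # below rheobase: silent, latency is the explicit missing value
  sr0 <- step_response(published_individual("FF1"), 5)
  expect_equal(sr0$mean_frequency_Hz, 0)
  expect_true(is.na(sr0$latency_ms))
})

test_that("rheobase search matches the published reference models", {
  expect_equal(rheobase(published_individual("FF1")), 10)
  expect_equal(rheobase(published_individual("FF2")), 3)
  expect_true(is.na(rheobase(published_individual("FF1"),
                             amplitudes = 0:5)))
})

test_that("the I-F curve is monotone and close to linear", {
  ic <- if_curve(published_individual("FF1"))
  expect_equal(ic$rheobase_pA, 10)
  expect_true(all(diff(ic$table$mean_frequency_Hz) >= 0))
  expect_true(ic$linear)
  expect_gt(ic$r, 0.9)
  expect_gt(ic$slope_Hz_per_pA, 0)
})

test_that("impedance cut-offs derive from tau_w and tau_m", {
  p4 <- published_individual("FF4")
  z <- impedance_profile(p4, frequencies = c(1, 2))
  expect_equal(z$cutoff_highpass_Hz, 1000 / (2 * pi * 619.07),
               tolerance = 1e-10)
  expect_equal(z$cutoff_lowpass_Hz, 1000 / (2 * pi * (2.80 / 0.25)),
               tolerance = 1e-10)
  expect_equal(round(z$cutoff_highpass_Hz, 3), 0.257)
  expect_equal(round(z$cutoff_lowpass_Hz, 1), 14.2)
})

test_that("without adaptation the impedance reduces to the RC low-pass form", {
  p0 <- passive_params(a = 0)
  freqs <- c(0.5, 2, 8, 20, 30)
  z <- impedance_profile(p0, frequencies = freqs)
  tau_m <- p0$C_m / p0$g_L
  rc <- 1 / (p0$g_L * sqrt(1 + (2 * pi * freqs * tau_m / 1000)^2))
  expect_equal(z$table$impedance_MOhm_like, rc, tolerance = 0.05)
})

test_that("suprathreshold stimulation is a regime error naming the frequency", {
  expect_error(impedance_profile(published_individual("FF2"),
                                 amplitude = 30, frequencies = 4),
               "4 Hz")
})

test_that("an all-silent resonance curve ties to the lowest grid frequency", {
  rc <- resonance_curve(silent_params(), amplitude = 6,
                        frequencies = c(4, 8, 12))
  expect_true(all(rc$table$mean_Hz == 0))
  expect_equal(rc$peak_frequency, 4)
})
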