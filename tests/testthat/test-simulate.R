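test_that("the FF4 reference neuron is silent at rest", {
  sim <- adex_simulate(published_individual("FF4"), zero_protocol(1000))
  expect_length(sim$spikes, 0)
})

test_that("zero-duration protocols return the initial state only", {
  p <- published_individual("FF4")
  sim <- adex_simulate(p, zero_protocol(0))
  expect_length(sim$spikes, 0)
  expect_equal(nrow(sim$trace), 1)
  expect_equal(sim$trace$V_mV, p$E_L)
  expect_equal(sim$trace$w_pA, 0)
})

test_that("hyperpolarizing steady state matches the fixed-step reference", {
  p <- published_individual("FF4")
  proto <- step_protocol(-8, duration = 1400, onset = 0, t_total = 1400)
  sim <- adex_simulate(p, proto, record_dt = 1)
  oracle <- adex_simulate_rk4(p, proto, dt = 0.001)
  expect_lt(abs(utils::tail(sim$trace$V_mV, 1) - oracle$V_final), 0.01)
})

test_that("with a = b = 0 the adaptation current stays identically zero", {
  p <- passive_params(a = 0)
  sim <- adex_simulate(p, sinusoid_protocol(5, 4, offset = 0, duration = 3000),
                       record_dt = 0.5)
  expect_lt(max(abs(sim$trace$w_pA)), 1e-12)
})

test_that("small-signal response matches the linearized impedance within 5%", {
  p <- passive_params(a = 0.3)
  f <- 4
  sim <- adex_simulate(p, sinusoid_protocol(0.1, f, offset = 0,
                                            duration = 6000),
                       record_dt = 0.5)
  expect_length(sim$spikes, 0)
  tr <- sim$trace[sim$trace$time_ms >= 4000, ]
  measured <- (max(tr$V_mV) - min(tr$V_mV)) / 2
  om <- 2 * pi * f / 1000 # rad/ms
  Z <- 1 / Mod(complex(real = p$g_L, imaginary = om * p$C_m) +
                 p$a / complex(real = 1, imaginary = om * p$tau_w))
  expect_equal(measured, 0.1 * Z, tolerance = 0.05)
})

test_that("no two spikes are closer than the refractory period", {
  for (case in list(list("FF2", step_protocol(22)),
                    list("FF1", sinusoid_protocol(8, 10.19, duration = 4000)),
                    list("FF4", step_protocol(25)))) {
    sim <- adex_simulate(published_individual(case[[1]]), case[[2]])
    expect_gt(length(sim$spikes), 1)
    expect_true(all(diff(sim$spikes) >= 1 - 1e-9))
    expect_true(all(diff(sim$spikes) > 0))
  }
})

test_that("recorded traces are well-formed and bounded by V_peak", {
  p <- published_individual("FF1")
  sim <- adex_simulate(p, step_protocol(16), record_dt = 0.1)
  expect_equal(nrow(sim$trace), length(sim$trace$time_ms))
  expect_true(all(diff(sim$trace$time_ms) > 0))
  expect_lte(max(sim$trace$V_mV), p$V_peak + 1e-6)
})

test_that("adaptive spike times agree with the fixed-step reference", {
  p <- published_individual("FF1")
  proto <- step_protocol(16)
  a <- adex_simulate(p, proto)$spikes
  o <- adex_simulate_rk4(p, proto, dt = 0.001)$spikes
  expect_equal(length(a), length(o))
  expect_lt(max(abs(a - o)), 0.05)
})

test_that("simulation is deterministic for identical inputs", {
  p <- published_individual("FF2")
  proto <- sinusoid_protocol(8, 8.08, duration = 3000)
  expect_identical(adex_simulate(p, proto)$spikes,
                   adex_simulate(p, proto)$spikes)
})

test_that("traces and spikes export to CSV and JSON", {
  sim <- adex_simulate(published_individual("FF4"), step_protocol(16),
                       record_dt = 1)
  csv <- tempfile(fileext = ".csv")
  write_trace_csv(sim, csv)
  tr <- utils::read.csv(csv)
  expect_named(tr, c("time_ms", "V_mV", "w_pA"))
  expect_equal(nrow(tr), nrow(sim$trace))
  scsv <- tempfile(fileext = ".csv")
  write_spikes_csv(sim, scsv)
  expect_equal(utils::read.csv(scsv)$spike_time_ms, sim$spikes)
  parsed <- jsonlite::fromJSON(sim_to_json(sim))
  expect_equal(parsed$spikes_ms, sim$spikes)
  expect_equal(parsed$parameters$tau_w, 619.07)
})

test_that("protocol constructors reject degenerate inputs", {
  expect_error(sinusoid_protocol(6, frequency = 0))
  expect_error(step_protocol(10, duration = 0))
  expect_error(step_protocol(Inf))
})

test_that("the step budget converts runaway integrations into errors", {
  p <- passive_params()
  expect_error(
    adex_simulate(p, zero_protocol(10000),
                  solver = solver_config(h_min = 1e-7, h_max = 1e-4,
                                         max_steps = 1000)),
    "step budget")
})
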