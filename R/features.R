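#' Per-cycle burst frequency
#'
#' The burst frequency within one stimulation cycle is the inverse of the
#' mean inter-spike interval (ISI) of the spikes falling inside the cycle
#' window, in Hz. Cycles holding one spike or none contribute 0 Hz (a
#' single spike has no ISI; this is the zero rule that makes resonance
#' curves fall to zero at high stimulation frequencies).
#'
#' @param spikes numeric vector of spike times (ms), sorted increasing.
#' @param window length-2 numeric, the half-open cycle window `[t0, t1)`
#'   in ms.
#' @return Burst frequency in Hz (>= 0).
#' @export
#' @examples
#' burst_frequency_per_cycle(c(100, 110, 120), c(0, 1000))  # 100 Hz
burst_frequency_per_cycle <- function(spikes, window) {
  if (is.unsorted(spikes, strictly = FALSE)) {
    stop("spike times must be sorted increasing", call. = FALSE)
  }
  stopifnot(length(window) == 2, window[2] > window[1])
  s <- spikes[spikes >= window[1] & spikes < window[2]]
  if (length(s) < 2) return(0)
  1000 / mean(diff(s))
}

# cycle windows of a sinusoidal protocol, trough-to-trough by default:
# cycle k spans [(k - 1/4) T, (k + 3/4) T) after stimulus onset, so each
# window is centred on the positive peak and bounded by the stimulus
# minima (phase 270 deg). "phase0" gives the plain [kT, (k+1)T) windows.
cycle_window <- function(protocol, k, anchor = c("trough", "phase0")) {
  anchor <- match.arg(anchor)
  T_ms <- 1000 / protocol$frequency
  off <- if (anchor == "trough") -0.25 else 0
  protocol$onset + c((k + off) * T_ms, (k + off + 1) * T_ms)
}

#' Average burst frequency over 10 stimulation cycles
#'
#' Measures the per-cycle burst frequency over 10 consecutive cycles of a
#' sinusoidal stimulation and returns their mean and standard deviation.
#' Two measurement windows are supported: `"initial"` uses cycles 0-9 of
#' the stimulation; `"stabilized"` (the default for fitness scoring) uses
#' the first 10 cycles starting at or after 2 s, letting the membrane
#' potential and the slow adaptation current reach their periodic steady
#' state before measuring (2 s is twice the largest admissible adaptation
#' time constant).
#'
#' Cycle windows are anchored at the stimulus minima (sinusoidal phase
#' 270 deg) so that each window is centred on the positive phase where the
#' burst occurs; spikes of a burst are then never split across windows and
#' the slow inter-burst intervals straddle the boundaries, where they are
#' excluded from the ISI average. Set `anchor = "phase0"` for plain
#' zero-phase windows.
#'
#' @param sim an `adex_sim` from a sinusoidal protocol.
#' @param mode `"stabilized"` or `"initial"`.
#' @param anchor cycle-window anchoring, `"trough"` (default) or
#'   `"phase0"`.
#' @param zero_rule `"per_cycle"` (default): each cycle with <= 1 spike
#'   contributes 0 Hz; `"whole_point"`: the mean is zeroed only when every
#'   measured cycle holds <= 1 spike, otherwise sparse cycles are dropped
#'   from the average.
#' @return A list of class `burst_measurement`: `frequency` and
#'   `amplitude` of the stimulation, `per_cycle` (10 values, Hz), `mean`,
#'   `sd`, `mode`.
#' @export
average_burst_frequency <- function(sim, mode = c("stabilized", "initial"),
                                    anchor = c("trough", "phase0"),
                                    zero_rule = c("per_cycle", "whole_point")) {
  mode <- match.arg(mode)
  anchor <- match.arg(anchor)
  zero_rule <- match.arg(zero_rule)
  protocol <- sim$protocol
  if (protocol$kind != "sinusoid") {
    stop("burst frequency is defined for sinusoidal protocols", call. = FALSE)
  }
  T_ms <- 1000 / protocol$frequency
  k0 <- if (mode == "stabilized") ceiling(2000 / T_ms) else 0
  ks <- k0:(k0 + 9)
  last_end <- cycle_window(protocol, ks[10], anchor)[2]
  if (last_end > protocol$t_total + 1e-9) {
    stop(sprintf(
      "simulation too short for 10 %s cycles at %g Hz: need %.0f ms, have %g ms",
      mode, protocol$frequency, last_end, protocol$t_total), call. = FALSE)
  }
  per_cycle <- vapply(ks, function(k) {
    burst_frequency_per_cycle(sim$spikes, cycle_window(protocol, k, anchor))
  }, numeric(1))
  vals <- per_cycle
  if (zero_rule == "whole_point" && any(per_cycle > 0)) {
    vals <- per_cycle[per_cycle > 0]
  }
  structure(list(frequency = protocol$frequency,
                 amplitude = protocol$amplitude,
                 per_cycle = per_cycle,
                 mean = mean(vals),
                 sd = stats::sd(vals) * sqrt((length(vals) - 1) / length(vals)),
                 mode = mode),
            class = "burst_measurement")
}

#' @export
print.burst_measurement <- function(x, ...) {
  cat(sprintf("Burst frequency @ %g Hz, %g pA: %.2f +/- %.2f Hz (%s window)\n",
              x$frequency, x$amplitude, x$mean, x$sd, x$mode))
  invisible(x)
}

#' Spiking-resonance curve
#'
#' Sweeps sinusoidal stimulation frequencies from 0.5 to 30 Hz in 0.5-Hz
#' steps at fixed amplitude (plus the 12-pA offset), measuring the 10-cycle
#' average burst frequency at each. The preferred (resonance) frequency is
#' the grid frequency with the maximal mean burst frequency; ties resolve
#' to the lowest frequency.
#'
#' @param params an [adex_parameters()] object.
#' @param amplitude sinusoidal amplitude (pA).
#' @param mode,anchor,zero_rule passed to [average_burst_frequency()].
#' @param frequencies stimulation-frequency grid (Hz).
#' @param offset offset current (pA).
#' @param solver a [solver_config()].
#' @return A list of class `resonance_curve`: `table` (data.frame
#'   `frequency_Hz`, `mean_Hz`, `sd_Hz`), `peak_frequency`, `amplitude`,
#'   `mode`.
#' @export
resonance_curve <- function(params, amplitude, mode = "stabilized",
                            frequencies = seq(0.5, 30, by = 0.5),
                            offset = 12, anchor = "trough",
                            zero_rule = "per_cycle",
                            solver = solver_config()) {
  stopifnot(amplitude > 0, length(frequencies) >= 1,
            !is.unsorted(frequencies, strictly = TRUE))
  rows <- lapply(frequencies, function(f) {
    sim <- adex_simulate(params, sinusoid_protocol(
      amplitude, frequency = f, offset = offset,
      duration = burst_duration_needed(f, mode)), solver = solver)
    bm <- average_burst_frequency(sim, mode = mode, anchor = anchor,
                                  zero_rule = zero_rule)
    data.frame(frequency_Hz = f, mean_Hz = bm$mean, sd_Hz = bm$sd)
  })
  tab <- do.call(rbind, rows)
  peak <- tab$frequency_Hz[which.max(tab$mean_Hz)]
  structure(list(table = tab, peak_frequency = peak, amplitude = amplitude,
                 mode = mode),
            class = "resonance_curve")
}

#' @export
print.resonance_curve <- function(x, ...) {
  cat(sprintf(
    "Spiking-resonance curve (%g pA, %s window): peak %.1f Hz, max %.2f Hz\n",
    x$amplitude, x$mode, x$peak_frequency, max(x$table$mean_Hz)))
  invisible(x)
}

#' Shortest sinusoidal duration containing the measured cycles
#'
#' The minimal stimulation length (ms) whose 10 measured cycle windows
#' are identical to those of the full 22.5-s protocol, capped at 22.5 s.
#' Used to shorten fitness-evaluation simulations without changing any
#' measured value.
#'
#' @param frequency stimulation frequency (Hz).
#' @param mode `"stabilized"` or `"initial"`.
#' @return Duration in ms.
#' @export
burst_duration_needed <- function(frequency, mode = "stabilized") {
  T_ms <- 1000 / frequency
  k0 <- if (mode == "stabilized") ceiling(2000 / T_ms) else 0
  min(22500, ceiling((k0 + 9.75) * T_ms) + 1)
}

#' Step-current response features
#'
#' Simulates a 1-s step current and extracts the two repetitive-firing
#' features: the mean frequency (spike count during the step divided by
#' the stimulation time) and the first-spike latency, measured from the
#' stimulation trigger. When no spike occurs the latency is `NA` and the
#' mean frequency 0.
#'
#' @param params an [adex_parameters()] object.
#' @param amplitude step amplitude (pA).
#' @param duration step duration (ms).
#' @param solver a [solver_config()].
#' @return A list of class `step_features`: `amplitude`,
#'   `mean_frequency_Hz`, `latency_ms` (NA if silent), `n_spikes`.
#' @export
#' @examples
#' step_response(published_individual("FF4"), 16)$mean_frequency_Hz
step_response <- function(params, amplitude, duration = 1000,
                          solver = solver_config()) {
  stopifnot(is.finite(amplitude))
  protocol <- step_protocol(amplitude, duration = duration)
  sim <- adex_simulate(params, protocol, solver = solver)
  s <- sim$spikes
  s <- s[s >= protocol$onset & s < protocol$onset + protocol$duration]
  structure(list(amplitude = amplitude,
                 mean_frequency_Hz = length(s) / (duration / 1000),
                 latency_ms = if (length(s)) s[1] else NA_real_,
                 n_spikes = length(s)),
            class = "step_features")
}

#' @export
print.step_features <- function(x, ...) {
  cat(sprintf("Step %g pA: %g Hz mean frequency, first spike at %s ms\n",
              x$amplitude, x$mean_frequency_Hz,
              if (is.na(x$latency_ms)) "-" else sprintf("%.2f", x$latency_ms)))
  invisible(x)
}

#' Rheobase
#'
#' The minimum step-current amplitude eliciting at least one spike,
#' searched on a regular amplitude grid with 1-s steps.
#'
#' @param params an [adex_parameters()] object.
#' @param amplitudes search grid (pA), default 0 to 25 pA at 1-pA
#'   resolution.
#' @param solver a [solver_config()].
#' @return The rheobase (pA), or `NA` when no grid amplitude fires.
#' @export
rheobase <- function(params, amplitudes = seq(0, 25, by = 1),
                     solver = solver_config()) {
  for (amp in amplitudes) {
    if (step_response(params, amp, solver = solver)$n_spikes >= 1) {
      return(amp)
    }
  }
  NA_real_
}

#' I-F curve and its linear fit
#'
#' Builds the intensity-frequency curve over 1-s step currents from the
#' rheobase to `max_amplitude` in 1-pA increments, and fits an ordinary
#' least-squares line through the (amplitude, mean frequency) points. The
#' slope (Hz/pA) quantifies intrinsic excitability; the Pearson
#' correlation is reported as a linearity diagnostic and flagged (not
#' failed) when r <= 0.9.
#'
#' @param params an [adex_parameters()] object.
#' @param max_amplitude top of the amplitude grid (pA).
#' @param resolution amplitude grid spacing (pA).
#' @param solver a [solver_config()].
#' @return A list of class `if_curve`: `table` (data.frame `amplitude_pA`,
#'   `mean_frequency_Hz`), `rheobase_pA`, `slope_Hz_per_pA`, `intercept`,
#'   `r`, `linear` (logical flag r > 0.9).
#' @export
if_curve <- function(params, max_amplitude = 25, resolution = 1,
                     solver = solver_config()) {
  stopifnot(resolution > 0)
  rheo <- rheobase(params, amplitudes = seq(0, max_amplitude, by = resolution),
                   solver = solver)
  if (is.na(rheo)) {
    stop("no rheobase found below ", max_amplitude, " pA; cannot fit I-F curve",
         call. = FALSE)
  }
  amps <- seq(rheo, max_amplitude, by = resolution)
  if (length(amps) < 2) stop("fewer than 2 I-F grid points", call. = FALSE)
  freqs <- vapply(amps, function(a) {
    step_response(params, a, solver = solver)$mean_frequency_Hz
  }, numeric(1))
  fit <- stats::lm(freqs ~ amps)
  r <- stats::cor(amps, freqs)
  structure(list(table = data.frame(amplitude_pA = amps,
                                    mean_frequency_Hz = freqs),
                 rheobase_pA = rheo,
                 slope_Hz_per_pA = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r = r, linear = r > 0.9),
            class = "if_curve")
}

#' @export
print.if_curve <- function(x, ...) {
  cat(sprintf("I-F curve: rheobase %g pA, slope %.2f Hz/pA (r = %.3f%s)\n",
              x$rheobase_pA, x$slope_Hz_per_pA, x$r,
              if (x$linear) "" else ", sub-linear"))
  invisible(x)
}

#' Subthreshold impedance profile
#'
#' Measures the membrane impedance modulus |Z(f)| under small sinusoidal
#' currents: for each grid frequency the neuron is stimulated with a
#' 2-pA (by default) zero-offset sinusoid, the first 2 s are discarded as
#' transient, and |Z(f)| is the ratio of the Fourier amplitudes of V and I
#' at the stimulation frequency over an integer number of cycles
#' (extracted with the FFT). The profile is bracketed by the high-pass
#' cut-off 1/(2 pi tau_w) set by the adaptation current and the low-pass
#' cut-off 1/(2 pi tau_m), tau_m = C_m/g_L, set by the passive membrane.
#'
#' The stimulation must remain subthreshold; a spike at any grid
#' frequency raises an error naming that frequency.
#'
#' @param params an [adex_parameters()] object.
#' @param amplitude sinusoidal amplitude (pA); keep small.
#' @param frequencies frequency grid (Hz); multiples of 0.5 Hz.
#' @param record_dt trace sampling interval (ms) for the FFT.
#' @param solver a [solver_config()].
#' @return A list of class `impedance_profile`: `table` (data.frame
#'   `frequency_Hz`, `impedance_MOhm_like` in mV/pA), `peak_frequency`,
#'   `cutoff_highpass_Hz`, `cutoff_lowpass_Hz`.
#' @export
impedance_profile <- function(params, amplitude = 2,
                              frequencies = seq(0.5, 30, by = 0.5),
                              record_dt = 0.5,
                              solver = solver_config()) {
  transient <- 2000
  rows <- lapply(frequencies, function(f) {
    n_cycles <- max(10, ceiling(2 * f))
    window_ms <- n_cycles / f * 1000
    protocol <- sinusoid_protocol(amplitude, frequency = f, offset = 0,
                                  duration = transient + window_ms)
    sim <- adex_simulate(params, protocol, solver = solver,
                         record_dt = record_dt)
    if (length(sim$spikes)) {
      stop(sprintf(
        "stimulation at %g Hz evoked %d spike(s); impedance needs a subthreshold regime",
        f, length(sim$spikes)), call. = FALSE)
    }
    tr <- sim$trace
    sel <- tr$time_ms >= transient & tr$time_ms < transient + window_ms
    v <- tr$V_mV[sel]
    i <- stim_current(protocol, tr$time_ms[sel])
    n <- length(v)
    bin <- n_cycles + 1L  # DC is bin 1; f occupies bin n_cycles + 1
    zf <- Mod(stats::fft(v)[bin]) / Mod(stats::fft(i)[bin])
    data.frame(frequency_Hz = f, impedance_MOhm_like = zf)
  })
  tab <- do.call(rbind, rows)
  tau_m <- params$C_m / params$g_L
  structure(list(table = tab,
                 peak_frequency = tab$frequency_Hz[which.max(tab$impedance_MOhm_like)],
                 cutoff_highpass_Hz = 1000 / (2 * pi * params$tau_w),
                 cutoff_lowpass_Hz = 1000 / (2 * pi * tau_m)),
            class = "impedance_profile")
}

#' @export
print.impedance_profile <- function(x, ...) {
  cat(sprintf(
    "Impedance profile: peak %.1f Hz; band %.3f - %.2f Hz (high/low-pass cut-offs)\n",
    x$peak_frequency, x$cutoff_highpass_Hz, x$cutoff_lowpass_Hz))
  invisible(x)
}
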