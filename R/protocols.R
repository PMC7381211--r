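#' Stimulation protocols
#'
#' Current-injection protocols for [adex_simulate()]. Currents are in pA,
#' times in ms.
#'
#' `step_protocol()` injects a constant current of the given amplitude for
#' `duration` ms starting at `onset`. The default onset of 1 ms reproduces
#' the one-transmission-delay lag with which event-driven simulators
#' deliver generator currents; first-spike latencies are conventionally
#' measured from the stimulation trigger at t = 0, so they include this
#' delay.
#'
#' `sinusoid_protocol()` injects `offset + amplitude * sin(2 pi f t)` pA
#' from t = 0 (phase 0 at onset). The default 12-pA offset and 22.5-s
#' duration are the standard burst-resonance stimulation conditions.
#'
#' `zero_protocol()` injects nothing; useful for resting-state checks.
#'
#' @param amplitude current amplitude (pA); for sinusoids the half-peak
#'   amplitude of the oscillating component.
#' @param onset stimulus start time (ms).
#' @param duration stimulated interval length (ms).
#' @param t_total total simulated time (ms); defaults to the end of the
#'   stimulus.
#' @return An object of class `stim_protocol`.
#' @export
#' @examples
#' step_protocol(16)                  # 16 pA for 1 s
#' sinusoid_protocol(6, frequency = 8.08)
step_protocol <- function(amplitude, duration = 1000, onset = 1,
                          t_total = onset + duration) {
  stopifnot(is.finite(amplitude), duration > 0, onset >= 0)
  structure(list(kind = "step", kind_code = 1L, amplitude = amplitude,
                 offset = 0, frequency = 0, onset = onset,
                 duration = duration, t_total = t_total),
            class = "stim_protocol")
}

#' @rdname step_protocol
#' @param offset constant current added to the sinusoid (pA).
#' @param frequency stimulation frequency (Hz).
#' @export
sinusoid_protocol <- function(amplitude, frequency, offset = 12,
                              duration = 22500, onset = 0,
                              t_total = onset + duration) {
  stopifnot(is.finite(amplitude), is.finite(offset), frequency > 0,
            duration > 0)
  structure(list(kind = "sinusoid", kind_code = 2L, amplitude = amplitude,
                 offset = offset, frequency = frequency, onset = onset,
                 duration = duration, t_total = t_total),
            class = "stim_protocol")
}

#' @rdname step_protocol
#' @export
zero_protocol <- function(t_total = 1000) {
  stopifnot(t_total >= 0)
  structure(list(kind = "zero", kind_code = 0L, amplitude = 0, offset = 0,
                 frequency = 0, onset = 0, duration = t_total,
                 t_total = t_total),
            class = "stim_protocol")
}

#' @export
print.stim_protocol <- function(x, ...) {
  desc <- switch(x$kind,
    zero = sprintf("zero current, %g ms", x$t_total),
    step = sprintf("step %g pA, onset %g ms, duration %g ms", x$amplitude,
                   x$onset, x$duration),
    sinusoid = sprintf("sinusoid %g pA at %g Hz + %g pA offset, %g ms",
                       x$amplitude, x$frequency, x$offset, x$duration))
  cat("Stimulation protocol:", desc, "\n")
  invisible(x)
}

#' Instantaneous stimulus current
#'
#' Evaluates the injected current of a protocol at arbitrary times;
#' matches the waveform the integrator sees.
#'
#' @param protocol a `stim_protocol`.
#' @param t numeric vector of times (ms).
#' @return Numeric vector of currents (pA).
#' @export
stim_current <- function(protocol, t) {
  switch(protocol$kind,
    zero = rep(0, length(t)),
    step = ifelse(t >= protocol$onset & t < protocol$onset + protocol$duration,
                  protocol$amplitude, 0),
    sinusoid = ifelse(t < protocol$onset, 0,
      protocol$offset + protocol$amplitude *
        sin(2 * pi * protocol$frequency * (t - protocol$onset) / 1000)))
}
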