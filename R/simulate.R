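#' Solver configuration
#'
#' Settings for the adaptive Runge-Kutta-Fehlberg 4(5) integrator.
#' Defaults are tight enough that feature values are limited by the model,
#' not by integration error.
#'
#' @param rtol relative error tolerance per step.
#' @param atol absolute error tolerance (mV for V, pA for w).
#' @param h_max maximum step size (ms).
#' @param h_min minimum step size (ms); steps at `h_min` are accepted even
#'   when the error estimate exceeds tolerance (counted in diagnostics).
#' @param spike_tol spike-crossing localization tolerance (ms): the time
#'   at which V crosses `V_peak` is bisected to within this value.
#' @param max_steps step budget per simulation; exceeding it raises an
#'   integration error (which fitness evaluation converts into the
#'   sentinel score). Guards against pathological parameter draws with
#'   sub-microsecond membrane time constants.
#' @return A list of class `solver_config`.
#' @export
solver_config <- function(rtol = 1e-8, atol = 1e-10, h_max = 0.1,
                          h_min = 1e-7, spike_tol = 1e-4, max_steps = 2e7) {
  stopifnot(rtol > 0, atol > 0, h_max > 0, h_min > 0, h_min < h_max,
            spike_tol > 0, max_steps >= 1000)
  structure(list(rtol = rtol, atol = atol, h_max = h_max, h_min = h_min,
                 spike_tol = spike_tol, max_steps = max_steps),
            class = "solver_config")
}

#' Simulate an AdEx neuron under a stimulation protocol
#'
#' Integrates the two-variable AdEx system from rest (`V = E_L`, `w = 0`)
#' with an embedded adaptive Runge-Kutta-Fehlberg 4(5) stepper. When the
#' membrane potential crosses `V_peak` within a trial step, the crossing
#' time is localized by bisection (to `spike_tol`), recorded as a spike,
#' the potential is reset to `V_r`, the adaptation current incremented by
#' `b`, and the potential held at `V_r` for the 1-ms refractory period
#' while `w` continues to relax. In both right-hand sides the potential is
#' read as `min(V, V_peak)` and the exponential argument is capped at +30
#' -- the standard guards that keep the spike upswing numerically benign.
#'
#' @param params an [adex_parameters()] object.
#' @param protocol a [step_protocol()], [sinusoid_protocol()] or
#'   [zero_protocol()].
#' @param solver a [solver_config()].
#' @param record_dt trace sampling interval (ms); `0` records no trace
#'   (spike times only), which is what the feature extractors need.
#' @return An object of class `adex_sim` with elements `spikes` (ms,
#'   strictly increasing), `trace` (data.frame `time_ms`, `V_mV`, `w_pA`,
#'   or NULL), `params`, `protocol` and solver `diagnostics`.
#' @export
#' @examples
#' p <- published_individual("FF4")
#' sim <- adex_simulate(p, step_protocol(16))
#' length(sim$spikes)  # spikes in 1 s
adex_simulate <- function(params, protocol, solver = solver_config(),
                          record_dt = 0) {
  stopifnot(inherits(params, "adex_parameters"),
            inherits(protocol, "stim_protocol"),
            inherits(solver, "solver_config"))
  if (protocol$t_total < 0) stop("total time must be >= 0", call. = FALSE)
  if (protocol$t_total == 0) {
    return(structure(list(
      spikes = numeric(0),
      trace = data.frame(time_ms = 0, V_mV = params$E_L, w_pA = 0),
      params = params, protocol = protocol,
      diagnostics = list(n_accepted = 0, n_rejected = 0, n_min_step = 0)),
      class = "adex_sim"))
  }
  pvec <- unlist(params)
  res <- adex_rkf45_cpp(pvec, unclass(protocol), protocol$t_total,
                        solver$rtol, solver$atol, solver$h_max,
                        solver$h_min, solver$spike_tol, record_dt,
                        solver$max_steps)
  trace <- NULL
  if (record_dt > 0) {
    trace <- data.frame(time_ms = res$time, V_mV = res$V, w_pA = res$w)
  }
  structure(list(spikes = res$spikes, trace = trace, params = params,
                 protocol = protocol,
                 diagnostics = list(n_accepted = res$n_accepted,
                                    n_rejected = res$n_rejected,
                                    n_min_step = res$n_min_step)),
            class = "adex_sim")
}

#' @export
print.adex_sim <- function(x, ...) {
  cat(sprintf("AdEx simulation: %d spikes over %g ms (%s)\n",
              length(x$spikes), x$protocol$t_total, x$protocol$kind))
  invisible(x)
}

#' Fixed-step RK4 reference integration
#'
#' A deliberately simple fixed-step fourth-order Runge-Kutta integration
#' of the same model, with spike crossings located by linear interpolation
#' inside the grid step. Used as an independent cross-check of the
#' adaptive production integrator; not intended for routine use.
#'
#' @inheritParams adex_simulate
#' @param dt fixed step size (ms).
#' @return A list with `spikes` (ms), `V_final` and `w_final`.
#' @export
adex_simulate_rk4 <- function(params, protocol, dt = 0.001) {
  stopifnot(inherits(params, "adex_parameters"),
            inherits(protocol, "stim_protocol"), dt > 0)
  adex_rk4_cpp(unlist(params), unclass(protocol), protocol$t_total, dt)
}

#' Export simulation results to CSV / JSON
#'
#' `write_trace_csv()` writes the sampled trace with columns
#' `time_ms, V_mV, w_pA`; `write_spikes_csv()` writes spike times as a
#' one-column CSV; `sim_to_json()` serializes both to a JSON string or
#' file.
#'
#' @param sim an `adex_sim` with a recorded trace (for the trace writer).
#' @param path output file path.
#' @return The path (writers, invisibly) or a JSON string.
#' @export
write_trace_csv <- function(sim, path) {
  if (is.null(sim$trace)) {
    stop("simulation has no recorded trace; rerun with record_dt > 0",
         call. = FALSE)
  }
  utils::write.csv(sim$trace, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
write_spikes_csv <- function(sim, path) {
  utils::write.csv(data.frame(spike_time_ms = sim$spikes), path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
sim_to_json <- function(sim, path = NULL) {
  obj <- list(spikes_ms = sim$spikes,
              trace = sim$trace,
              protocol = unclass(sim$protocol),
              parameters = as.list(params_to_genes(sim$params)))
  if (is.null(path)) {
    jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
    invisible(path)
  }
}

#' AdEx right-hand sides
#'
#' Evaluates the instantaneous derivatives (dV/dt, dw/dt) of the AdEx
#' system at a given state and current, in mV/ms and pA/ms. Applies the
#' same `min(V, V_peak)` state read and +30 exponential-argument cap as
#' the integrator.
#'
#' @param params an [adex_parameters()] object.
#' @param V membrane potential (mV).
#' @param w adaptation current (pA).
#' @param I injected current (pA).
#' @return Named numeric vector `c(dV = ..., dw = ...)`.
#' @export
adex_derivatives <- function(params, V, w, I = 0) {
  if (!all(is.finite(c(V, w, I)))) {
    stop("state and current must be finite", call. = FALSE)
  }
  Vc <- min(V, params$V_peak)
  arg <- min((Vc - params$V_T) / params$Delta_T, 30)
  dV <- (-params$g_L * (Vc - params$E_L) +
           params$g_L * params$Delta_T * exp(arg) + I - w) / params$C_m
  dw <- (params$a * (Vc - params$E_L) - w) / params$tau_w
  c(dV = dV, dw = dw)
}
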