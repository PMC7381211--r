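#' AdEx model parameters
#'
#' Constructs a validated parameter set for the adaptive exponential
#' integrate-and-fire (AdEx) point-neuron model
#' \deqn{C_m \frac{dV}{dt} = -g_L (V - E_L) + g_L \Delta_T
#'       e^{(V - V_T)/\Delta_T} + I(t) - w}
#' \deqn{\tau_w \frac{dw}{dt} = a (V - E_L) - w}
#' with spike emission when \eqn{V} crosses \eqn{V_{peak}} (reset to
#' \eqn{V_r}, \eqn{w \leftarrow w + b}) and a fixed 1-ms refractory period.
#' The unit system is pF / nS / mV / ms / pA throughout, so the membrane
#' time constant \eqn{\tau_m = C_m / g_L} is in ms and the adaptation
#' current \eqn{w} shares units (pA) with the injected current and with
#' the spike-triggered increment \code{b}.
#'
#' The membrane potential is initialised at \code{E_L} and the adaptation
#' current at 0 in every simulation.
#'
#' @param C_m membrane capacitance (pF)
#' @param g_L leak conductance (nS)
#' @param E_L leak reversal potential (mV); also the initial potential
#' @param Delta_T spike-initiation slope factor (mV)
#' @param V_T exponential-threshold potential (mV)
#' @param V_peak spike-detection potential (mV); crossing it triggers reset
#' @param V_r post-spike reset potential (mV)
#' @param a subthreshold adaptation conductance (nS)
#' @param b spike-triggered adaptation increment (pA)
#' @param tau_w adaptation time constant (ms)
#'
#' @return An object of class `adex_parameters`: a named list of the ten
#'   tunable constants plus the fixed refractory period `tau_ref = 1` ms.
#' @seealso [published_individual()] for the bundled reference models,
#'   [parameter_bounds()] for the optimization search box.
#' @export
#' @examples
#' p <- published_individual("FF4")
#' p$tau_w
adex_parameters <- function(C_m, g_L, E_L, Delta_T, V_T, V_peak, V_r,
                            a, b, tau_w) {
  p <- list(C_m = C_m, g_L = g_L, E_L = E_L, Delta_T = Delta_T, V_T = V_T,
            V_peak = V_peak, V_r = V_r, a = a, b = b, tau_w = tau_w,
            tau_ref = 1)
  vals <- unlist(p)
  if (!all(is.finite(vals))) {
    stop("all AdEx parameters must be finite numbers", call. = FALSE)
  }
  for (nm in c("C_m", "g_L", "Delta_T", "tau_w")) {
    if (p[[nm]] <= 0) stop(sprintf("'%s' must be > 0", nm), call. = FALSE)
  }
  class(p) <- "adex_parameters"
  p
}

#' @export
print.adex_parameters <- function(x, ...) {
  cat("AdEx parameter set (pF/nS/mV/ms/pA units)\n")
  v <- unlist(x[param_names()])
  print(round(v, 4))
  invisible(x)
}

#' @export
format.adex_parameters <- function(x, ...) {
  paste0(param_names(), " = ", vapply(x[param_names()], format, ""),
         collapse = ", ")
}

#' Names of the ten tunable AdEx parameters
#'
#' The fixed gene/column ordering used by the optimizer and by parameter
#' files.
#'
#' @return Character vector of length 10.
#' @export
param_names <- function() {
  c("C_m", "Delta_T", "E_L", "V_peak", "V_r", "V_T", "a", "b", "g_L", "tau_w")
}

#' Search-box bounds for the tunable parameters
#'
#' The closed interval for each parameter inside which the evolutionary
#' search operates. Defaults are the published optimization boundaries for
#' the granule-cell fitting problem.
#'
#' @param ... optional `name = c(lo, hi)` overrides for individual
#'   parameters.
#' @return An object of class `adex_bounds`: a named list of length-2
#'   numeric vectors in [param_names()] order.
#' @export
#' @examples
#' b <- parameter_bounds()
#' b$C_m
parameter_bounds <- function(...) {
  b <- list(
    C_m     = c(0.1, 5.0),    # pF
    Delta_T = c(1, 1000),     # mV
    E_L     = c(-80, -40),    # mV
    V_peak  = c(-20, 20),     # mV
    V_r     = c(-80, -40),    # mV
    V_T     = c(-60, -20),    # mV
    a       = c(-1, 1),       # nS
    b       = c(-1, 1),       # pA
    g_L     = c(0.001, 10.0), # nS
    tau_w   = c(1, 1000)      # ms
  )
  dots <- list(...)
  for (nm in names(dots)) {
    if (!nm %in% names(b)) stop("unknown parameter: ", nm, call. = FALSE)
    b[[nm]] <- as.numeric(dots[[nm]])
  }
  for (nm in names(b)) {
    iv <- b[[nm]]
    if (length(iv) != 2 || !all(is.finite(iv)) || iv[1] >= iv[2]) {
      stop(sprintf("bounds for '%s' must be a finite interval [lo, hi], lo < hi", nm),
           call. = FALSE)
    }
  }
  structure(b, class = "adex_bounds")
}

#' Check a parameter set against bounds
#'
#' @param params an [adex_parameters()] object.
#' @param bounds an [parameter_bounds()] object.
#' @return Logical: `TRUE` when every tunable parameter lies inside its
#'   closed interval.
#' @export
params_within_bounds <- function(params, bounds = parameter_bounds()) {
  all(vapply(param_names(), function(nm) {
    v <- params[[nm]]
    v >= bounds[[nm]][1] && v <= bounds[[nm]][2]
  }, logical(1)))
}

#' Convert between parameter objects and bare gene vectors
#'
#' The optimizer works on unnamed numeric vectors in [param_names()]
#' order; these helpers translate both ways.
#'
#' @param genes numeric vector of length 10 in [param_names()] order.
#' @return `genes_to_params()` returns an [adex_parameters()] object;
#'   `params_to_genes()` a named numeric vector of length 10.
#' @export
genes_to_params <- function(genes) {
  stopifnot(length(genes) == 10)
  g <- as.numeric(genes)
  names(g) <- param_names()
  adex_parameters(C_m = g[["C_m"]], g_L = g[["g_L"]], E_L = g[["E_L"]],
                  Delta_T = g[["Delta_T"]], V_T = g[["V_T"]],
                  V_peak = g[["V_peak"]], V_r = g[["V_r"]], a = g[["a"]],
                  b = g[["b"]], tau_w = g[["tau_w"]])
}

#' @rdname genes_to_params
#' @param params an [adex_parameters()] object.
#' @export
params_to_genes <- function(params) {
  unlist(params[param_names()])
}

#' Read and write parameter files
#'
#' Parameter sets are stored as flat key-value files (JSON, or YAML when
#' the yaml package is available), keyed by the standard symbol names
#' `C_m, g_L, E_L, Delta_T, V_T, V_peak, V_r, a, b, tau_w`.
#'
#' @param path file path; format chosen by extension (`.json`, `.yaml`/`.yml`).
#' @return `read_parameters()` returns an [adex_parameters()] object;
#'   `write_parameters()` returns `path` invisibly.
#' @export
read_parameters <- function(path) {
  vals <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML parameter files requires the 'yaml' package",
           call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  missing <- setdiff(param_names(), names(vals))
  if (length(missing)) {
    stop("parameter file is missing: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  do.call(adex_parameters, lapply(
    stats::setNames(param_names(), param_names()),
    function(nm) as.numeric(vals[[nm]])))
}

#' @rdname read_parameters
#' @param params an [adex_parameters()] object to serialize.
#' @export
write_parameters <- function(params, path) {
  vals <- as.list(params_to_genes(params))
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("writing YAML parameter files requires the 'yaml' package",
           call. = FALSE)
    }
    yaml::write_yaml(vals, path)
  } else {
    jsonlite::write_json(vals, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
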