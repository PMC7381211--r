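ref_csv <- function(name) {
  path <- system.file("extdata", name, package = "adexfit")
  if (path == "") path <- file.path("inst", "extdata", name) # load_all fallback
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Published reference models
#'
#' Loads one of the four published best-fit granule-cell AdEx parameter
#' sets, named after the fitness function that produced it: `"FF1"`
#' (bursts only), `"FF2"` (bursts + mean step-current frequency), `"FF3"`
#' (bursts + first-spike latency), `"FF4"` (all three feature families).
#'
#' @param id one of `"FF1"`, `"FF2"`, `"FF3"`, `"FF4"`.
#' @return An [adex_parameters()] object.
#' @export
#' @examples
#' published_individual("FF1")$C_m   # 3.10 pF
published_individual <- function(id) {
  tab <- ref_csv("reference_parameters.csv")
  if (!is.character(id) || length(id) != 1 || !id %in% names(tab)[-1]) {
    stop("unknown reference model id: ", paste(id, collapse = ", "),
         "; expected one of ", paste(names(tab)[-1], collapse = ", "),
         call. = FALSE)
  }
  genes <- stats::setNames(tab[[id]], tab$parameter)
  genes_to_params(genes[param_names()])
}

#' Experimental feature targets
#'
#' The bundled experimental target table used by the fitness functions:
#' 14 burst-frequency values under sinusoidal stimulation (6 at 6-pA and
#' 8 at 8-pA amplitude, 12-pA offset), and mean firing frequency plus
#' first-spike latency under 10/16/22-pA 1-s steps. Default weights are 1
#' for the Hz-valued features and 1000 for the latency, which is scored in
#' seconds (so a 1-ms lag weighs like a 1-Hz error).
#'
#' @return A data.frame with columns `feature`
#'   (`burst`/`mean_frequency`/`latency`), `amplitude_pA`, `frequency_Hz`
#'   (NA for steps), `exp` (target value, Hz or ms), `weight`.
#' @export
experimental_targets <- function() {
  tab <- ref_csv("experimental_targets.csv")
  data.frame(feature = tab$feature,
             amplitude_pA = tab$amplitude_pA,
             frequency_Hz = tab$frequency_Hz,
             exp = tab$value,
             weight = ifelse(tab$feature == "latency", 1000, 1))
}

#' Published simulated feature values of the reference models
#'
#' The feature table reported for the four reference models (burst
#' frequencies, mean frequencies, latencies), for cross-checking a
#' reproduced feature table cell for cell.
#'
#' @return A data.frame with columns `feature`, `amplitude_pA`,
#'   `frequency_Hz`, `FF1` ... `FF4`.
#' @export
reference_features <- function() {
  ref_csv("reference_features.csv")
}

#' Generate synthetic feature targets from a known parameter set
#'
#' Simulates every protocol demanded by a fitness specification with the
#' given parameters and emits the measured features as a target table with
#' default weights. By construction the generating parameter set scores
#' ~0 against these targets (up to the SD penalty), which is what the
#' optimizer-recovery tests exploit.
#'
#' @param params an [adex_parameters()] object (within bounds).
#' @param spec a [fitness_spec()].
#' @param solver a [solver_config()].
#' @return A target data.frame in the [experimental_targets()] layout.
#' @export
make_synthetic_target <- function(params, spec, solver = solver_config()) {
  feats <- simulate_features(params, spec, solver = solver)
  data.frame(feature = feats$feature,
             amplitude_pA = feats$amplitude_pA,
             frequency_Hz = feats$frequency_Hz,
             exp = feats$value,
             weight = ifelse(feats$feature == "latency", 1000, 1))
}
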