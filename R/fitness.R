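#' Fitness-function specification
#'
#' Defines which feature families a fitness function scores and how the
#' burst component is measured. The four standard combinations are:
#' `FF1` bursts only; `FF2` bursts + mean step-current frequency; `FF3`
#' bursts + first-spike latency; `FF4` all three. All four default to the
#' stabilized 10-cycle burst window with the standard-deviation penalty
#' (each burst term multiplied by `sd + 1`), which preferentially selects
#' models whose cycle-to-cycle burst frequency is stable. The plain
#' unpenalized score and the initial-cycles window remain available to
#' reproduce the four measurement-strategy variants (initial cycles,
#' initial cycles + SD, stabilization, stabilization + SD).
#'
#' @param id `"FF1"`, `"FF2"`, `"FF3"`, `"FF4"`, or `"custom"`.
#' @param features feature families to score; subset of
#'   `c("burst", "mean_frequency", "latency")`. Chosen by `id` unless
#'   given explicitly.
#' @param burst_mode burst measurement window, `"stabilized"` or
#'   `"initial"`.
#' @param sd_penalty logical; multiply each burst error by (per-condition
#'   burst-frequency SD + 1).
#' @param targets target table in the [experimental_targets()] layout.
#' @param anchor,zero_rule cycle-window conventions, see
#'   [average_burst_frequency()].
#' @return A list of class `fitness_spec`.
#' @export
#' @examples
#' fitness_spec("FF4")
fitness_spec <- function(id = c("FF1", "FF2", "FF3", "FF4", "custom"),
                         features = NULL,
                         burst_mode = "stabilized",
                         sd_penalty = TRUE,
                         targets = experimental_targets(),
                         anchor = "trough",
                         zero_rule = "per_cycle") {
  id <- match.arg(id)
  if (is.null(features)) {
    features <- switch(id,
      FF1 = "burst",
      FF2 = c("burst", "mean_frequency"),
      FF3 = c("burst", "latency"),
      FF4 = c("burst", "mean_frequency", "latency"),
      custom = stop("'custom' spec needs an explicit 'features' argument",
                    call. = FALSE))
  }
  stopifnot(all(features %in% c("burst", "mean_frequency", "latency")))
  targets <- targets[targets$feature %in% features, , drop = FALSE]
  if (!nrow(targets)) stop("no targets left for the requested features",
                           call. = FALSE)
  if (any(targets$weight <= 0)) stop("target weights must be > 0",
                                     call. = FALSE)
  structure(list(id = id, features = features, burst_mode = burst_mode,
                 sd_penalty = sd_penalty, targets = targets,
                 anchor = anchor, zero_rule = zero_rule),
            class = "fitness_spec")
}

#' @export
print.fitness_spec <- function(x, ...) {
  cat(sprintf("Fitness spec %s: %s; %s burst window%s; %d targets\n",
              x$id, paste(x$features, collapse = " + "), x$burst_mode,
              if (x$sd_penalty) " with SD penalty" else "",
              nrow(x$targets)))
  invisible(x)
}

#' Measure all features a fitness specification demands
#'
#' Runs one simulation per target condition (a sinusoidal protocol per
#' burst condition, a 1-s step per step amplitude) and returns the
#' measured feature values. Sinusoidal simulations are run for the
#' shortest duration containing the measured cycles; the measured windows
#' are identical to those of the full-length stimulation.
#'
#' A silent step response yields mean frequency 0 and, as the latency
#' penalty, a latency equal to the stimulus duration.
#'
#' @param params an [adex_parameters()] object.
#' @param spec a [fitness_spec()].
#' @param solver a [solver_config()].
#' @return A data.frame with columns `feature`, `amplitude_pA`,
#'   `frequency_Hz`, `value`, `sd` (burst rows only; NA otherwise).
#' @export
simulate_features <- function(params, spec, solver = solver_config()) {
  tg <- spec$targets
  out <- vector("list", 0)

  bt <- tg[tg$feature == "burst", , drop = FALSE]
  if (nrow(bt)) {
    mode <- if (spec$burst_mode == "stabilized") "stabilized" else "initial"
    for (i in seq_len(nrow(bt))) {
      f <- bt$frequency_Hz[i]
      sim <- adex_simulate(params, sinusoid_protocol(
        bt$amplitude_pA[i], frequency = f,
        duration = burst_duration_needed(f, mode)), solver = solver)
      bm <- average_burst_frequency(sim, mode = mode, anchor = spec$anchor,
                                    zero_rule = spec$zero_rule)
      out[[length(out) + 1]] <- data.frame(
        feature = "burst", amplitude_pA = bt$amplitude_pA[i],
        frequency_Hz = f, value = bm$mean, sd = bm$sd)
    }
  }

  step_amps <- unique(tg$amplitude_pA[tg$feature != "burst"])
  for (amp in step_amps) {
    sr <- step_response(params, amp, solver = solver)
    if (any(tg$feature == "mean_frequency" & tg$amplitude_pA == amp)) {
      out[[length(out) + 1]] <- data.frame(
        feature = "mean_frequency", amplitude_pA = amp,
        frequency_Hz = NA_real_, value = sr$mean_frequency_Hz, sd = NA_real_)
    }
    if (any(tg$feature == "latency" & tg$amplitude_pA == amp)) {
      lat <- if (is.na(sr$latency_ms)) 1000 else sr$latency_ms
      out[[length(out) + 1]] <- data.frame(
        feature = "latency", amplitude_pA = amp,
        frequency_Hz = NA_real_, value = lat, sd = NA_real_)
    }
  }
  do.call(rbind, out)
}

match_targets <- function(features, targets) {
  key <- function(d) paste(d$feature, d$amplitude_pA,
                           ifelse(is.na(d$frequency_Hz), "-", d$frequency_Hz))
  idx <- match(key(targets), key(features))
  if (anyNA(idx)) {
    stop("missing simulated feature for target condition(s): ",
         paste(key(targets)[is.na(idx)], collapse = "; "), call. = FALSE)
  }
  idx
}

#' Weighted absolute-error feature score
#'
#' The plain fitness score: the sum over targets of
#' `|feat_i - exp_i| * w_i`. Hz-valued features are scored in Hz;
#' latencies are converted to seconds before applying their weight of
#' 1000, so a 1-ms lag contributes 1.0 like a 1-Hz error.
#'
#' @param features a data.frame from [simulate_features()].
#' @param targets a target data.frame ([experimental_targets()] layout).
#' @return Non-negative scalar score.
#' @export
score_features <- function(features, targets) {
  idx <- match_targets(features, targets)
  sim <- features$value[idx]
  exp_v <- targets$exp
  err <- abs(sim - exp_v)
  is_lat <- targets$feature == "latency"
  err[is_lat] <- err[is_lat] / 1000  # ms -> s; weight 1000 restores scale
  sum(err * targets$weight)
}

#' SD-penalized burst score
#'
#' The burst-frequency score with the cycle-to-cycle instability penalty:
#' the sum over the burst conditions of
#' `|mean_sim_j - exp_j| * w_BF * (sd_sim_j + 1)`. With all SDs zero it
#' reduces exactly to the plain weighted absolute-error score.
#'
#' @param features a data.frame from [simulate_features()] (burst rows
#'   carry the per-condition SD).
#' @param targets burst rows of a target table.
#' @return Non-negative scalar score.
#' @export
score_bursts_sd <- function(features, targets) {
  targets <- targets[targets$feature == "burst", , drop = FALSE]
  if (!nrow(targets)) return(0)
  idx <- match_targets(features, targets)
  sum(abs(features$value[idx] - targets$exp) * targets$weight *
        (features$sd[idx] + 1))
}

#' Score a parameter set against a fitness specification
#'
#' Simulates every protocol the specification demands, extracts the
#' features and composes the fitness score: the burst block scored with
#' the SD penalty when `spec$sd_penalty` is set (plain otherwise), and the
#' step-current blocks with the plain weighted absolute error.
#' Out-of-bounds parameters and failed simulations receive a large finite
#' sentinel score (ten times the all-silent score) so tournament
#' comparisons remain well defined.
#'
#' @param params an [adex_parameters()] object (or a 10-gene vector).
#' @param spec a [fitness_spec()].
#' @param solver a [solver_config()].
#' @param bounds a [parameter_bounds()] box for the validity check, or
#'   `NULL` to skip it.
#' @return A list: `score` (scalar), `features` (data.frame or NULL when
#'   sentinel-scored), `sentinel` (logical).
#' @export
#' @examples
#' \donttest{
#' res <- evaluate_individual(published_individual("FF1"), fitness_spec("FF1"))
#' res$score
#' }
evaluate_individual <- function(params, spec, solver = solver_config(),
                                bounds = parameter_bounds()) {
  if (is.numeric(params)) params <- genes_to_params(params)
  sentinel <- 10 * silent_score(spec)
  if (!is.null(bounds) && !params_within_bounds(params, bounds)) {
    return(list(score = sentinel, features = NULL, sentinel = TRUE))
  }
  feats <- tryCatch(simulate_features(params, spec, solver = solver),
                    error = function(e) NULL)
  if (is.null(feats) || anyNA(feats$value)) {
    return(list(score = sentinel, features = feats, sentinel = TRUE))
  }
  tg <- spec$targets
  burst_tg <- tg[tg$feature == "burst", , drop = FALSE]
  other_tg <- tg[tg$feature != "burst", , drop = FALSE]
  score <- 0
  if (nrow(burst_tg)) {
    score <- score + if (spec$sd_penalty) {
      score_bursts_sd(feats, burst_tg)
    } else {
      score_features(feats, burst_tg)
    }
  }
  if (nrow(other_tg)) score <- score + score_features(feats, other_tg)
  list(score = score, features = feats, sentinel = FALSE)
}

# fitness score of a neuron that never spikes: every burst and mean
# frequency reads 0, every latency takes the 1-s penalty value
silent_score <- function(spec) {
  tg <- spec$targets
  err <- abs(tg$exp)
  is_lat <- tg$feature == "latency"
  err[is_lat] <- abs(1000 - tg$exp[is_lat]) / 1000
  sum(err * tg$weight)
}
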