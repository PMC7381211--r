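#' Recompute the full feature table of the reference models
#'
#' Simulates each requested reference model under every bundled target
#' condition — the 14 sinusoidal burst conditions (10-cycle stabilized
#' average) and the three 1-s step currents (mean frequency and
#' first-spike latency) — and returns the feature table in the layout of
#' [reference_features()], enabling cell-for-cell comparison with the
#' published values.
#'
#' @param models character vector of reference-model ids.
#' @param solver a [solver_config()].
#' @return A data.frame with columns `feature`, `amplitude_pA`,
#'   `frequency_Hz` and one column per model.
#' @export
#' @examples
#' \donttest{
#' tab <- reproduce_feature_table("FF1")
#' head(tab)
#' }
reproduce_feature_table <- function(models = c("FF1", "FF2", "FF3", "FF4"),
                                    solver = solver_config()) {
  spec <- fitness_spec("FF4")  # all three feature families
  layout <- NULL
  cols <- list()
  for (id in models) {
    feats <- simulate_features(published_individual(id), spec,
                               solver = solver)
    if (is.null(layout)) {
      layout <- feats[c("feature", "amplitude_pA", "frequency_Hz")]
    }
    cols[[id]] <- feats$value
  }
  cbind(layout, as.data.frame(cols))
}

#' Compare a reproduced feature table with the published values
#'
#' Joins a [reproduce_feature_table()] output with the published feature
#' table and reports, per cell, the absolute deviation and whether it
#' falls within the standard reproduction tolerances: burst frequencies
#' within the larger of 2 Hz and 5 %, mean frequencies within 3 Hz,
#' latencies within 20 %.
#'
#' @param reproduced output of [reproduce_feature_table()].
#' @param reference published table, by default [reference_features()].
#' @return A long-format data.frame with columns `model`, `feature`,
#'   `amplitude_pA`, `frequency_Hz`, `simulated`, `published`,
#'   `deviation`, `tolerance`, `within`.
#' @export
compare_feature_tables <- function(reproduced,
                                   reference = reference_features()) {
  models <- intersect(names(reproduced),
                      setdiff(names(reference),
                              c("feature", "amplitude_pA", "frequency_Hz")))
  key <- function(d) paste(d$feature, d$amplitude_pA,
                           ifelse(is.na(d$frequency_Hz), "-", d$frequency_Hz))
  idx <- match(key(reproduced), key(reference))
  out <- list()
  for (id in models) {
    sim <- reproduced[[id]]
    pub <- reference[[id]][idx]
    tol <- ifelse(reproduced$feature == "burst", pmax(2, 0.05 * pub),
           ifelse(reproduced$feature == "mean_frequency", 3, 0.20 * pub))
    out[[id]] <- data.frame(model = id,
                            feature = reproduced$feature,
                            amplitude_pA = reproduced$amplitude_pA,
                            frequency_Hz = reproduced$frequency_Hz,
                            simulated = sim, published = pub,
                            deviation = abs(sim - pub), tolerance = tol,
                            within = abs(sim - pub) <= tol)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
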