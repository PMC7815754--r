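#' Preset study regimes for validation experiments
#'
#' Named parameterisations of [simulation_config()] that put the generator
#' into the ecological regimes the inference pipeline is validated against.
#' Each preset states its expected downstream signature:
#'
#' * `"succession"` — the default hatch/transition design: selection
#'   strengths (0.3, 0.6, 0.8) across stages S1-S3; homogeneous selection
#'   should increase with developmental stage.
#' * `"neutral"` — no selection, one shared well-mixed pool, strong mass
#'   effects (all lineages exchanged): the selection fraction of pairs
#'   should stay at the nominal false-positive level and homogenizing
#'   dispersal is the expected modal non-undominated process.
#' * `"dispersal_limited"` — no selection, each cage restricted to a random
#'   30% subset of the pool with free within-cage exchange: dispersal
#'   limitation should be the modal non-undominated process.
#' * `"selection_gradient"` — the succession design with one flat selection
#'   strength `s` at every stage (for parameter-recovery sweeps over `s`).
#' * `"similarity_calibration"` — one shared pool and abundance-weighted
#'   colonization, so that under `s = 0` the assembly process matches the
#'   richness- and abundance-constrained null of [selection_strength()];
#'   with `s > 0` observed within-stage similarity exceeds the null. Used
#'   to validate the deterministic-ratio statistic.
#'
#' @param regime preset name.
#' @param s flat selection strength for `"selection_gradient"` and
#'   `"similarity_calibration"` (default 0).
#' @param ... overrides passed on to [simulation_config()]
#'   (e.g. `n_otus`, `depth`, `replicates`, `dph_schedule`, `seed`).
#' @return A [simulation_config()].
#' @export
regime_config <- function(regime = c("succession", "neutral",
                                     "dispersal_limited",
                                     "selection_gradient",
                                     "similarity_calibration"),
                          s = 0, ...) {
  regime <- match.arg(regime)
  flat <- c(S1 = s, S2 = s, S3 = s)
  args <- switch(regime,
    succession = list(),
    neutral = list(selection_strength_by_stage = c(S1 = 0, S2 = 0, S3 = 0),
                   env_pool_mode = "shared", host_capacity = Inf,
                   dispersal_rate = 0.7, immigrant_richness = Inf),
    dispersal_limited = list(selection_strength_by_stage = c(S1 = 0, S2 = 0, S3 = 0),
                             cage_pool_frac = 0.3, host_capacity = Inf),
    selection_gradient = list(selection_strength_by_stage = flat),
    similarity_calibration = list(selection_strength_by_stage = flat,
                                  env_pool_mode = "shared",
                                  colonization_exp = 1, abundance_exp = 1,
                                  host_drift_sd = 0.3))
  do.call(simulation_config, utils::modifyList(args, list(...)))
}
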