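#' Planted per-class effect table
#'
#' Builds the long table of planted effects used by [simulate_apms()]: one
#' row per (binder class, bait condition, treatment) giving the slope `beta`
#' of the prey on the bait log2 fluctuation and the mean log2 enrichment
#' `delta` over the empty-vector control. Background preys (and every prey in
#' EV samples) implicitly have `beta = 0`, `delta = 0`.
#'
#' Defaults encode the study conditions: every binder tracks the bait with
#' unit slope; shared binders are enriched by 2 log2 units in all three bait
#' conditions; preference-class binders get 2.5 in their preferred condition
#' and 1.5 elsewhere (a 1 log2-unit preference difference); module members
#' behave as shared low-level binders (1.5) except in ALT under oxidative
#' stress, where they rise to 2.5. Preference is carried entirely by `delta`
#' so that the single-slope bait regression remains exactly well specified
#' and slope recovery is meaningful.
#'
#' @param beta Slope of prey log2 abundance on the bait log2 fluctuation,
#'   applied to every binder class in every bait condition.
#' @param delta_shared Enrichment over EV (log2) for shared binders.
#' @param delta_pref,delta_base Enrichment in the preferred / non-preferred
#'   condition for preference-class binders.
#' @param delta_module_stress Enrichment of module members in ALT under
#'   oxidative treatment.
#' @param treatments Treatments to include.
#' @return data.frame with columns `class`, `condition`, `treatment`,
#'   `beta`, `delta`.
#' @export
default_effects <- function(beta = 1,
                            delta_shared = 2,
                            delta_pref = 2.5,
                            delta_base = 1.5,
                            delta_module_stress = 2.5,
                            treatments = apms_treatments) {
  classes <- apms_binder_classes
  grid <- expand.grid(
    class = classes,
    condition = apms_bait_conditions,
    treatment = treatments,
    KEEP.OUT.ATTRS = FALSE,
    stringsAsFactors = FALSE
  )
  delta <- rep(delta_base, nrow(grid))
  delta[grid$class == "binder_shared"] <- delta_shared
  pref_cond <- c(binder_WT_pref = "WT", binder_ALT_pref = "ALT",
                 binder_NLS_pref = "NLS")
  is_pref <- grid$class %in% names(pref_cond) &
    grid$condition == pref_cond[grid$class]
  delta[is_pref] <- delta_pref
  delta[grid$class == "module_member" & grid$condition == "ALT" &
          grid$treatment == "oxidative"] <- delta_module_stress
  grid$beta <- beta
  grid$delta <- delta
  grid
}

apms_binder_classes <- c("binder_shared", "binder_WT_pref",
                         "binder_ALT_pref", "binder_NLS_pref",
                         "module_member")

#' Simulation parameters
#'
#' Constructs and validates the parameter set of the synthetic AP-MS
#' generator. All log2-scale quantities are in log2 reporter-intensity
#' units; `detection_limit` is on the linear intensity scale.
#'
#' @param n_proteins Total number of proteins including the bait row.
#' @param n_binders_per_class Number of planted binders in each of the five
#'   binder classes (shared, WT-, ALT-, NLS-preferring, module members).
#' @param n_replicates Default number of replicate batches when the pipeline
#'   builds its own design.
#' @param baseline_log2_mean,baseline_log2_sd Mean and SD of the per-protein
#'   baseline log2 abundance.
#' @param bait_log2_mean Mean log2 level of the immunoprecipitated bait.
#' @param bait_efficiency_sd SD of the per-sample bait log2 pulldown
#'   (models variable IP efficiency across samples and variants).
#' @param effects Planted effect table, see [default_effects()].
#' @param noise_sd SD of the per-measurement log2 noise.
#' @param batch_effect_sd SD of the per-protein, per-batch log2 offset.
#' @param ev_background_log2 Residual bait-scale log2 signal in EV samples.
#' @param detection_limit Linear-scale intensity below which a measurement
#'   is reported missing. Use 0 (or `-Inf`) to disable.
#' @param module_set_name Name of the planted gene set.
#' @param seed Integer seed for the generator's single pseudo-random stream.
#' @return An object of class `apms_sim_params`.
#' @export
sim_params <- function(n_proteins = 2000,
                       n_binders_per_class = 200,
                       n_replicates = 4,
                       baseline_log2_mean = 10,
                       baseline_log2_sd = 1.5,
                       bait_log2_mean = 12,
                       bait_efficiency_sd = 0.5,
                       effects = default_effects(),
                       noise_sd = 0.3,
                       batch_effect_sd = 0.3,
                       ev_background_log2 = 6,
                       detection_limit = 128,
                       module_set_name = "planted_module",
                       seed = 1) {
  p <- list(
    n_proteins = as.integer(n_proteins),
    n_binders_per_class = as.integer(n_binders_per_class),
    n_replicates = as.integer(n_replicates),
    baseline_log2_mean = baseline_log2_mean,
    baseline_log2_sd = baseline_log2_sd,
    bait_log2_mean = bait_log2_mean,
    bait_efficiency_sd = bait_efficiency_sd,
    effects = effects,
    noise_sd = noise_sd,
    batch_effect_sd = batch_effect_sd,
    ev_background_log2 = ev_background_log2,
    detection_limit = detection_limit,
    module_set_name = as.character(module_set_name),
    seed = as.integer(seed)
  )
  class(p) <- "apms_sim_params"
  validate_sim_params(p)
}

#' @rdname sim_params
#' @param params An `apms_sim_params` object.
#' @export
validate_sim_params <- function(params) {
  if (!inherits(params, "apms_sim_params")) {
    stop("parameter error: not an apms_sim_params object", call. = FALSE)
  }
  sds <- c(baseline_log2_sd = params$baseline_log2_sd,
           bait_efficiency_sd = params$bait_efficiency_sd,
           noise_sd = params$noise_sd,
           batch_effect_sd = params$batch_effect_sd)
  bad <- !is.finite(sds) | sds < 0
  if (any(bad)) {
    stop("parameter error: standard deviations must be finite and >= 0 (",
         paste(names(sds)[bad], collapse = ", "), ")", call. = FALSE)
  }
  n_classes <- length(unique(params$effects$class))
  if (params$n_binders_per_class * n_classes > params$n_proteins - 1) {
    stop("parameter error: n_binders_per_class x number of classes must ",
         "leave room for the bait (<= n_proteins - 1)", call. = FALSE)
  }
  if (params$n_binders_per_class < 0 || params$n_proteins < 2) {
    stop("parameter error: need n_proteins >= 2 and a nonnegative binder ",
         "count", call. = FALSE)
  }
  req <- c("class", "condition", "treatment", "beta", "delta")
  if (!is.data.frame(params$effects) || !all(req %in% names(params$effects))) {
    stop("parameter error: effects must be a data.frame with columns ",
         paste(req, collapse = ", "), call. = FALSE)
  }
  invisible(params)
}
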