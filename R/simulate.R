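#' Simulate an AP-MS abundance matrix with planted ground truth
#'
#' Generates a protein-by-sample reporter-intensity matrix under the
#' generative model the downstream analysis assumes, so that every stage of
#' the pipeline has a known planted answer.
#'
#' For sample \eqn{s}, the bait log2 level is
#' \eqn{B_s = \mu_B + \epsilon_s} with
#' \eqn{\epsilon_s \sim N(0, \sigma_{bait}^2)} in bait conditions and
#' \eqn{B_s} equal to `ev_background_log2` in EV samples (residual
#' background signal). A prey \eqn{p} has log2 intensity
#' \deqn{y_{ps} = \mu_p + \beta_{p,c(s),t(s)} (B_s - \mu_B)
#'   + \delta_{p,c(s),t(s)} + b_{p,batch(s)} + e_{ps},}
#' where \eqn{\mu_p} is the planted baseline, \eqn{\beta} the slope on the
#' bait fluctuation (0 in EV and for background preys), \eqn{\delta} the
#' planted mean enrichment over EV (0 in EV and for background),
#' \eqn{b} a per-protein batch offset and \eqn{e_{ps} \sim N(0, \sigma^2)}.
#' Binders are therefore simultaneously EV-enriched (through \eqn{\delta})
#' and bait-correlated (through \eqn{\beta}), the two signals the pipeline
#' uses. The bait's own row is its log2 level \eqn{B_s} exactly (the bait is
#' treated as precisely quantified; errors-in-variables are out of scope).
#'
#' The matrix is returned on the linear intensity scale
#' (\eqn{2^{y_{ps}}}); values below `detection_limit` are masked missing.
#' A single pseudo-random stream seeded with `params$seed` is used, with a
#' fixed draw order (baselines, bait efficiencies, batch effects, noise), so
#' identical inputs give bit-identical output.
#'
#' @param params An [sim_params()] object.
#' @param design A sample design, see [make_design()].
#' @return A list of class `apms_sim` with elements
#'   \describe{
#'     \item{abundance}{numeric matrix, proteins x samples, linear scale,
#'       `NA` = below detection; the bait row is named `hSFPQ`.}
#'     \item{truth}{list: `proteins` (protein_id, class, baseline_log2),
#'       `effects` (the per-class planted effect table), `module_set`
#'       (ids of planted module members), `module_set_name`, `bait_id`.}
#'     \item{design, params}{the inputs, for provenance.}
#'   }
#' @examples
#' sim <- simulate_apms(sim_params(n_proteins = 50, n_binders_per_class = 5,
#'                                 seed = 7), make_design(2, "untreated"))
#' dim(sim$abundance)
#' @export
simulate_apms <- function(params, design) {
  validate_sim_params(params)
  validate_design(design)

  n_prey <- params$n_proteins - 1L
  n_samples <- nrow(design)
  bait_id <- "hSFPQ"

  cls <- rep("background", n_prey)
  n_per <- params$n_binders_per_class
  classes <- intersect(apms_binder_classes, unique(params$effects$class))
  idx <- 0L
  for (cl in classes) {
    if (n_per > 0L) cls[idx + seq_len(n_per)] <- cl
    idx <- idx + n_per
  }
  prey_ids <- sprintf("P%0*d", nchar(as.character(n_prey)), seq_len(n_prey))

  set.seed(params$seed)
  mu <- stats::rnorm(n_prey, params$baseline_log2_mean,
                     params$baseline_log2_sd)
  is_bait_sample <- design$condition != "EV"
  bait_log2 <- rep(params$ev_background_log2, n_samples)
  bait_log2[is_bait_sample] <- params$bait_log2_mean +
    stats::rnorm(sum(is_bait_sample), 0, params$bait_efficiency_sd)

  batches <- sort(unique(design$replicate_batch))
  batch_fx <- matrix(stats::rnorm(n_prey * length(batches), 0,
                                  params$batch_effect_sd),
                     nrow = n_prey,
                     dimnames = list(NULL, as.character(batches)))
  noise <- matrix(stats::rnorm(n_prey * n_samples, 0, params$noise_sd),
                  nrow = n_prey)

  beta_arr <- effect_lookup(params$effects, "beta")
  delta_arr <- effect_lookup(params$effects, "delta")

  log2_prey <- matrix(NA_real_, n_prey, n_samples)
  for (j in seq_len(n_samples)) {
    cond <- design$condition[j]
    treat <- design$treatment[j]
    beta_j <- beta_arr[cbind(cls, cond, treat)]
    delta_j <- delta_arr[cbind(cls, cond, treat)]
    log2_prey[, j] <- mu + beta_j * (bait_log2[j] - params$bait_log2_mean) +
      delta_j + batch_fx[, as.character(design$replicate_batch[j])] +
      noise[, j]
  }

  log2_all <- rbind(matrix(bait_log2, nrow = 1), log2_prey)
  abundance <- 2^log2_all
  dimnames(abundance) <- list(c(bait_id, prey_ids), design$sample_id)
  if (is.finite(params$detection_limit) && params$detection_limit > 0) {
    abundance[abundance < params$detection_limit] <- NA_real_
  }
  if (all(is.na(abundance[bait_id, ]))) {
    stop("simulation error: the bait row is entirely below the detection ",
         "limit; raise bait_log2_mean or lower detection_limit",
         call. = FALSE)
  }

  truth <- list(
    proteins = data.frame(
      protein_id = c(bait_id, prey_ids),
      class = c("bait", cls),
      baseline_log2 = c(NA_real_, mu),
      stringsAsFactors = FALSE
    ),
    effects = params$effects,
    module_set = prey_ids[cls == "module_member"],
    module_set_name = params$module_set_name,
    bait_id = bait_id
  )
  structure(list(abundance = abundance, truth = truth, design = design,
                 params = params),
            class = "apms_sim")
}

# class x condition x treatment lookup array; 0 for EV, background and any
# combination absent from the effect table
effect_lookup <- function(effects, what) {
  cls <- c(unique(effects$class), "background")
  arr <- array(0,
               dim = c(length(cls), length(apms_conditions),
                       length(apms_treatments)),
               dimnames = list(cls, apms_conditions, apms_treatments))
  arr[cbind(effects$class, effects$condition, effects$treatment)] <-
    effects[[what]]
  arr
}

#' Expand planted effects to one row per prey
#'
#' Joins the per-class effect table to the per-protein class assignment,
#' giving each prey's planted `beta` and `delta` for every (condition,
#' treatment). Background preys get zeros.
#'
#' @param truth The `truth` element of an [simulate_apms()] result.
#' @param treatments Treatments to expand; defaults to those in the effect
#'   table.
#' @return data.frame: `protein_id`, `class`, `condition`, `treatment`,
#'   `beta`, `delta`.
#' @export
planted_effects <- function(truth,
                            treatments = unique(truth$effects$treatment)) {
  prey <- truth$proteins[truth$proteins$class != "bait", ]
  grid <- expand.grid(
    protein_id = prey$protein_id,
    condition = apms_bait_conditions,
    treatment = treatments,
    KEEP.OUT.ATTRS = FALSE,
    stringsAsFactors = FALSE
  )
  grid$class <- prey$class[match(grid$protein_id, prey$protein_id)]
  beta_arr <- effect_lookup(truth$effects, "beta")
  delta_arr <- effect_lookup(truth$effects, "delta")
  key <- cbind(grid$class, grid$condition, grid$treatment)
  grid$beta <- beta_arr[key]
  grid$delta <- delta_arr[key]
  grid[, c("protein_id", "class", "condition", "treatment", "beta", "delta")]
}
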