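#' Evaluate a pipeline run against the planted ground truth
#'
#' Computes recovery metrics for a simulated run:
#' \describe{
#'   \item{ev_sensitivity}{fraction of planted (binder, condition,
#'     treatment) truths with delta > 0 called binders over EV.}
#'   \item{ev_fdr}{fraction of called binders that are planted background.}
#'   \item{slope_rmse}{root-mean-square error of the fitted bait-regression
#'     slope against the planted per-treatment beta, over all fitted preys
#'     whose planted enrichment is condition-constant (the single-line
#'     model holds exactly); `slope_rmse_all` is the same over every fitted
#'     prey, including preference binders whose condition-varying
#'     enrichment inflates the residual.}
#'   \item{selected_size}{size of the correlated-binder subset.}
#'   \item{alt_pref_median_rank_fraction}{median ALT-vs-WT pi rank of
#'     planted ALT-preferring binders, as a fraction of the ranked set.}
#'   \item{module_ora_rank}{rank of the planted module among ALT-vs-WT ORA
#'     terms.}
#'   \item{triple_overlap_fraction}{triple overlap / union of the
#'     three-way binder Venn.}
#' }
#'
#' @param result List returned by [run_apms()] (or the same structure).
#' @param sim The [simulate_apms()] object the run was produced from.
#' @return data.frame with columns `metric`, `treatment`, `value`, `n`.
#' @export
evaluate_run <- function(result, sim) {
  truth <- sim$truth
  eff <- planted_effects(truth)
  rows <- list()
  add <- function(metric, treatment, value, n) {
    rows[[length(rows) + 1]] <<- data.frame(
      metric = metric, treatment = treatment, value = value,
      n = as.integer(n), stringsAsFactors = FALSE)
  }

  for (treat in names(result$enrichment)) {
    enr <- result$enrichment[[treat]]
    key_enr <- paste(enr$protein_id, enr$condition, enr$treatment)
    eff_t <- eff[eff$treatment == treat, ]
    key_eff <- paste(eff_t$protein_id, eff_t$condition, eff_t$treatment)
    planted <- eff_t$delta[match(key_enr, key_eff)]
    is_true <- !is.na(planted) & planted > 0
    called <- enr$is_binder

    # denominator over the planted truth, so preys lost to the observation
    # filter count as missed
    n_pos_truth <- sum(eff_t$delta > 0)
    add("ev_sensitivity", treat, sum(called & is_true) / n_pos_truth,
        n_pos_truth)
    add("ev_fdr", treat,
        if (sum(called) == 0) 0 else mean(!is_true[called]), sum(called))

    fits <- result$regression[[treat]]$fits
    fitted <- !is.na(fits$slope)
    beta_t <- stats::aggregate(beta ~ protein_id, data = eff_t, FUN = mean)
    uniform_beta <- stats::aggregate(
      beta ~ protein_id, data = eff_t,
      FUN = function(b) length(unique(b)) == 1)
    uniform_delta <- stats::aggregate(
      delta ~ protein_id, data = eff_t,
      FUN = function(d) length(unique(d)) == 1)
    planted_beta <- beta_t$beta[match(fits$protein_id, beta_t$protein_id)]
    well_spec <- fitted &
      uniform_beta$beta[match(fits$protein_id, uniform_beta$protein_id)] &
      uniform_delta$delta[match(fits$protein_id, uniform_delta$protein_id)]
    err_all <- fits$slope[fitted] - planted_beta[fitted]
    err_ws <- fits$slope[well_spec] - planted_beta[well_spec]
    add("slope_rmse", treat, sqrt(mean(err_ws^2)), sum(well_spec))
    add("slope_rmse_all", treat, sqrt(mean(err_all^2)), sum(fitted))

    sel <- result$selected[[treat]]
    add("selected_size", treat, length(sel), length(sel))

    ranked <- result$contrasts[[treat]][["ALT_vs_WT"]]
    n_ranked <- sum(!is.na(ranked$rank))
    cls <- truth$proteins$class[match(ranked$protein_id,
                                      truth$proteins$protein_id)]
    alt_ranks <- ranked$rank[cls == "binder_ALT_pref" & !is.na(ranked$rank)]
    if (length(alt_ranks) > 0 && n_ranked > 0) {
      add("alt_pref_median_rank_fraction", treat,
          stats::median(alt_ranks) / n_ranked, length(alt_ranks))
    }

    if (!is.null(result$ora[[treat]][["ALT_vs_WT"]])) {
      oratab <- result$ora[[treat]][["ALT_vs_WT"]]
      add("module_ora_rank", treat,
          match(truth$module_set_name, oratab$set_name), nrow(oratab))
    }

    add("triple_overlap_fraction", treat,
        attr(result$venn[[treat]], "triple_fraction"),
        attr(result$venn[[treat]], "union_size"))
  }
  out <- do.call(rbind, rows)
  row.names(out) <- NULL
  out
}
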