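#' Per-protein enrichment over the empty-vector control
#'
#' For each bait condition and treatment, tests every prey's centered log2
#' values in the bait pull-down against the EV control samples with a
#' two-sample t-test (Student pooled-variance by default). The bait's own
#' row is excluded. Proteins with fewer than `min_per_group` non-missing
#' values in either group are reported with `NA` statistics and
#' `insufficient = TRUE`.
#'
#' @param rel Centered relative log2 matrix (see [center_batches()]).
#' @param design Sample design.
#' @param treatments Treatments to analyze (each treatment is analyzed as an
#'   independent dataset); defaults to those present.
#' @param conditions Bait conditions to test against EV.
#' @param variant t-test variant, `"student"` or `"welch"`.
#' @param bait_id Row to exclude from testing.
#' @param min_per_group Minimum finite values per group.
#' @return data.frame with one row per (protein, condition, treatment):
#'   `protein_id`, `condition`, `treatment`, `log2FC` (bait minus EV group
#'   mean), `t`, `p_value`, `insufficient`.
#' @export
ev_enrichment <- function(rel, design, treatments = NULL,
                          conditions = apms_bait_conditions,
                          variant = c("student", "welch"),
                          bait_id = "hSFPQ", min_per_group = 2) {
  variant <- match.arg(variant)
  d <- design[match(colnames(rel), design$sample_id), ]
  if (is.null(treatments)) treatments <- intersect(apms_treatments,
                                                   unique(d$treatment))
  prey <- setdiff(rownames(rel), bait_id)

  out <- list()
  for (treat in treatments) {
    ev_cols <- which(d$condition == "EV" & d$treatment == treat)
    for (cond in conditions) {
      cond_cols <- which(d$condition == cond & d$treatment == treat)
      res <- data.frame(protein_id = prey, condition = cond,
                        treatment = treat, log2FC = NA_real_, t = NA_real_,
                        p_value = NA_real_, insufficient = FALSE,
                        stringsAsFactors = FALSE)
      for (i in seq_along(prey)) {
        a <- rel[prey[i], cond_cols]
        b <- rel[prey[i], ev_cols]
        if (sum(is.finite(a)) < min_per_group ||
            sum(is.finite(b)) < min_per_group) {
          res$insufficient[i] <- TRUE
          next
        }
        tt <- suppressWarnings(two_sample_t(a, b, variant))
        res$log2FC[i] <- tt$mean_diff
        res$t[i] <- tt$t
        res$p_value[i] <- tt$p
      }
      out[[paste(cond, treat)]] <- res
    }
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Call binders at fold-change and p-value thresholds
#'
#' Flags proteins significantly enriched over EV using strict inequalities
#' on both criteria (`log2FC > fc_threshold` and `p_value < p_threshold`).
#' Raw p-values are used for calling; a Benjamini-Hochberg adjusted column
#' (`p_adj`, computed within each condition x treatment) is added for
#' reference only and never enters the call.
#'
#' @param enr Result of [ev_enrichment()].
#' @param fc_threshold Positive log2 fold-change threshold (default 0.5).
#' @param p_threshold Positive p-value threshold (default 0.05).
#' @return `enr` with columns `p_adj` and `is_binder` added.
#' @export
call_binders <- function(enr, fc_threshold = 0.5, p_threshold = 0.05) {
  if (!is.numeric(fc_threshold) || fc_threshold <= 0 ||
      !is.numeric(p_threshold) || p_threshold <= 0) {
    stop("thresholds must be positive", call. = FALSE)
  }
  grp <- paste(enr$condition, enr$treatment)
  enr$p_adj <- stats::ave(enr$p_value, grp,
                          FUN = function(p) stats::p.adjust(p, "BH"))
  enr$is_binder <- !is.na(enr$log2FC) & !is.na(enr$p_value) &
    enr$log2FC > fc_threshold & enr$p_value < p_threshold
  enr
}

#' Extract per-group binder sets
#'
#' @param enr Result of [call_binders()].
#' @return Named list of character vectors of protein ids, one per
#'   `<condition>.<treatment>`.
#' @export
binder_sets <- function(enr) {
  if (is.null(enr$is_binder)) {
    stop("run call_binders() first", call. = FALSE)
  }
  b <- enr[enr$is_binder, ]
  split(b$protein_id, paste(b$condition, b$treatment, sep = "."))
}

#' Three-way Venn partition of binder sets
#'
#' Partitions the union of the WT, ALT and NLS binder sets into the seven
#' disjoint regions of a three-set Venn diagram.
#'
#' @param set_wt,set_alt,set_nls Character vectors of protein ids.
#' @return data.frame of class `venn_partition` with columns `region` and
#'   `count` (regions `WT_only`, `ALT_only`, `NLS_only`, `WT_ALT`,
#'   `WT_NLS`, `ALT_NLS`, `triple`), plus attributes `union_size` and
#'   `triple_fraction` (triple / union; 0 when the union is empty).
#' @examples
#' venn_partition(c("p1", "p2"), c("p2", "p3"), "p2")
#' @export
venn_partition <- function(set_wt, set_alt, set_nls) {
  set_wt <- unique(as.character(set_wt))
  set_alt <- unique(as.character(set_alt))
  set_nls <- unique(as.character(set_nls))
  u <- union(union(set_wt, set_alt), set_nls)
  in_wt <- u %in% set_wt
  in_alt <- u %in% set_alt
  in_nls <- u %in% set_nls
  counts <- c(
    WT_only = sum(in_wt & !in_alt & !in_nls),
    ALT_only = sum(!in_wt & in_alt & !in_nls),
    NLS_only = sum(!in_wt & !in_alt & in_nls),
    WT_ALT = sum(in_wt & in_alt & !in_nls),
    WT_NLS = sum(in_wt & !in_alt & in_nls),
    ALT_NLS = sum(!in_wt & in_alt & in_nls),
    triple = sum(in_wt & in_alt & in_nls)
  )
  out <- data.frame(region = names(counts), count = as.integer(counts),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "union_size") <- length(u)
  attr(out, "triple_fraction") <-
    if (length(u) == 0) 0 else unname(counts["triple"]) / length(u)
  class(out) <- c("venn_partition", "data.frame")
  out
}
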