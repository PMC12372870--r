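#' Supported variant-versus-variant contrasts
#' @keywords internal
apms_contrast_defs <- list(
  ALT_vs_WT = c(a = "ALT", b = "WT"),
  NLS_vs_WT = c(a = "NLS", b = "WT"),
  NLS_vs_ALT = c(a = "NLS", b = "ALT")
)

#' Matched per-batch log2 ratios between two bait conditions
#'
#' For every protein and every replicate batch in which both conditions of
#' the contrast are observed, computes
#' `value(condition A, batch) - value(condition B, batch)` on the
#' bait-corrected (or centered) matrix. Batches missing either side are
#' dropped for that protein.
#'
#' @param mat Relative log2 matrix (typically the `corrected` matrix of
#'   [bait_correct()]).
#' @param design Sample design.
#' @param contrast One of `"ALT_vs_WT"`, `"NLS_vs_WT"`, `"NLS_vs_ALT"`.
#' @param treatment Single treatment.
#' @return Numeric matrix proteins x batches of matched ratios (`NA` where
#'   either side is missing).
#' @export
matched_log2_ratios <- function(mat, design, contrast, treatment) {
  cdef <- apms_contrast_defs[[match.arg(contrast,
                                        names(apms_contrast_defs))]]
  d <- design[match(colnames(mat), design$sample_id), ]
  a_idx <- d$condition == cdef["a"] & d$treatment == treatment
  b_idx <- d$condition == cdef["b"] & d$treatment == treatment
  batches <- sort(intersect(d$replicate_batch[a_idx],
                            d$replicate_batch[b_idx]))
  if (length(batches) < 2) {
    stop("contrast '", contrast, "' needs the two conditions in >= 2 ",
         "shared replicate batches", call. = FALSE)
  }
  ratios <- matrix(NA_real_, nrow(mat), length(batches),
                   dimnames = list(rownames(mat), as.character(batches)))
  for (k in seq_along(batches)) {
    ca <- colnames(mat)[a_idx & d$replicate_batch == batches[k]]
    cb <- colnames(mat)[b_idx & d$replicate_batch == batches[k]]
    ratios[, k] <- mat[, ca] - mat[, cb]
  }
  ratios
}

#' Pi significance score
#'
#' `pi = log2FC x (-log10 p)`: combines effect size and confidence into a
#' single ranking score. `p` must lie in (0, 1]; an exact zero (possible
#' only through the degenerate-variance clamp upstream) is clamped to the
#' smallest positive representable double with a warning.
#'
#' @param log2fc Numeric vector of log2 fold changes.
#' @param p Numeric vector of p-values in (0, 1].
#' @return Numeric vector of pi values.
#' @examples
#' pi_score(1, 0.01) # 2
#' @export
pi_score <- function(log2fc, p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  if (any(p == 0, na.rm = TRUE)) {
    warning("p = 0 clamped to the smallest positive double", call. = FALSE)
    p[!is.na(p) & p == 0] <- .Machine$double.xmin
  }
  log2fc * (-log10(p))
}

#' Test a contrast via matched ratios and one-sample t-tests
#'
#' Computes matched per-batch log2 ratios for one contrast and treatment and
#' tests each protein's ratios against mean zero with [one_sample_t()].
#' Proteins with fewer than 2 usable ratios are flagged `insufficient` and
#' excluded from testing.
#'
#' @inheritParams matched_log2_ratios
#' @return data.frame: `protein_id`, `contrast`, `treatment`, `n_ratios`,
#'   `log2FC` (mean matched ratio), `t`, `p_value`, `insufficient`.
#' @export
contrast_tests <- function(mat, design, contrast, treatment) {
  ratios <- matched_log2_ratios(mat, design, contrast, treatment)
  n_ok <- rowSums(is.finite(ratios))
  res <- data.frame(protein_id = rownames(ratios), contrast = contrast,
                    treatment = treatment, n_ratios = as.integer(n_ok),
                    log2FC = NA_real_, t = NA_real_, p_value = NA_real_,
                    insufficient = n_ok < 2, stringsAsFactors = FALSE,
                    row.names = NULL)
  for (i in which(n_ok >= 2)) {
    tt <- suppressWarnings(one_sample_t(ratios[i, ]))
    res$log2FC[i] <- tt$mean
    res$t[i] <- tt$t
    res$p_value[i] <- tt$p
  }
  res
}

#' Rank the correlated-binder subset by pi value
#'
#' Computes pi values only for proteins in `selected` (the
#' positive-correlation binder subset) and ranks them in descending pi
#' order. Ties are broken by ascending p-value, then lexicographic protein
#' id, so ranks are a deterministic permutation.
#'
#' @param results data.frame from [contrast_tests()] (one contrast, one
#'   treatment).
#' @param selected Character vector of protein ids; must be a subset of
#'   `results$protein_id`.
#' @return `results` with columns `selected`, `pi_value`, `rank` added
#'   (`NA` outside the selected, testable subset), sorted by rank with
#'   unranked proteins last.
#' @export
rank_binders <- function(results, selected) {
  if (!all(selected %in% results$protein_id)) {
    stop("selected must be a subset of the proteins with results",
         call. = FALSE)
  }
  results$selected <- results$protein_id %in% selected
  results$pi_value <- NA_real_
  idx <- which(results$selected & !results$insufficient &
                 !is.na(results$p_value))
  results$pi_value[idx] <- pi_score(results$log2FC[idx],
                                    results$p_value[idx])
  results$rank <- NA_integer_
  ord <- idx[order(-results$pi_value[idx], results$p_value[idx],
                   results$protein_id[idx])]
  results$rank[ord] <- seq_along(ord)
  results[order(results$rank, !results$selected, results$protein_id), ,
          drop = FALSE]
}
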