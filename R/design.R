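#' Pull-down conditions and treatments
#'
#' The experimental grid consists of four pull-down conditions -- the
#' empty-vector negative control (`EV`) and three bait variants (`WT`, `ALT`,
#' `NLS`) -- each assayed under one or two treatments (`untreated`,
#' `oxidative`), with one sample per condition, treatment and replicate batch
#' (one multiplexed run per batch).
#'
#' @name apms-grid
#' @keywords internal
NULL

apms_conditions <- c("EV", "WT", "ALT", "NLS")
apms_bait_conditions <- c("WT", "ALT", "NLS")
apms_treatments <- c("untreated", "oxidative")

#' Build a balanced AP-MS sample design
#'
#' Returns one sample per (condition, treatment, replicate batch) for the
#' four pull-down conditions. The grid is fully deterministic; `seed` is
#' accepted for interface symmetry with the simulator but does not influence
#' the design.
#'
#' @param n_replicates Number of replicate batches (multiplexed runs); must
#'   be at least 2 so that downstream t-tests are defined.
#' @param treatments Character vector, subset of
#'   `c("untreated", "oxidative")`.
#' @param seed Ignored; the design is deterministic.
#'
#' @return A data.frame with columns `sample_id`, `condition`, `treatment`,
#'   `replicate_batch`.
#' @examples
#' design <- make_design(4)
#' nrow(design) # 32 = 4 conditions x 2 treatments x 4 batches
#' @export
make_design <- function(n_replicates = 4,
                        treatments = c("untreated", "oxidative"),
                        seed = NULL) {
  if (!is.numeric(n_replicates) || length(n_replicates) != 1 ||
      is.na(n_replicates) || n_replicates < 2) {
    stop("design error: n_replicates must be a single integer >= 2 ",
         "(replicated groups are required for the t-tests)", call. = FALSE)
  }
  n_replicates <- as.integer(n_replicates)
  treatments <- match.arg(treatments, apms_treatments, several.ok = TRUE)

  grid <- expand.grid(
    replicate_batch = seq_len(n_replicates),
    condition = apms_conditions,
    treatment = treatments,
    KEEP.OUT.ATTRS = FALSE,
    stringsAsFactors = FALSE
  )
  ord <- order(match(grid$treatment, apms_treatments),
               match(grid$condition, apms_conditions),
               grid$replicate_batch)
  grid <- grid[ord, , drop = FALSE]
  data.frame(
    sample_id = paste(grid$condition, grid$treatment, grid$replicate_batch,
                      sep = "_"),
    condition = grid$condition,
    treatment = grid$treatment,
    replicate_batch = as.integer(grid$replicate_batch),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Validate a sample design table
#'
#' Checks the structural invariants the downstream statistics rely on:
#' unique sample ids, known condition/treatment labels, at most one sample
#' per (condition, treatment, batch), and every condition observed in at
#' least two replicate batches per treatment.
#'
#' @param design A data.frame as returned by [make_design()].
#' @return The validated design, invisibly.
#' @export
validate_design <- function(design) {
  req <- c("sample_id", "condition", "treatment", "replicate_batch")
  if (!is.data.frame(design) || !all(req %in% names(design))) {
    stop("design error: expected a data.frame with columns ",
         paste(req, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(design$sample_id)) {
    stop("design error: sample_ids must be unique", call. = FALSE)
  }
  if (!all(design$condition %in% apms_conditions)) {
    stop("design error: unknown condition label(s): ",
         paste(setdiff(unique(design$condition), apms_conditions),
               collapse = ", "), call. = FALSE)
  }
  if (!all(design$treatment %in% apms_treatments)) {
    stop("design error: unknown treatment label(s)", call. = FALSE)
  }
  key <- paste(design$condition, design$treatment, design$replicate_batch)
  if (anyDuplicated(key)) {
    stop("design error: more than one sample for the same ",
         "(condition, treatment, replicate_batch)", call. = FALSE)
  }
  tab <- table(design$condition, design$treatment)
  if (any(tab[, colSums(tab) > 0, drop = FALSE] < 2)) {
    stop("design error: every condition must be present in >= 2 replicate ",
         "batches per treatment", call. = FALSE)
  }
  invisible(design)
}
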