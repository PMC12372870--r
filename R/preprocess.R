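#' Log2-transform a raw abundance matrix
#'
#' @param raw Numeric matrix of nonnegative linear-scale intensities
#'   (proteins x samples), `NA` = missing.
#' @param pseudocount Nonnegative value added before taking log2. Must be
#'   positive if any intensity is exactly zero.
#' @return Matrix of log2 values; missing entries stay missing.
#' @examples
#' log2_transform(matrix(c(8, 2), 1), pseudocount = 0)
#' @export
log2_transform <- function(raw, pseudocount = 0) {
  if (!is.numeric(pseudocount) || length(pseudocount) != 1 ||
      pseudocount < 0) {
    stop("pseudocount must be a single nonnegative number", call. = FALSE)
  }
  if (any(raw < 0, na.rm = TRUE)) {
    stop("abundances must be nonnegative", call. = FALSE)
  }
  if (pseudocount == 0 && any(raw == 0, na.rm = TRUE)) {
    stop("zero intensity with pseudocount 0: log2 undefined; ",
         "set pseudocount > 0", call. = FALSE)
  }
  log2(raw + pseudocount)
}

#' Center log2 abundances to the row mean per replicate batch
#'
#' Converts absolute log2 intensities into relative log2 abundances: for
#' every protein and every replicate batch, the mean of that protein's
#' non-missing log2 values over the batch's samples is subtracted. This
#' makes each multiplexed run self-normalizing and removes run-to-run
#' labeling and loading differences (and, exactly, any per-protein batch
#' offset constant within the run).
#'
#' @param log2_matrix Numeric matrix of log2 values, columns named by
#'   sample id.
#' @param design Sample design covering every column.
#' @param scope `"batch"` pools all samples of a replicate batch (all
#'   conditions and treatments of one multiplexed run, the default);
#'   `"batch_treatment"` centers untreated and oxidative samples of a batch
#'   separately.
#' @return The centered matrix with attribute `provenance = "centered"`.
#'   Cells of a protein entirely missing within a batch remain missing.
#' @examples
#' m <- matrix(c(4, 6, 8), 1, dimnames = list("p", paste0("s", 1:3)))
#' d <- data.frame(sample_id = paste0("s", 1:3), condition = "WT",
#'                 treatment = "untreated", replicate_batch = 1)
#' center_batches(m, d) # -2 0 2
#' @export
center_batches <- function(log2_matrix, design,
                           scope = c("batch", "batch_treatment")) {
  scope <- match.arg(scope)
  if (is.null(colnames(log2_matrix)) ||
      !all(colnames(log2_matrix) %in% design$sample_id)) {
    stop("every matrix column must appear in the design", call. = FALSE)
  }
  d <- design[match(colnames(log2_matrix), design$sample_id), ]
  grp <- if (scope == "batch") as.character(d$replicate_batch) else
    paste(d$replicate_batch, d$treatment, sep = ".")

  out <- log2_matrix
  for (g in unique(grp)) {
    cols <- which(grp == g)
    m <- rowMeans(log2_matrix[, cols, drop = FALSE], na.rm = TRUE)
    m[!is.finite(m)] <- 0  # protein unobserved in this batch: leave NA cells
    out[, cols] <- log2_matrix[, cols, drop = FALSE] - m
  }
  attr(out, "provenance") <- "centered"
  out
}

#' Filter proteins by minimum observations per group
#'
#' Retains proteins with at least `min_per_group` non-missing values in
#' every (condition, treatment) group present in the design, so that every
#' group statistic downstream is defined. Row order is preserved.
#'
#' @param matrix Relative log2 matrix (columns named by sample id).
#' @param design Sample design.
#' @param min_per_group Minimum non-missing values per group; must be >= 2.
#' @param always_keep Row names exempt from the filter (the bait row, whose
#'   EV cells are legitimately below detection, must survive to serve as
#'   the regression covariate).
#' @return The filtered matrix (attributes preserved).
#' @export
filter_min_observed <- function(matrix, design, min_per_group = 2,
                                always_keep = NULL) {
  if (!is.numeric(min_per_group) || length(min_per_group) != 1 ||
      min_per_group < 2) {
    stop("min_per_group must be >= 2 (group statistics need replication)",
         call. = FALSE)
  }
  d <- design[match(colnames(matrix), design$sample_id), ]
  grp <- paste(d$condition, d$treatment, sep = ".")
  keep <- rep(TRUE, nrow(matrix))
  for (g in unique(grp)) {
    cols <- grp == g
    keep <- keep &
      rowSums(!is.na(matrix[, cols, drop = FALSE])) >= min_per_group
  }
  keep <- keep | rownames(matrix) %in% always_keep
  prov <- attr(matrix, "provenance")
  out <- matrix[keep, , drop = FALSE]
  attr(out, "provenance") <- prov
  out
}
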