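#' Pearson correlation of a prey profile to the bait
#'
#' Sample Pearson correlation on pairwise-complete observations. If either
#' vector is constant over the complete pairs, the correlation is reported
#' as 0 with attribute `degenerate = TRUE`, keeping the positive-correlation
#' filter total.
#'
#' @param prey,bait Numeric vectors over the same samples.
#' @return Numeric correlation in \[-1, 1\] with attribute `degenerate`.
#' @export
pearson_to_bait <- function(prey, bait) {
  ok <- is.finite(prey) & is.finite(bait)
  if (sum(ok) < 3) {
    stop("insufficient data: need >= 3 paired points for a correlation",
         call. = FALSE)
  }
  x <- bait[ok]
  y <- prey[ok]
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    return(structure(0, degenerate = TRUE))
  }
  structure(stats::cor(x, y), degenerate = FALSE)
}

#' Ordinary least squares of a prey profile on the bait profile
#'
#' Fits `prey = a * bait + b` on pairwise-complete observations; the
#' residuals are the bait-amount-corrected relative log2 abundances. A
#' constant (zero-variance) prey is handled as `a = 0`, `b = mean(prey)`
#' with zero residuals and correlation 0, flagged degenerate.
#'
#' @param prey,bait Numeric vectors over the same samples (named vectors
#'   keep their names on the residuals).
#' @return List of class `bait_fit`: `slope`, `intercept`, `residuals`
#'   (on the samples used), `pearson_r`, `n_points`, `degenerate`.
#' @examples
#' fit_bait_regression(prey = c(1, 3, 5), bait = c(0, 1, 2)) # a = 2, b = 1
#' @export
fit_bait_regression <- function(prey, bait) {
  ok <- is.finite(prey) & is.finite(bait)
  if (sum(ok) < 3) {
    stop("insufficient data: need >= 3 paired points for the regression",
         call. = FALSE)
  }
  x <- bait[ok]
  y <- prey[ok]
  if (stats::var(x) == 0) {
    stop("degenerate regressor: bait values are constant", call. = FALSE)
  }
  if (stats::var(y) == 0) {
    res <- y - y  # zeros, names preserved
    return(structure(list(slope = 0, intercept = mean(y), residuals = res,
                          pearson_r = 0, n_points = length(y),
                          degenerate = TRUE),
                     class = "bait_fit"))
  }
  fit <- stats::lm.fit(cbind(intercept = 1, bait = x), y)
  structure(list(slope = unname(fit$coefficients["bait"]),
                 intercept = unname(fit$coefficients["intercept"]),
                 residuals = fit$residuals,
                 pearson_r = as.numeric(pearson_to_bait(y, x)),
                 n_points = length(y),
                 degenerate = FALSE),
            class = "bait_fit")
}

#' Regress the bait profile out of every prey
#'
#' For one treatment, takes the centered relative log2 values of the bait
#' variant samples (WT, ALT, NLS pooled; EV excluded), uses the bait
#' protein's own centered row as the independent variable, and fits
#' [fit_bait_regression()] per prey. The residuals form the bait-corrected
#' matrix used by the variant-versus-variant contrasts; the per-prey Pearson
#' correlation to the bait feeds the correlated-binder filter.
#'
#' @param rel Centered relative log2 matrix.
#' @param design Sample design.
#' @param treatment Single treatment to analyze.
#' @param bait_id Row name of the bait protein.
#' @param min_points Minimum paired non-missing points per prey (>= 3).
#' @param per_condition If `TRUE`, fit each bait condition separately
#'   (sensitivity analysis); the default pools WT/ALT/NLS in one fit, which
#'   preserves between-variant differences in the residuals.
#' @return List of class `bait_correction`:
#'   \describe{
#'     \item{corrected}{residual matrix (preys x bait-variant samples,
#'       `NA` where missing or unfit), attribute
#'       `provenance = "bait_corrected"`.}
#'     \item{fits}{data.frame `protein_id`, `treatment`, `slope`,
#'       `intercept`, `pearson_r`, `n_points`, `degenerate`,
#'       `insufficient`.}
#'     \item{bait}{the centered bait values used as regressor.}
#'   }
#' @export
bait_correct <- function(rel, design, treatment, bait_id = "hSFPQ",
                         min_points = 3, per_condition = FALSE) {
  if (min_points < 3) {
    stop("min_points must be >= 3", call. = FALSE)
  }
  if (!bait_id %in% rownames(rel)) {
    stop("bait row '", bait_id, "' not found in the matrix", call. = FALSE)
  }
  d <- design[match(colnames(rel), design$sample_id), ]
  use <- which(d$treatment == treatment & d$condition != "EV")
  if (length(use) == 0) {
    stop("no bait-variant samples for treatment '", treatment, "'",
         call. = FALSE)
  }
  cols <- colnames(rel)[use]
  bait <- rel[bait_id, cols]
  prey <- setdiff(rownames(rel), bait_id)

  groups <- if (per_condition) split(cols, d$condition[use]) else
    list(pooled = cols)

  corrected <- matrix(NA_real_, length(prey), length(cols),
                      dimnames = list(prey, cols))
  fits <- data.frame(protein_id = prey, treatment = treatment,
                     slope = NA_real_, intercept = NA_real_,
                     pearson_r = NA_real_, n_points = NA_integer_,
                     degenerate = FALSE, insufficient = FALSE,
                     stringsAsFactors = FALSE)
  for (i in seq_along(prey)) {
    y_all <- rel[prey[i], cols]
    any_fit <- FALSE
    for (g in groups) {
      y <- y_all[g]
      x <- bait[g]
      if (sum(is.finite(y) & is.finite(x)) < min_points) next
      f <- fit_bait_regression(y, x)
      corrected[i, names(f$residuals)] <- f$residuals
      if (!any_fit || length(groups) == 1) {
        fits$slope[i] <- f$slope
        fits$intercept[i] <- f$intercept
        fits$n_points[i] <- f$n_points
        fits$degenerate[i] <- f$degenerate
      }
      any_fit <- TRUE
    }
    if (!any_fit) {
      fits$insufficient[i] <- TRUE
      next
    }
    # correlation always on the pooled samples (one r per protein)
    ok <- is.finite(y_all) & is.finite(bait)
    if (sum(ok) >= 3) {
      r <- pearson_to_bait(y_all, bait)
      fits$pearson_r[i] <- as.numeric(r)
      if (isTRUE(attr(r, "degenerate"))) fits$degenerate[i] <- TRUE
    }
  }
  attr(corrected, "provenance") <- "bait_corrected"
  structure(list(corrected = corrected, fits = fits, bait = bait),
            class = "bait_correction")
}

#' Select correlated binders
#'
#' Restricts the binder universe (union of per-condition EV-enriched
#' proteins) to preys whose Pearson correlation to the bait is strictly
#' greater than `r_cutoff` (positive-correlation filter).
#'
#' @param fits `fits` data.frame from [bait_correct()].
#' @param binder_universe Character vector of protein ids.
#' @param r_cutoff Correlation cutoff in (0, 1); default 0.3.
#' @return Sorted character vector of selected protein ids.
#' @export
select_correlated_binders <- function(fits, binder_universe,
                                      r_cutoff = 0.3) {
  if (!is.numeric(r_cutoff) || length(r_cutoff) != 1 ||
      r_cutoff <= 0 || r_cutoff >= 1) {
    stop("r_cutoff must lie in (0, 1)", call. = FALSE)
  }
  keep <- fits$protein_id %in% binder_universe &
    !is.na(fits$pearson_r) & fits$pearson_r > r_cutoff
  sort(fits$protein_id[keep])
}
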