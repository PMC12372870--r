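#' Two-sample t-test with explicit degenerate rules
#'
#' Thin wrapper around [stats::t.test()] (Student pooled-variance by
#' default, Welch optional) that makes the zero-variance corner cases
#' explicit so the pipeline stays total on exact synthetic data: if both
#' groups are constant and equal the result is `t = 0, p = 1`; if both are
#' constant but unequal, `p` is set to the smallest positive representable
#' double and the result flagged degenerate (with a warning).
#'
#' @param a,b Numeric vectors; non-finite values are dropped; each group
#'   needs at least 2 finite values.
#' @param variant `"student"` (pooled variance) or `"welch"`.
#' @return List with `mean_diff` (= mean(a) - mean(b)), `t`, `p`, `df`,
#'   `degenerate`.
#' @examples
#' two_sample_t(c(2.1, 1.9, 2.0, 2.0), c(1.0, 1.0, 0.9, 1.1))
#' @export
two_sample_t <- function(a, b, variant = c("student", "welch")) {
  variant <- match.arg(variant)
  a <- a[is.finite(a)]
  b <- b[is.finite(b)]
  if (length(a) < 2 || length(b) < 2) {
    stop("insufficient data: each group needs >= 2 finite values",
         call. = FALSE)
  }
  mean_diff <- mean(a) - mean(b)
  degen <- function() {
    if (isTRUE(all.equal(mean_diff, 0)) || mean_diff == 0) {
      list(mean_diff = mean_diff, t = 0, p = 1, df = NA_real_,
           degenerate = TRUE)
    } else {
      warning("zero within-group variance with unequal means: p clamped ",
              "to the smallest positive double", call. = FALSE)
      list(mean_diff = mean_diff, t = sign(mean_diff) * Inf,
           p = .Machine$double.xmin, df = NA_real_, degenerate = TRUE)
    }
  }
  if (stats::var(a) == 0 && stats::var(b) == 0) return(degen())
  ht <- tryCatch(
    stats::t.test(a, b, var.equal = (variant == "student")),
    error = function(e) NULL  # "data are essentially constant"
  )
  if (is.null(ht)) return(degen())
  list(mean_diff = mean_diff, t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter), degenerate = FALSE)
}

#' One-sample t-test of mean zero with explicit degenerate rules
#'
#' Two-sided test that the mean of `x` is zero, via [stats::t.test()]. An
#' all-zero vector gives `t = 0, p = 1`; a constant nonzero vector gives
#' `p` equal to the smallest positive representable double, flagged
#' degenerate with a warning.
#'
#' @param x Numeric vector of matched log2 ratios; needs >= 2 finite values.
#' @return List with `mean`, `t`, `p`, `df`, `degenerate`.
#' @export
one_sample_t <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2) {
    stop("insufficient data: need >= 2 finite ratios", call. = FALSE)
  }
  m <- mean(x)
  if (stats::var(x) == 0) {
    if (m == 0) {
      return(list(mean = 0, t = 0, p = 1, df = NA_real_, degenerate = TRUE))
    }
    warning("zero variance with nonzero mean: p clamped to the smallest ",
            "positive double", call. = FALSE)
    return(list(mean = m, t = sign(m) * Inf, p = .Machine$double.xmin,
                df = NA_real_, degenerate = TRUE))
  }
  ht <- tryCatch(stats::t.test(x, mu = 0), error = function(e) NULL)
  if (is.null(ht)) {
    warning("near-constant ratios: p clamped to the smallest positive ",
            "double", call. = FALSE)
    return(list(mean = m, t = sign(m) * Inf, p = .Machine$double.xmin,
                df = NA_real_, degenerate = TRUE))
  }
  list(mean = m, t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter), degenerate = FALSE)
}
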