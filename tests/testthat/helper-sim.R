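# Small simulation settings for fast unit tests; the full study-scale
# scenario lives in test-acceptance.R only.
small_params <- function(seed = 7, detection_limit = 0, ...) {
  sim_params(n_proteins = 120, n_binders_per_class = 10,
             detection_limit = detection_limit, seed = seed, ...)
}

# minimal one-protein design helper for matrix-level unit tests
tiny_design <- function(sample_id, condition = "WT",
                        treatment = "untreated", replicate_batch = 1) {
  data.frame(sample_id = sample_id,
             condition = rep_len(condition, length(sample_id)),
             treatment = rep_len(treatment, length(sample_id)),
             replicate_batch = as.integer(rep_len(replicate_batch,
                                                  length(sample_id))),
             stringsAsFactors = FALSE)
}

# independent closed-form t-test oracles (textbook formulas; deliberately
# not stats::t.test, which backs the implementation)
oracle_two_sample_t <- function(a, b, welch = FALSE) {
  n1 <- length(a); n2 <- length(b)
  v1 <- sum((a - mean(a))^2) / (n1 - 1)
  v2 <- sum((b - mean(b))^2) / (n2 - 1)
  if (welch) {
    se2 <- v1 / n1 + v2 / n2
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    tt <- (mean(a) - mean(b)) / sqrt(se2)
  } else {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    df <- n1 + n2 - 2
    tt <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  }
  list(t = tt, df = df, p = 2 * stats::pt(-abs(tt), df))
}

oracle_one_sample_t <- function(x) {
  n <- length(x)
  tt <- mean(x) / (stats::sd(x) / sqrt(n))
  list(t = tt, df = n - 1, p = 2 * stats::pt(-abs(tt), n - 1))
}

# normal-equations OLS oracle
oracle_ols <- function(x, y) {
  X <- cbind(1, x)
  coef <- solve(t(X) %*% X, t(X) %*% y)
  list(intercept = coef[1], slope = coef[2])
}

# direct covariance/SD Pearson oracle
oracle_pearson <- function(x, y) {
  dx <- x - mean(x)
  dy <- y - mean(y)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

# brute-force hypergeometric upper tail by enumeration of all C(N, n) draws
oracle_hyper_enum <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)  # items 1..K are "in the set"
  mean(hits >= k)
}
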