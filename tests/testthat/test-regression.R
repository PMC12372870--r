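test_that("an exact line is recovered with zero residuals", {
  f <- fit_bait_regression(prey = c(1, 3, 5), bait = c(0, 1, 2))
  expect_equal(f$slope, 2)
  expect_equal(f$intercept, 1)
  expect_lt(max(abs(f$residuals)), 1e-12)
  expect_equal(f$pearson_r, 1)
})

test_that("a constant prey degenerates to slope 0 and r 0", {
  f <- fit_bait_regression(c(4, 4, 4, 4), c(0, 1, 2, 3))
  expect_equal(f$slope, 0)
  expect_equal(f$intercept, 4)
  expect_equal(unname(f$residuals), rep(0, 4))
  expect_equal(f$pearson_r, 0)
  expect_true(f$degenerate)
})

test_that("OLS matches the normal-equations oracle to 1e-10", {
  set.seed(77)
  for (i in 1:100) {
    x <- rnorm(12)
    y <- 0.8 * x + rnorm(12, sd = 0.5)
    f <- fit_bait_regression(y, x)
    want <- oracle_ols(x, y)
    expect_lt(abs(f$slope - want$slope), 1e-10)
    expect_lt(abs(f$intercept - want$intercept), 1e-10)
  }
})

test_that("residuals are orthogonal to the bait with zero mean", {
  set.seed(78)
  for (i in 1:50) {
    n <- sample(5:15, 1)
    x <- rnorm(n)
    y <- rnorm(1) * x + rnorm(n)
    f <- fit_bait_regression(y, x)
    expect_lt(abs(mean(f$residuals)), 1e-9)
    expect_lt(abs(cor(f$residuals, x)), 1e-8)
  }
})

test_that("regressing the bait on itself gives the identity fit", {
  x <- rnorm(10)
  f <- fit_bait_regression(x, x)
  expect_equal(f$slope, 1)
  expect_lt(abs(f$intercept), 1e-12)
  expect_lt(max(abs(f$residuals)), 1e-12)
})

test_that("degenerate and undersized regressions error as specified", {
  expect_error(fit_bait_regression(c(1, 2), c(1, 2)), "insufficient")
  expect_error(fit_bait_regression(c(1, 2, 3), c(2, 2, 2)),
               "degenerate regressor")
  expect_error(pearson_to_bait(c(1, 2), c(1, 2)), "insufficient")
})

test_that("Pearson correlation matches the direct formula", {
  expect_equal(as.numeric(pearson_to_bait(-(1:5), 1:5)), -1)
  expect_equal(as.numeric(pearson_to_bait(2 * (1:6) + 5, 1:6)), 1)
  set.seed(79)
  for (i in 1:50) {
    x <- rnorm(10)
    y <- rnorm(10)
    expect_lt(abs(as.numeric(pearson_to_bait(y, x)) - oracle_pearson(x, y)),
              1e-12)
  }
  d <- pearson_to_bait(c(3, 3, 3, 3), rnorm(4))
  expect_equal(as.numeric(d), 0)
  expect_true(attr(d, "degenerate"))
})

test_that("pairwise-complete handling drops missing pairs", {
  x <- c(0, 1, 2, 3, NA)
  y <- c(1, 3, NA, 7, 9)
  f <- fit_bait_regression(y, x)
  expect_equal(f$n_points, 3)
  want <- oracle_ols(c(0, 1, 3), c(1, 3, 7))
  expect_lt(abs(f$slope - want$slope), 1e-10)
})

test_that("the correlated-binder filter is strict and positive", {
  fits <- data.frame(protein_id = c("a", "b", "c", "d"),
                     pearson_r = c(0.31, 0.30, -0.9, NA),
                     stringsAsFactors = FALSE)
  expect_equal(select_correlated_binders(fits, fits$protein_id), "a")
  expect_error(select_correlated_binders(fits, "a", r_cutoff = 0),
               "r_cutoff")
  expect_error(select_correlated_binders(fits, "a", r_cutoff = 1),
               "r_cutoff")
})

test_that("slope recovery attains the theoretical OLS error bound", {
  # condition-constant enrichment: the pooled per-treatment fit is exactly
  # specified, so the slope error should match the OLS sampling error.
  flat <- default_effects(delta_shared = 1.5, delta_pref = 1.5,
                          delta_base = 1.5, delta_module_stress = 1.5)
  p <- sim_params(n_proteins = 800, n_binders_per_class = 80,
                  effects = flat, detection_limit = 0, seed = 13)
  sim <- simulate_apms(p, make_design(4, "untreated"))
  rel <- center_batches(log2_transform(sim$abundance), sim$design)
  bc <- bait_correct(rel, sim$design, "untreated")
  cls <- sim$truth$proteins$class[match(bc$fits$protein_id,
                                        sim$truth$proteins$protein_id)]
  beta <- ifelse(cls == "background", 0, 1)
  err <- bc$fits$slope - beta
  rmse <- sqrt(mean(err^2))
  # centering leaves residual SD sqrt(7/8) * noise_sd (8 samples per batch)
  x <- bc$bait
  se_theory <- sqrt(7 / 8) * p$noise_sd / sqrt(sum((x - mean(x))^2))
  expect_lt(rmse, 1.1 * se_theory)
  expect_gt(rmse, 0.5 * se_theory)  # and not implausibly small
})

test_that("matrix-level bait correction removes the bait profile", {
  sim <- simulate_apms(small_params(seed = 91), make_design(4, "untreated"))
  rel <- center_batches(log2_transform(sim$abundance), sim$design)
  bc <- bait_correct(rel, sim$design, "untreated")
  expect_identical(attr(bc$corrected, "provenance"), "bait_corrected")
  for (pid in rownames(bc$corrected)[c(1, 30, 60, 90)]) {
    res <- bc$corrected[pid, ]
    ok <- is.finite(res)
    expect_lt(abs(mean(res[ok])), 1e-9)
    if (sd(res[ok]) > 0) {
      expect_lt(abs(cor(res[ok], bc$bait[ok])), 1e-8)
    }
  }
  # binders track the bait strongly, background does not, on average
  cls <- sim$truth$proteins$class[match(bc$fits$protein_id,
                                        sim$truth$proteins$protein_id)]
  expect_gt(mean(bc$fits$pearson_r[cls == "binder_shared"]), 0.5)
  expect_lt(mean(abs(bc$fits$pearson_r[cls == "background"])), 0.3)
})
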