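test_that("identical parameters and seed give bit-identical simulations", {
  design <- make_design(3)
  s1 <- simulate_apms(small_params(seed = 11), design)
  s2 <- simulate_apms(small_params(seed = 11), design)
  expect_identical(s1$abundance, s2$abundance)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_apms(small_params(seed = 12), design)
  expect_false(identical(s1$abundance, s3$abundance))
})

test_that("noise-free simulations satisfy the planted linear model exactly", {
  p <- small_params(seed = 3, noise_sd = 0, batch_effect_sd = 0)
  design <- make_design(4)
  sim <- simulate_apms(p, design)
  lm2 <- log2(sim$abundance)
  bait <- lm2["hSFPQ", ]
  eff <- planted_effects(sim$truth)

  for (cond in c("WT", "ALT", "NLS")) {
    cols <- design$sample_id[design$condition == cond &
                               design$treatment == "untreated"]
    for (pid in c("P001", "P011", "P111")) {  # shared, WT-pref, background
      tr <- sim$truth$proteins[sim$truth$proteins$protein_id == pid, ]
      e <- eff[eff$protein_id == pid & eff$condition == cond &
                 eff$treatment == "untreated", ]
      y <- lm2[pid, cols]
      x <- bait[cols]
      if (e$beta != 0) {
        fit <- oracle_ols(x, y)
        expect_lt(abs(fit$slope - e$beta), 1e-9)
        # intercept = mu + delta - beta * bait_log2_mean
        mu_hat <- fit$intercept + e$beta * p$bait_log2_mean - e$delta
        expect_lt(abs(mu_hat - tr$baseline_log2), 1e-9)
      } else {
        expect_lt(max(abs(y - tr$baseline_log2)), 1e-9)
      }
    }
  }
})

test_that("EV separation equals the planted enrichment exactly without noise", {
  p <- small_params(seed = 5, noise_sd = 0, batch_effect_sd = 0.4,
                    bait_efficiency_sd = 0)
  design <- make_design(3, "untreated")
  sim <- simulate_apms(p, design)
  lm2 <- log2(sim$abundance)
  eff <- planted_effects(sim$truth)
  for (pid in c("P001", "P021", "P031")) {
    for (cond in c("WT", "ALT", "NLS")) {
      d_cond <- design[design$condition == cond, ]
      d_ev <- design[design$condition == "EV", ]
      # paired by batch so the planted batch offsets cancel exactly
      diffs <- lm2[pid, d_cond$sample_id[order(d_cond$replicate_batch)]] -
        lm2[pid, d_ev$sample_id[order(d_ev$replicate_batch)]]
      delta <- eff$delta[eff$protein_id == pid & eff$condition == cond &
                           eff$treatment == "untreated"]
      expect_lt(max(abs(diffs - delta)), 1e-9)
    }
  }
})

test_that("no emitted value lies below the detection limit", {
  sim <- simulate_apms(small_params(seed = 9, detection_limit = 600),
                       make_design(3))
  expect_true(all(sim$abundance >= 600, na.rm = TRUE))
  expect_true(anyNA(sim$abundance))  # the limit actually bites
  expect_false(all(is.na(sim$abundance["hSFPQ", ])))
})

test_that("invalid simulation parameters are rejected", {
  expect_error(small_params(noise_sd = -1), "standard deviations")
  expect_error(sim_params(n_proteins = 50, n_binders_per_class = 10),
               "n_binders_per_class")
  expect_error(validate_sim_params(list()), "apms_sim_params")
})

test_that("ground truth is consistent with the planted model", {
  sim <- simulate_apms(small_params(seed = 2), make_design(2))
  tr <- sim$truth
  expect_equal(sum(tr$proteins$class == "bait"), 1)
  eff <- planted_effects(tr)
  bg <- eff[eff$class == "background", ]
  expect_true(all(bg$beta == 0) && all(bg$delta == 0))
  expect_setequal(tr$module_set,
                  tr$proteins$protein_id[tr$proteins$class == "module_member"])
})
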