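ratio_fixture <- function() {
  # 2 proteins x (ALT, WT) x 2 batches, values chosen by hand
  ids <- c("ALT_untreated_1", "ALT_untreated_2",
           "WT_untreated_1", "WT_untreated_2")
  mat <- matrix(c(2, 3, 1, 1,
                  4, 4, 4, 4), 2, byrow = TRUE,
                dimnames = list(c("pa", "pb"), ids))
  design <- data.frame(sample_id = ids,
                       condition = c("ALT", "ALT", "WT", "WT"),
                       treatment = "untreated",
                       replicate_batch = c(1L, 2L, 1L, 2L),
                       stringsAsFactors = FALSE)
  list(mat = mat, design = design)
}

test_that("matched ratios pair by replicate batch", {
  fx <- ratio_fixture()
  r <- matched_log2_ratios(fx$mat, fx$design, "ALT_vs_WT", "untreated")
  expect_equal(unname(r["pa", ]), c(1, 2))
  expect_equal(mean(r["pa", ]), 1.5)
  expect_equal(unname(r["pb", ]), c(0, 0))  # identical profiles

  fx$mat["pa", "WT_untreated_2"] <- NA  # batch 2 dropped for that protein
  r2 <- matched_log2_ratios(fx$mat, fx$design, "ALT_vs_WT", "untreated")
  expect_equal(unname(r2["pa", ]), c(1, NA))
})

test_that("contrasts need two shared batches", {
  fx <- ratio_fixture()
  d1 <- fx$design[fx$design$replicate_batch == 1, ]
  expect_error(matched_log2_ratios(fx$mat[, d1$sample_id], d1,
                                   "ALT_vs_WT", "untreated"),
               "shared replicate batches")
})

test_that("contrast tests flag proteins with insufficient pairs", {
  fx <- ratio_fixture()
  fx$mat["pa", "WT_untreated_2"] <- NA
  ct <- contrast_tests(fx$mat, fx$design, "ALT_vs_WT", "untreated")
  expect_true(ct$insufficient[ct$protein_id == "pa"])
  expect_true(is.na(ct$p_value[ct$protein_id == "pa"]))
  expect_equal(ct$log2FC[ct$protein_id == "pb"], 0)
  expect_equal(ct$p_value[ct$protein_id == "pb"], 1)  # all-zero ratios
})

test_that("reversing a contrast negates log2FC and pi, keeps p", {
  sim <- simulate_apms(small_params(seed = 51), make_design(4, "untreated"))
  rel <- center_batches(log2_transform(sim$abundance), sim$design)
  fwd <- contrast_tests(rel, sim$design, "ALT_vs_WT", "untreated")
  swapped <- sim$design
  swapped$condition[swapped$condition == "ALT"] <- "tmp"
  swapped$condition[swapped$condition == "WT"] <- "ALT"
  swapped$condition[swapped$condition == "tmp"] <- "WT"
  rev <- contrast_tests(rel, swapped, "ALT_vs_WT", "untreated")
  ok <- !fwd$insufficient & !rev$insufficient
  expect_equal(fwd$log2FC[ok], -rev$log2FC[ok])
  expect_equal(fwd$p_value[ok], rev$p_value[ok], tolerance = 1e-12)
  pi_f <- pi_score(fwd$log2FC[ok], fwd$p_value[ok])
  pi_r <- pi_score(rev$log2FC[ok], rev$p_value[ok])
  expect_equal(pi_f, -pi_r)
})

test_that("pi score is the product of effect and -log10 p", {
  expect_equal(pi_score(1, 0.01), 2)
  expect_equal(pi_score(0, 0.001), 0)
  expect_equal(pi_score(-0.5, 0.1), -0.5)
  expect_warning(clamped <- pi_score(1, 0), "clamped")
  expect_true(is.finite(clamped) && clamped > 300)
  expect_error(pi_score(1, 1.5), "0, 1")
})

test_that("pi magnitude grows with effect size and significance", {
  fc <- seq(0.1, 3, by = 0.1)
  expect_true(all(diff(abs(pi_score(fc, 0.01))) > 0))
  p <- 10^seq(-1, -8)
  expect_true(all(diff(abs(pi_score(0.5, p))) > 0))
  expect_true(all(sign(pi_score(c(-2, -0.1, 0.1, 2), 0.05)) ==
                    c(-1, -1, 1, 1)))
})

test_that("ranking is a deterministic permutation with the stated ties", {
  res <- data.frame(protein_id = c("pC", "pA", "pB", "pD", "pE"),
                    contrast = "ALT_vs_WT", treatment = "untreated",
                    n_ratios = 4L,
                    log2FC = c(3, -1, 0.5, 1, 1),
                    t = NA_real_,
                    p_value = c(0.1, 0.1, 0.1, 0.02, 0.02),
                    insufficient = FALSE, stringsAsFactors = FALSE)
  ranked <- rank_binders(res, selected = c("pC", "pA", "pB", "pD", "pE"))
  # pi: pC 3, pB 0.5, pA -1 (at p = .1); pD and pE tie at pi ~ 1.7 with
  # tied p, so lexicographic id order breaks the tie
  expect_equal(ranked$protein_id[1:3], c("pC", "pD", "pE"))
  expect_equal(ranked$rank[match(c("pB", "pA"), ranked$protein_id)],
               c(4L, 5L))
  expect_setequal(ranked$rank, 1:5)

  sub <- rank_binders(res, selected = c("pC", "pB"))
  expect_true(is.na(sub$pi_value[sub$protein_id == "pA"]))
  expect_true(is.na(sub$rank[sub$protein_id == "pA"]))
  expect_setequal(sub$rank[!is.na(sub$rank)], 1:2)

  expect_error(rank_binders(res, "nope"), "subset")
})
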