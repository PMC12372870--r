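test_that("GMT files round-trip and malformed lines are named", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("SetA\tdesc\tp1\tp2",
               "SetB\tother\tp2\tp3\tp3"), path)
  gs <- read_gmt(path)
  expect_setequal(gs$SetA, c("p1", "p2"))
  expect_equal(gs$SetB, c("p2", "p3"))  # duplicate member stored once
  expect_equal(attr(gs, "descriptions")[["SetA"]], "desc")

  writeLines(c("SetA\tdesc\tp1", "Bad\tonly-two-fields"), path)
  expect_error(read_gmt(path), "line 2")

  gs2 <- list(S1 = c("a", "b"), S2 = "c")
  write_gmt(gs2, path)
  back <- read_gmt(path)
  expect_equal(back$S1, c("a", "b"))
  expect_equal(back$S2, "c")
})

test_that("hypergeometric p matches exhaustive enumeration", {
  # the 5-of-5 from a 10-universe case: p = 1/choose(10, 5) = 1/252
  res <- hypergeometric_ora(letters[1:5], letters[1:10],
                            list(S = letters[1:5]))
  expect_equal(res$p_value, 1 / 252)
  expect_equal(res$p_value, oracle_hyper_enum(10, 5, 5, 5), tolerance = 1e-12)

  set.seed(60)
  for (i in 1:20) {
    N <- sample(6:12, 1)
    K <- sample(1:(N - 1), 1)
    n <- sample(1:(N - 1), 1)
    universe <- sprintf("g%02d", 1:N)
    set_members <- universe[1:K]
    selection <- sample(universe, n)
    k <- length(intersect(selection, set_members))
    res <- hypergeometric_ora(selection, universe, list(S = set_members))
    expect_lt(abs(res$p_value - oracle_hyper_enum(N, K, n, k)), 1e-10)
  }
})

test_that("hypergeometric edge cases behave as specified", {
  universe <- sprintf("g%02d", 1:20)
  # zero overlap: P[X >= 0] = 1 exactly
  res0 <- hypergeometric_ora(universe[11:15], universe,
                             list(S = universe[1:5]))
  expect_equal(res0$overlap, 0)
  expect_equal(res0$p_value, 1)
  # saturation: selection = universe forces k = K and p = 1
  res1 <- hypergeometric_ora(universe, universe, list(S = universe[1:7]))
  expect_equal(res1$overlap, 7)
  expect_equal(res1$p_value, 1)

  expect_error(hypergeometric_ora(c("zz"), universe, list(S = universe)),
               "subset")
  # sets with no members in the universe are skipped
  res2 <- hypergeometric_ora(universe[1:3], universe,
                             list(S = universe[1:5], empty = c("xx")))
  expect_equal(res2$set_name, "S")
})

test_that("the upper-tail probabilities are a valid distribution", {
  N <- 12; K <- 5; n <- 6
  pmf <- vapply(0:min(K, n), function(k) {
    choose(K, k) * choose(N - K, n - k) / choose(N, n)
  }, 0)
  expect_lt(abs(sum(pmf) - 1), 1e-12)
  # our tail at k equals the pmf sum from k upward
  for (k in 0:min(K, n)) {
    res <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    expect_lt(abs(res - sum(pmf[(k + 1):length(pmf)])), 1e-12)
  }
})

test_that("enrichment ratio and BH adjustment are emitted", {
  universe <- sprintf("g%02d", 1:40)
  sets <- list(A = universe[1:10], B = universe[11:30])
  res <- hypergeometric_ora(universe[1:10], universe, sets)
  a <- res[res$set_name == "A", ]
  expect_equal(a$enrichment_ratio, (10 / 10) / (10 / 40))
  expect_true(all(res$p_adj >= res$p_value - 1e-15))
})

test_that("top-pi selection feeds ORA with the ranked head or tail", {
  res <- data.frame(protein_id = sprintf("p%02d", 1:20),
                    contrast = "ALT_vs_WT", treatment = "untreated",
                    n_ratios = 4L, log2FC = seq(2, -2, length.out = 20),
                    t = NA_real_, p_value = rep(0.01, 20),
                    insufficient = FALSE, stringsAsFactors = FALSE)
  ranked <- rank_binders(res, res$protein_id)
  sets <- list(head_set = sprintf("p%02d", 1:5),
               tail_set = sprintf("p%02d", 16:20))
  top <- ora_top_pi(ranked, sets, top_n = 5, direction = "top")
  expect_equal(top$set_name[1], "head_set")
  expect_equal(top$overlap[top$set_name == "head_set"], 5)
  bottom <- ora_top_pi(ranked, sets, top_n = 5, direction = "bottom")
  expect_equal(bottom$set_name[1], "tail_set")
})
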