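mk_expr <- function(values, hk = character()) {
  expr_matrix(values, housekeeping = hk)
}

test_that("housekeeping normalization zeroes the panel mean per sample", {
  set.seed(3)
  m <- matrix(rnorm(50 * 4, 6, 2), 50, 4,
              dimnames = list(sprintf("G%02d", 1:50), paste0("s", 1:4)))
  hk <- sprintf("G%02d", 1:10)
  em <- housekeeping_normalize(mk_expr(m, hk))
  expect_equal(unname(colMeans(em$values[hk, ])), rep(0, 4),
               tolerance = 1e-12)
})

test_that("normalization removes a per-sample shift exactly", {
  set.seed(4)
  m <- matrix(rnorm(20 * 3), 20, 3,
              dimnames = list(sprintf("G%02d", 1:20), paste0("s", 1:3)))
  hk <- sprintf("G%02d", 1:5)
  base <- housekeeping_normalize(mk_expr(m, hk))
  shifted <- m; shifted[, 2] <- shifted[, 2] + 3.7
  shifted_norm <- housekeeping_normalize(mk_expr(shifted, hk))
  expect_equal(shifted_norm$values, base$values, tolerance = 1e-12)
  # a sample whose housekeeping mean is already zero is untouched
  m0 <- sweep(m, 2, colMeans(m[hk, ]), `-`)
  expect_equal(housekeeping_normalize(mk_expr(m0, hk))$values, m0,
               tolerance = 1e-12)
})

test_that("empty housekeeping set is an error", {
  m <- matrix(1:4, 2, 2, dimnames = list(c("a", "b"), c("x", "y")))
  expect_error(housekeeping_normalize(mk_expr(m + 0)), "empty")
})

test_that("Welch statistic matches the hand-computed formula on a toy set", {
  a <- c(1, 2, 3); b <- c(2, 4, 9)
  # Welch: t = (mean a - mean b) / sqrt(va/na + vb/nb), Satterthwaite df
  va <- var(a); vb <- var(b)
  tstat <- (mean(a) - mean(b)) / sqrt(va / 3 + vb / 3)
  df <- (va / 3 + vb / 3)^2 / ((va / 3)^2 / 2 + (vb / 3)^2 / 2)
  p_hand <- 2 * pt(-abs(tstat), df)
  tt <- t.test(a, b)
  expect_equal(unname(tt$statistic), tstat, tolerance = 1e-12)
  expect_equal(tt$p.value, p_hand, tolerance = 1e-12)
})

sim_state_expr <- function(n_per = 500, seed = 1) {
  set.seed(seed)
  means <- c(K4 = 10, BIVALENT = 8, NONE = 5.5, K27 = 5)
  states <- rep(names(means), each = n_per)
  ids <- sprintf("G%05d", seq_along(states))
  vals <- matrix(rnorm(length(ids) * 2, means[states], 1), ncol = 2,
                 dimnames = list(ids, c("s1", "s2")))
  list(em = expr_matrix(vals), states = setNames(states, ids))
}

test_that("planted state means yield the expected ordering and p < 0.001", {
  sim <- sim_state_expr()
  sx <- stratify_and_test(sim$em, sim$states)
  expect_true(sx$ordering_ok)
  sts <- c("K4", "K27", "BIVALENT", "NONE")
  pw <- sx$pairwise[sts, sts]
  expect_true(all(pw[upper.tri(pw)] < 0.001))
  expect_equal(sum(sx$groups$n[sx$groups$state != "ALL"]),
               sx$groups$n[sx$groups$state == "ALL"])
})

test_that("stratification is invariant to gene order", {
  sim <- sim_state_expr(n_per = 50)
  perm <- sample(length(sim$states))
  em2 <- expr_matrix(sim$em$values[perm, , drop = FALSE])
  sx1 <- stratify_and_test(sim$em, sim$states)
  sx2 <- stratify_and_test(em2, sim$states[perm])
  expect_equal(sx1$groups, sx2$groups)
  expect_equal(sx1$pairwise, sx2$pairwise)
})

test_that("identical constant groups have equal medians and no ordering", {
  ids <- sprintf("G%02d", 1:40)
  vals <- matrix(5, 40, 2, dimnames = list(ids, c("s1", "s2")))
  states <- setNames(rep(c("K4", "K27", "BIVALENT", "NONE"), 10), ids)
  sx <- stratify_and_test(expr_matrix(vals), states)
  expect_false(sx$ordering_ok)
  meds <- sx$groups$median
  expect_true(all(meds == 5))
  # zero-variance pairs cannot be tested: reported absent, not zero
  expect_true(all(is.na(sx$pairwise[upper.tri(sx$pairwise)])))
})

test_that("groups with fewer than two genes report absent tests", {
  ids <- c("G1", "G2", "G3", "G4", "G5")
  vals <- matrix(c(1, 2, 3, 4, 10), 5, 1, dimnames = list(ids, "s1"))
  states <- setNames(c("K4", "K4", "NONE", "NONE", "K27"), ids)
  sx <- stratify_and_test(expr_matrix(vals), states)
  expect_true(is.na(sx$pairwise["K4", "K27"]))
  expect_false(is.na(sx$pairwise["K4", "NONE"]))
})

test_that("genes without expression are excluded and counted", {
  ids <- c("G1", "G2", "G3")
  vals <- matrix(1:2, 2, 1, dimnames = list(ids[1:2], "s1"))
  states <- setNames(c("K4", "K4", "NONE"), ids)
  sx <- stratify_and_test(expr_matrix(vals + 0), states)
  expect_equal(sx$n_missing_expression, 1L)
  expect_equal(sx$groups$n[sx$groups$state == "NONE"], 0L)
})

test_that("pairwise testing is calibrated under the null", {
  # equal-mean groups through the stratification surface: the K4-vs-K27
  # p-value rejects at ~ alpha
  set.seed(99)
  n_rep <- 2000
  ids <- sprintf("G%02d", 1:40)
  states <- setNames(rep(c("K4", "K27"), each = 20), ids)
  pvals <- vapply(seq_len(n_rep), function(i) {
    vals <- matrix(rnorm(40), 40, 1, dimnames = list(ids, "s1"))
    stratify_and_test(expr_matrix(vals), states)$pairwise["K4", "K27"]
  }, 0)
  expect_lt(abs(mean(pvals < 0.05) - 0.05), 3 * sqrt(0.05 * 0.95 / n_rep))
  expect_gt(mean(pvals), 0.45)  # null p-values are uniform on average
})
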