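test_that("zone z-scores standardize each gene across zones", {
  zm <- rbind(g1 = c(1, 2, 3), g2 = c(5, 5, 5))
  z <- zone_zscore(zm)
  expect_equal(unname(z["g1", ]), c(-1, 0, 1))  # sample sd = 1
  expect_equal(unname(z["g2", ]), c(0, 0, 0))   # degenerate sd rule
  set.seed(6)
  zr <- zone_zscore(matrix(rnorm(40), 8, 5))
  expect_equal(unname(rowMeans(zr)), rep(0, 8), tolerance = 1e-12)
  expect_equal(unname(apply(zr, 1, sd)), rep(1, 8), tolerance = 1e-12)
  expect_error(zone_zscore(matrix(1:5, 5, 1)), ">= 2 zones")
})

test_that("two-variable correlation PCA follows the closed form exactly", {
  # r = 0 is excluded: the identity correlation matrix has a degenerate
  # eigenbasis, so no particular F1 direction is forced
  for (r in c(0.5, 0.9)) {
    m <- exact_corr_pair(200, r, seed = 17)
    p <- pca_circle(m)
    expect_equal(abs(unname(p$var_cor[, "F1"])), rep(sqrt((1 + r) / 2), 2),
                 tolerance = 1e-9)
    expect_equal(unname(p$explained), c((1 + r) / 2, (1 - r) / 2),
                 tolerance = 1e-9)
  }
})

test_that("sampled two-variable PCA approaches the closed form at large n", {
  set.seed(23)
  n <- 1e5; r <- 0.5
  x <- rnorm(n)
  m <- cbind(A = x, B = r * x + sqrt(1 - r^2) * rnorm(n))
  p <- pca_circle(m)
  expect_equal(abs(unname(p$var_cor[, "F1"])), rep(sqrt((1 + r) / 2), 2),
               tolerance = 0.01)
})

test_that("duplicated variables share circle coordinates", {
  set.seed(12)
  x <- rnorm(50)
  m <- cbind(A = x, B = 2 * x + 1, C = rnorm(50))  # B is affine in A
  p <- pca_circle(m)
  expect_equal(p$var_cor["A", ], p$var_cor["B", ], tolerance = 1e-9)
})

test_that("explained variance is non-increasing and sums to one", {
  set.seed(13)
  m <- matrix(rnorm(30 * 5), 30, 5)
  p <- pca_circle(m)
  expect_equal(sum(p$explained), 1, tolerance = 1e-12)
  expect_true(all(diff(p$explained) <= 1e-12))
  # per-variable F1^2 + F2^2 <= 1
  expect_true(all(rowSums(p$var_cor[, 1:2]^2) <= 1 + 1e-9))
})

test_that("circle coordinates are invariant to affine rescaling", {
  set.seed(14)
  m <- matrix(rnorm(40 * 4), 40, 4,
              dimnames = list(NULL, paste0("V", 1:4)))
  p1 <- pca_circle(m)
  m2 <- m
  m2[, 2] <- 5 * m2[, 2] - 3
  m2[, 4] <- 0.1 * m2[, 4] + 100
  p2 <- pca_circle(m2)
  expect_equal(p1$var_cor, p2$var_cor, tolerance = 1e-9)
})

test_that("component sign convention is deterministic", {
  set.seed(15)
  m <- matrix(rnorm(30 * 3), 30, 3, dimnames = list(NULL, c("A", "B", "C")))
  p1 <- pca_circle(m)
  p2 <- pca_circle(-m)  # flips every loading; convention restores signs
  expect_equal(abs(p1$var_cor), abs(p2$var_cor), tolerance = 1e-9)
  # lexicographically smallest variable has positive F1 correlation
  expect_gte(p1$var_cor["A", "F1"], 0)
})

test_that("zero-variance variables are rejected by name", {
  m <- cbind(A = rnorm(10), BAD = rep(2, 10))
  expect_error(pca_circle(m), "BAD")
})

test_that("covariation score behaves as a cosine similarity", {
  # hand-built circle coordinates via a rank-2 construction
  set.seed(16)
  base <- matrix(rnorm(200 * 2), 200, 2)
  dirs <- rbind(Q = c(1, 0), S1 = c(1, 0.1), S2 = c(1, -0.1),
                ORTH = c(0, 1))
  m <- base %*% t(dirs) + matrix(rnorm(200 * 4, 0, 0.01), 200, 4)
  colnames(m) <- rownames(dirs)
  p <- pca_circle(m)
  cv <- covariation_score(p, "Q", c("S1", "S2"))
  expect_gt(cv$score, 0.99)
  expect_true(cv$f1_sign_agreement)
  cv_orth <- covariation_score(p, "ORTH", c("S1", "S2"))
  expect_lt(abs(cv_orth$score), 0.1)
  expect_error(covariation_score(p, "NOPE", "S1"), "query")
  expect_error(covariation_score(p, "Q", "NOPE"), "signature")
})

test_that("query built as signature mean plus small noise scores > 0.9", {
  set.seed(18)
  n <- 200
  sig <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("S", 1:5)))
  sig <- sig + rnorm(n)  # shared component so the signature co-varies
  query <- rowMeans(sig) + rnorm(n, 0, 0.1)
  m <- cbind(sig, Q = query)
  p <- pca_circle(m)
  cv <- covariation_score(p, "Q", paste0("S", 1:5))
  expect_gt(cv$score, 0.9)
})

test_that("covariation score is invariant under joint rotation of vectors", {
  p <- list(var_cor = rbind(Q = c(0.8, 0.2), S1 = c(0.7, 0.3),
                            S2 = c(0.9, 0.1)))
  colnames(p$var_cor) <- c("F1", "F2")
  class(p) <- "pca_circle"
  s0 <- covariation_score(p, "Q", c("S1", "S2"))$score
  th <- 0.7
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  p2 <- p
  p2$var_cor <- p$var_cor %*% rot
  colnames(p2$var_cor) <- c("F1", "F2")
  s1 <- covariation_score(p2, "Q", c("S1", "S2"))$score
  expect_equal(s0, s1, tolerance = 1e-12)
})
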