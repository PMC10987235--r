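test_that("correlation_from_cov matches its definition", {
  m <- matrix(c(4, 6, 6, 9), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(correlation_from_cov(m, "a", "b"), 1.0)
  m[1, 2] <- m[2, 1] <- 0
  expect_equal(correlation_from_cov(m, 1, 2), 0)
  m2 <- matrix(c(1, 0.19, 0.19, 1), 2)
  expect_equal(correlation_from_cov(m2, 1, 2), 0.19)
  m2[1, 1] <- 0
  expect_error(correlation_from_cov(m2, 1, 2), "zero variance")
  # applied to a correlation matrix it is the identity on off-diagonals
  r <- matrix(c(1, -0.4, -0.4, 1), 2)
  expect_equal(correlation_from_cov(r, 1, 2), -0.4)
  # per-draw over an array
  a <- array(c(m2 * 0 + diag(2), r), dim = c(2, 2, 2))
  expect_equal(correlation_from_cov(a, 1, 2), c(0, -0.4))
})

test_that("repeatability follows the default denominator and is scale invariant", {
  expect_equal(repeatability(1, 0, 1), 0.5)
  expect_equal(repeatability(0, 1, 1), 0)
  expect_equal(repeatability(2, 1, 1), 0.5)
  expect_equal(repeatability(2, 1, 1, v_assay = 1), 0.4)
  c_ <- 3.7
  expect_equal(repeatability(2 * c_, 1 * c_, 1 * c_), repeatability(2, 1, 1))
  expect_error(repeatability(-1, 1, 1), "non-negative")
})

test_that("partial regression on survival solves the normal equations", {
  # orthogonal predictors: beta_j = cov_js / var_j
  m <- diag(c(2, 5, 1))
  m[1, 3] <- m[3, 1] <- 0.4
  m[2, 3] <- m[3, 2] <- -1
  dimnames(m) <- rep(list(c("p1", "p2", "s")), 2)
  b <- partial_regression_on_survival(m, c("p1", "p2"), "s")
  expect_equal(unname(b), c(0.4 / 2, -1 / 5))
  # hand-solved 2x2 system
  m2 <- matrix(0, 3, 3, dimnames = rep(list(c("p1", "p2", "s")), 2))
  m2[1:2, 1:2] <- matrix(c(1, 0.5, 0.5, 1), 2)
  m2[3, 3] <- 1
  m2[1:2, 3] <- m2[3, 1:2] <- 0.5
  expect_equal(unname(partial_regression_on_survival(m2, 1:2, 3)),
               c(1 / 3, 1 / 3))
  # zero predictor-survival covariance gives zero coefficients
  m2[1:2, 3] <- m2[3, 1:2] <- 0
  expect_equal(unname(partial_regression_on_survival(m2, 1:2, 3)), c(0, 0))
})

test_that("partial regression agrees with a brute-force latent-sample regression", {
  set.seed(10)
  S <- matrix(c(1.0, 0.3, 0.1, -0.3,
                0.3, 0.8, 0.2, -0.25,
                0.1, 0.2, 0.6, 0.15,
                -0.3, -0.25, 0.15, 1.0), 4, 4)
  dimnames(S) <- rep(list(c("rltl", "fec", "igg_tc", "survival")), 2)
  beta_cov <- partial_regression_on_survival(S, 1:3, 4)
  z <- MASS::mvrnorm(400000, rep(0, 4), S)
  beta_lm <- coef(lm(z[, 4] ~ z[, 1:3]))[-1]
  expect_equal(unname(beta_cov), unname(beta_lm), tolerance = 0.01)
})

test_that("singular draws are skipped and counted", {
  good <- diag(3); good[1, 3] <- good[3, 1] <- 0.2
  sing <- matrix(1, 3, 3)   # predictors perfectly collinear
  a <- array(c(good, sing), dim = c(3, 3, 2),
             dimnames = c(rep(list(c("p1", "p2", "s")), 2), list(NULL)))
  res <- partial_regression_on_survival(a, c("p1", "p2"), "s")
  expect_identical(attr(res, "n_skipped"), 1L)
  expect_identical(nrow(res), 1L)
})

test_that("negating a trait flips correlations and survival gradients but not repeatability", {
  set.seed(11)
  K <- 3
  base <- crossprod(matrix(rnorm(9), 3)) + diag(3)
  dimnames(base) <- rep(list(c("rltl", "fec", "survival")), 2)
  flip <- diag(c(-1, 1, 1))
  neg <- flip %*% base %*% flip
  dimnames(neg) <- dimnames(base)
  expect_equal(correlation_from_cov(neg, "rltl", "fec"),
               -correlation_from_cov(base, "rltl", "fec"))
  b0 <- partial_regression_on_survival(base, c("rltl", "fec"), "survival")
  b1 <- partial_regression_on_survival(neg, c("rltl", "fec"), "survival")
  expect_equal(unname(b1), unname(b0) * c(-1, 1))
  expect_equal(repeatability(neg["rltl", "rltl"], 0.3, 0.5),
               repeatability(base["rltl", "rltl"], 0.3, 0.5))
})
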