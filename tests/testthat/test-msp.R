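# Multiple sparse priors: smoothing matrix, prior centers, ReML inversion.

toy_lf <- function() rand_leadfield(8, 12, seed = 42, scale = FALSE)

test_that("smoothing matrix follows the exponential-series definition", {
  # no neighbors: identity
  A0 <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                             dims = c(5, 5))
  G0 <- build_smoothing_matrix(A0)
  expect_equal(as.matrix(G0$G), diag(5), ignore_attr = TRUE)
  # 3-node chain vs dense brute-force matrix powers
  A <- Matrix::sparseMatrix(i = c(1, 2, 2, 3), j = c(2, 1, 3, 2), x = 1)
  G <- build_smoothing_matrix(A, sigma = 0.6, order = 8)
  Ad <- as.matrix(A)
  Gd <- diag(3)
  P <- diag(3)
  for (i in 1:8) {
    P <- P %*% Ad
    Gd <- Gd + 0.6^i / factorial(i) * P
  }
  expect_equal(as.matrix(G$G), Gd, tolerance = 1e-12, ignore_attr = TRUE)
  expect_gte(min(Matrix::diag(G$G)), 1)
  expect_error(build_smoothing_matrix(A, order = -1), "order")
})

test_that("smoothing support is capped at the hop order", {
  # 12-node chain: node 1 reaches node 9 in 8 hops, node 10 never
  n <- 12
  A <- Matrix::sparseMatrix(i = c(1:(n - 1), 2:n), j = c(2:n, 1:(n - 1)),
                            x = 1)
  G <- build_smoothing_matrix(A, sigma = 0.6, order = 8)
  Gd <- as.matrix(G$G)
  expect_gt(Gd[1, 9], 0)
  expect_equal(Gd[1, 10], 0)
  expect_equal(Gd[1, 12], 0)
})

test_that("prior centers are unique, quasi-uniform and hemisphere-balanced", {
  src <- make_sphere_source_space(72, 200, seed = 2)
  ss <- src$source_space
  expect_equal(select_prior_centers(ss, 200), 1:200)  # n = D: all dipoles
  expect_error(select_prior_centers(ss, 201), "exceeds")
  cen <- select_prior_centers(ss, 40, seed = 3)
  expect_equal(anyDuplicated(cen), 0)
  hl <- table(ss$hemisphere[cen])
  expect_true(all(hl >= 10))  # both hemispheres covered proportionally
  # farthest-point spread beats uniform-random selection (Monte Carlo)
  pos <- ss$positions
  mind <- function(idx) min(dist(pos[idx, ]))
  wins <- vapply(1:20, function(s) {
    fps <- select_prior_centers(ss, 30, seed = s)
    set.seed(s)
    rnd <- sample(200, 30)
    c(mind(fps), mind(rnd))
  }, numeric(2))
  expect_gte(mean(wins[1, ] >= wins[2, ]), 0.9)
  expect_gt(median(wins[1, ]), median(wins[2, ]))
})

test_that("zero data give zero source estimates", {
  lf <- toy_lf()
  pri <- prior_set(Matrix::Diagonal(12), c(1, 5, 9))
  res <- suppressWarnings(msp_invert(matrix(0, 8, 10), lf, pri))
  expect_equal(res$E, matrix(0, 12, 10), ignore_attr = TRUE)
})

test_that("data generated from one prior select it and stay on its support", {
  lf <- toy_lf()
  src <- make_sphere_source_space(72, 12, seed = 2)
  G <- build_smoothing_matrix(src$adjacency)
  pri <- prior_set(G, c(1, 4, 7, 10))
  g <- as.numeric(pri$columns[, 2])
  Y <- lf$matrix %*% (g %o% sin(seq(0, 3, length.out = 40))) * 2
  res <- msp_invert(Y, lf, pri)
  expect_true(res$converged)
  expect_equal(which.max(res$lambda[-1]), 2, ignore_attr = TRUE)
  sup <- which(g != 0)
  expect_gte(sum(res$E[sup, ]^2) / sum(res$E^2), 0.99)
  # free energy is non-decreasing
  expect_true(all(diff(res$free_energy) > -1e-8))
})

test_that("with one all-ones prior and fixed weights the MAP operator is ridge", {
  lf <- toy_lf()
  D <- 12; L <- 8
  pri <- prior_set(Matrix::Matrix(rep(1, D), ncol = 1, sparse = TRUE), 1L)
  set.seed(9)
  Y <- matrix(rnorm(L * 20), L, 20)
  Y <- sweep(Y, 2, colMeans(Y))
  lam <- c(log(0.3), log(2))
  res <- msp_invert(Y, lf, pri, temporal_modes = NULL, scale_data = FALSE,
                    lambda_init = lam, lambda_fixed = c(TRUE, TRUE),
                    max_iter = 1)
  B <- hexsource:::avg_ref_basis(L)
  Lt <- crossprod(B, lf$matrix)
  Q <- exp(lam[2]) * tcrossprod(rep(1, D))
  Mref <- Q %*% t(Lt) %*%
    solve(Lt %*% Q %*% t(Lt) + exp(lam[1]) * diag(L - 1)) %*% t(B)
  expect_equal(res$M, Mref, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("source estimates are linear in the data for a fixed operator", {
  lf <- toy_lf()
  pri <- prior_set(Matrix::Diagonal(12), c(2, 6, 11))
  set.seed(10)
  Y <- matrix(rnorm(8 * 15), 8, 15)
  res <- msp_invert(Y, lf, pri)
  expect_equal(res$E, res$M %*% Y, tolerance = 1e-12)
  expect_equal(res$M %*% (2 * Y), 2 * (res$M %*% Y), tolerance = 1e-12)
})

test_that("hyperparameter recovery identifies the active priors", {
  lf <- toy_lf()
  L <- 8; n <- 7
  Gs <- Matrix::Matrix(diag(12)[, seq(1, 12, 2)], sparse = TRUE)
  pri <- prior_set(Gs, seq(1, 12, 2))
  B <- hexsource:::avg_ref_basis(L)
  Lt <- crossprod(B, lf$matrix)
  hits <- vapply(1:50, function(s) {
    set.seed(s)
    act <- sample(6, 2)
    Sig <- 0.01 * diag(n)
    for (a in act) {
      u <- as.numeric(Lt %*% Gs[, a])
      Sig <- Sig + tcrossprod(u)
    }
    Yt <- t(chol(Sig)) %*% matrix(rnorm(n * 50), n, 50)
    res <- suppressWarnings(msp_invert(B %*% Yt, lf, pri))
    setequal(order(res$lambda[-1], decreasing = TRUE)[1:2], act)
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("snapshots index the estimate matrix and validate the time index", {
  lf <- toy_lf()
  pri <- prior_set(Matrix::Diagonal(12), c(1, 6))
  set.seed(13)
  Y <- matrix(rnorm(8 * 9), 8, 9)
  res <- suppressWarnings(msp_invert(Y, lf, pri))
  s <- msp_snapshot(res, 4)
  expect_equal(s$values, as.numeric(res$M %*% Y[, 4]), tolerance = 1e-12)
  expect_equal(s$solver, "msp")
  expect_error(msp_snapshot(res, 0), "range")
  expect_error(msp_snapshot(res, 10), "range")
  expect_error(msp_invert(matrix(NA_real_, 8, 2), lf, pri), "NA")
})
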