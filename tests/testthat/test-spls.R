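test_that("soft-thresholding obeys its defining identities", {
  expect_equal(soft_threshold(5, 2), 3)
  expect_equal(soft_threshold(-5, 2), -3)
  y <- c(-3.2, -1, 0, 0.5, 7)
  expect_equal(soft_threshold(y, 0), y)
  expect_equal(soft_threshold(y, 2), sign(y) * pmax(abs(y) - 2, 0))
  # boundary ties go to zero
  expect_identical(soft_threshold(c(2, -2), 2), c(0, 0))
  expect_error(soft_threshold(1, -0.1), "nonnegative")
})

test_that("number of survivors is nonincreasing in the penalty", {
  set.seed(7)
  for (rep in 1:5) {
    y <- rnorm(50)
    lams <- sort(runif(20, 0, max(abs(y))))
    nz <- vapply(lams, function(l) sum(soft_threshold(y, l) != 0), 1L)
    expect_true(all(diff(nz) <= 0))
  }
})

test_that("unpenalized component equals the leading singular pair of X'Y", {
  set.seed(101)
  for (rep in 1:20) {
    n <- sample(8:15, 1); p <- sample(3:8, 1); q <- sample(3:9, 1)
    X <- matrix(rnorm(n * p), n, p)
    Y <- matrix(rnorm(n * q), n, q)
    Xc <- scale(X, scale = FALSE); Yc <- scale(Y, scale = FALSE)
    f <- spls_component(Xc, Yc)
    sv <- svd(crossprod(Xc, Yc))
    # align signs before comparing
    s <- sign(sum(f$u * sv$u[, 1]))
    expect_equal(f$u, s * sv$u[, 1], tolerance = 1e-8)
    expect_equal(f$v, s * sv$v[, 1], tolerance = 1e-8)
    expect_equal(sqrt(sum(f$u^2)), 1, tolerance = 1e-12)
    expect_equal(sqrt(sum(f$v^2)), 1, tolerance = 1e-12)
  }
})

test_that("penalized supports stay inside the true rank-1 supports", {
  # noiseless rank-1 cross-product: orthonormal X columns make
  # X'Y = 3 u0 v0' exactly, with sparse u0, v0
  u0 <- c(0.8, 0.6, 0, 0, 0)
  v0 <- c(0, 0.6, -0.8, 0)
  set.seed(11)
  X <- qr.Q(qr(matrix(rnorm(40 * 5), 40, 5)))
  Y <- (X %*% u0) %*% t(v0) * 3
  expect_equal(crossprod(X, Y), 3 * u0 %o% v0, tolerance = 1e-12)
  f <- spls_component(X, Y, lamX = 0.5, lamY = 0.3)
  expect_true(all(which(f$u != 0) %in% which(u0 != 0)))
  expect_true(all(which(f$v != 0) %in% which(v0 != 0)))
  expect_gt(sum(f$u != 0), 0)
})

test_that("degenerate and over-penalized inputs fail loudly", {
  X <- matrix(rnorm(20), 10, 2)
  Y0 <- matrix(0, 10, 3)
  expect_error(spls_component(X, Y0), "zero")
  set.seed(2)
  Y <- matrix(rnorm(30), 10, 3)
  Xc <- scale(X, scale = FALSE); Yc <- scale(Y, scale = FALSE)
  big <- 10 * max(abs(crossprod(Xc, Yc)))
  expect_error(spls_component(Xc, Yc, lamX = big), "X block")
  expect_error(spls_component(Xc, Yc, lamY = big), "Y block")
})

test_that("deflation leaves both blocks orthogonal to the score", {
  set.seed(21)
  for (rep in 1:10) {
    toy <- make_toy_blocks(seed = rep)
    f <- spls_component(toy$Xc, toy$Yc, lamX = 0.1, lamY = 0.1)
    d <- deflate(toy$Xc, toy$Yc, f)
    relx <- sqrt(sum(crossprod(d$X, f$t)^2)) /
      (sqrt(sum(f$t^2)) * sqrt(sum(toy$Xc^2)))
    rely <- sqrt(sum(crossprod(d$Y, f$t)^2)) /
      (sqrt(sum(f$t^2)) * sqrt(sum(toy$Yc^2)))
    expect_lt(relx, 1e-8)
    expect_lt(rely, 1e-8)
  }
  toy <- make_toy_blocks()
  f <- spls_component(toy$Xc, toy$Yc)
  f$t <- f$t * 0
  expect_error(deflate(toy$Xc, toy$Yc, f), "zero score")
})

test_that("multi-component fit reproduces exact low-rank data", {
  set.seed(31)
  n <- 20; p <- 6; q <- 8
  Tm <- matrix(rnorm(n * 2), n, 2)
  Qm <- matrix(rnorm(q * 2), q, 2)
  Pm <- matrix(rnorm(p * 2), p, 2)
  X <- Tm %*% t(Pm) + 1e-4 * matrix(rnorm(n * p), n, p)  # keep X full rank
  Y <- Tm %*% t(Qm)
  m <- fit_spls(X, Y, k = 2)
  Yc <- scale(Y, scale = FALSE)
  Xc <- scale(X, scale = FALSE)
  expect_equal(Xc %*% m$C, m$T %*% t(m$Q), tolerance = 1e-8)
  resid <- Yc - m$T %*% t(m$Q)
  expect_lt(max(abs(resid)) / max(abs(Yc)), 1e-4)
})

test_that("coefficients, prediction and sign convention are consistent", {
  toy <- make_toy_blocks(n = 15, p = 6, q = 5, seed = 41)
  m <- fit_spls(toy$X, toy$Y, k = 3)
  # fitted values via C match the score-loading form on the training data
  expect_equal(toy$Xc %*% m$C, m$T %*% t(m$Q), tolerance = 1e-10)
  # predicting the training data reproduces fitted values + Y centres
  expect_equal(predict(m, toy$X),
               m$T %*% t(m$Q) + rep(1, 15) %o% colMeans(toy$Y),
               tolerance = 1e-10)
  # a centred-zero row predicts the training column means
  expect_equal(drop(predict(m, colMeans(toy$X))), colMeans(toy$Y))
  # hand-sized product check
  m1 <- fit_spls(toy$X, toy$Y, k = 1)
  xnew <- toy$X[3, ]
  expect_equal(drop(predict(m1, xnew)),
               drop((xnew - colMeans(toy$X)) %*% m1$C) + colMeans(toy$Y))
  # deterministic output: the largest-|.| entry of each u column is positive
  for (j in seq_len(m$k)) expect_gt(m$U[which.max(abs(m$U[, j])), j], 0)
  m2 <- fit_spls(toy$X, toy$Y, k = 3)
  expect_identical(m$U, m2$U)
  # unit norms after thresholding and renormalization
  m3 <- fit_spls(toy$X, toy$Y, lamX = 0.5, lamY = 0.5, k = 2)
  expect_equal(colSums(m3$U^2), rep(1, 2), tolerance = 1e-12)
  expect_equal(colSums(m3$V^2), rep(1, 2), tolerance = 1e-12)
})

test_that("k limits and dimension mismatches are rejected", {
  toy <- make_toy_blocks(n = 6, p = 4, q = 3)
  expect_error(fit_spls(toy$X, toy$Y, k = 0), "at least 1")
  expect_error(fit_spls(toy$X, toy$Y, k = 4), "exceeds")
  m <- fit_spls(toy$X, toy$Y, k = 2)
  expect_error(predict(m, matrix(0, 2, 5)), "columns")
  expect_error(fit_spls(toy$X, toy$Y[-1, ], k = 1), "same number of rows")
})

test_that("first component agrees with an independent sPLS implementation", {
  skip_if_not_installed("mixOmics")
  set.seed(51)
  X <- matrix(rnorm(30 * 6), 30, 6)
  Y <- X %*% matrix(rnorm(6 * 8), 6, 8) + matrix(rnorm(30 * 8), 30, 8)
  ours <- fit_spls(X, Y, k = 1)
  theirs <- mixOmics::spls(X, Y, ncomp = 1, mode = "regression",
                           scale = FALSE)
  u_ref <- theirs$loadings$X[, 1]
  v_ref <- theirs$loadings$Y[, 1]
  s <- sign(sum(ours$U[, 1] * u_ref))
  expect_equal(ours$U[, 1], s * unname(u_ref) / sqrt(sum(u_ref^2)),
               tolerance = 1e-6)
  expect_equal(ours$V[, 1], s * unname(v_ref) / sqrt(sum(v_ref^2)),
               tolerance = 1e-6)
})
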