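# Normalization layers: centering, batch normalization, iterative batch
# whitening (forward, inference statistics, exact gradients), unrolling.

test_that("centering removes row means exactly", {
  set.seed(1)
  X <- matrix(rnorm(5 * 40), 5, 40)
  cn <- center(X)
  expect_lt(max(abs(rowSums(cn$XC))), 1e-10 * 40 * max(abs(X)))
  expect_equal(cn$mu, rowMeans(X))

  X0 <- X - rowMeans(X)
  expect_equal(center(X0)$XC, X0)
  expect_equal(center(X0)$mu, rep(0, 5))

  Xc <- matrix(3, 4, 7)
  expect_true(all(center(Xc)$XC == 0))
  expect_equal(center(Xc)$mu, rep(3, 4))
})

test_that("batch normalization matches an elementwise loop oracle", {
  set.seed(2)
  d <- 4L; m <- 64L
  X <- matrix(rnorm(d * m, sd = 2), d, m) + 1:d
  st <- bn_state(d)
  st$alpha <- runif(d, 0.5, 2); st$beta <- rnorm(d)
  out <- batch_norm(X, st, training = TRUE)$output
  ref <- matrix(0, d, m)
  for (i in seq_len(d)) {
    mu <- mean(X[i, ])
    s2 <- mean((X[i, ] - mu)^2)          # 1/m convention
    for (j in seq_len(m))
      ref[i, j] <- st$alpha[i] * (X[i, j] - mu) / sqrt(s2 + st$eps) +
        st$beta[i]
  }
  expect_equal(out, ref, tolerance = 1e-10)
})

test_that("batch normalization affine contract and identity behavior", {
  set.seed(3)
  d <- 3L; m <- 200L
  Z <- matrix(rnorm(d * m), d, m)
  Z <- (Z - rowMeans(Z)) / sqrt(rowMeans((Z - rowMeans(Z))^2))
  st <- bn_state(d, eps = 1e-12)
  expect_equal(batch_norm(Z, st, TRUE)$output, Z, tolerance = 1e-6)

  st2 <- bn_state(d)
  st2$alpha <- rep(2, d); st2$beta <- rep(5, d)
  out <- batch_norm(matrix(rnorm(d * m, sd = 3), d, m), st2, TRUE)$output
  expect_equal(rowMeans(out), rep(5, d), tolerance = 1e-9)
  expect_equal(apply(out, 1, sd) * sqrt((m - 1) / m), rep(2, d),
               tolerance = 1e-3)
  expect_error(batch_norm(matrix(1, 2, 1), bn_state(2), TRUE), "m >= 2")
})

test_that("batch normalization gradients match finite differences", {
  set.seed(4)
  d <- 3L; m <- 10L
  X <- matrix(rnorm(d * m), d, m)
  st <- bn_state(d)
  st$alpha <- runif(d, 0.5, 2); st$beta <- rnorm(d)
  G <- matrix(rnorm(d * m), d, m)
  fw <- batch_norm(X, st, TRUE)
  gX <- batch_norm_backward(fw$cache, G)$gX
  h <- 1e-6
  num <- matrix(0, d, m)
  for (i in seq_len(d)) for (j in seq_len(m)) {
    Xp <- X; Xp[i, j] <- Xp[i, j] + h
    Xm <- X; Xm[i, j] <- Xm[i, j] - h
    num[i, j] <- (sum(G * batch_norm(Xp, st, TRUE)$output) -
                    sum(G * batch_norm(Xm, st, TRUE)$output)) / (2 * h)
  }
  expect_lt(max(abs(gX - num)) / max(abs(num)), 1e-5)
})

test_that("whitening an already-white batch is the identity transform", {
  set.seed(5)
  d <- 4L; m <- 256L
  X0 <- matrix(rnorm(d * m), d, m)
  X <- eigen_whitening_oracle(X0, eps = 0)$XW   # exactly unit covariance
  r <- iternorm_whiten(X, iternorm_state(d, K = 20L, affine = FALSE), TRUE)
  expect_lt(max(abs(r$W - diag(d))), 1e-3)
  expect_lt(max(abs(r$XW - X)), 1e-3)
})

test_that("Newton whitening matches the eigen-decomposition oracle", {
  set.seed(6)
  for (d in c(2L, 4L, 8L, 16L)) {
    m <- 64L * d
    X <- random_batch(d, m)
    r <- iternorm_whiten(X, iternorm_state(d, K = 20L, affine = FALSE), TRUE)
    or <- eigen_whitening_oracle(X)
    expect_lt(max(abs(r$W - or$W)), 1e-4)
    cov <- tcrossprod(r$XW) / m
    expect_lt(norm(cov - diag(d), "F"), 0.05)
  }
})

test_that("operational-depth whitening (K = 5) still near-whitens", {
  set.seed(7)
  for (d in c(4L, 16L)) {
    m <- 64L * d
    r <- iternorm_whiten(random_batch(d, m),
                         iternorm_state(d, K = 5L, affine = FALSE), TRUE)
    expect_lt(norm(tcrossprod(r$XW) / m - diag(d), "F"), 0.3)
  }
})

test_that("whitening gradients agree with finite differences", {
  set.seed(8)
  d <- 3L; m <- 8L; K <- 5L
  X <- matrix(rnorm(d * m), d, m)
  st <- iternorm_state(d, K = K, affine = FALSE)
  G <- matrix(rnorm(d * m), d, m)
  r <- iternorm_whiten(X, st, TRUE)
  gX <- iternorm_backward(r$cache, G)$gX
  h <- 1e-6
  num <- matrix(0, d, m)
  for (i in seq_len(d)) for (j in seq_len(m)) {
    Xp <- X; Xp[i, j] <- Xp[i, j] + h
    Xm <- X; Xm[i, j] <- Xm[i, j] - h
    num[i, j] <- (sum(G * iternorm_whiten(Xp, st, TRUE)$XW) -
                    sum(G * iternorm_whiten(Xm, st, TRUE)$XW)) / (2 * h)
  }
  expect_lt(max(abs(gX - num)) / max(abs(num)), 1e-4)
})

test_that("affine gradients of the whitening layer are exact", {
  set.seed(9)
  d <- 3L; m <- 12L
  X <- matrix(rnorm(d * m), d, m)
  st <- iternorm_state(d, K = 3L, affine = TRUE)
  st$alpha <- runif(d, 0.5, 2); st$beta <- rnorm(d)
  G <- matrix(rnorm(d * m), d, m)
  r <- iternorm_whiten(X, st, TRUE)
  bk <- iternorm_backward(r$cache, G)
  h <- 1e-6
  for (i in seq_len(d)) {
    stp <- st; stp$alpha[i] <- stp$alpha[i] + h
    stm <- st; stm$alpha[i] <- stm$alpha[i] - h
    num <- (sum(G * iternorm_whiten(X, stp, TRUE)$XW) -
              sum(G * iternorm_whiten(X, stm, TRUE)$XW)) / (2 * h)
    expect_equal(bk$galpha[i], num, tolerance = 1e-5)
  }
})

test_that("normalization layers are invariant to sample permutations", {
  set.seed(10)
  d <- 6L; m <- 50L
  X <- matrix(rnorm(d * m), d, m)
  perm <- sample(m)
  bn <- batch_norm(X, bn_state(d), TRUE)$output
  bnp <- batch_norm(X[, perm], bn_state(d), TRUE)$output
  expect_equal(bn[, perm], bnp, tolerance = 1e-12)
  st <- iternorm_state(d, K = 5L, affine = FALSE)
  w <- iternorm_whiten(X, st, TRUE)$XW
  wp <- iternorm_whiten(X[, perm], st, TRUE)$XW
  expect_equal(w[, perm], wp, tolerance = 1e-10)
})

test_that("inference mode applies running statistics", {
  set.seed(11)
  d <- 4L; m <- 512L
  st <- iternorm_state(d, K = 20L, affine = FALSE, momentum = 0.5)
  # feed the same population repeatedly so the EMA converges to it
  X <- random_batch(d, m)
  for (i in 1:30) st <- iternorm_whiten(X, st, TRUE)$state
  out <- iternorm_whiten(X, st, FALSE)$XW
  expect_lt(norm(tcrossprod(out) / m - diag(d), "F"), 0.1)
  # bn inference likewise standardizes with stored statistics
  stb <- bn_state(d, momentum = 0.5)
  for (i in 1:30) stb <- batch_norm(X, stb, TRUE)$state
  ob <- batch_norm(X, stb, FALSE)$output
  expect_equal(rowMeans(ob), rep(0, d), tolerance = 0.02)
})

test_that("unrolling maps channels to rows and is exactly invertible", {
  set.seed(12)
  A <- array(rnorm(2 * 2 * 3 * 4), c(2, 2, 3, 4))
  X <- unroll_conv_batch(A)
  expect_equal(dim(X), c(3L, 16L))
  expect_equal(roll_conv_batch(X), A)
  for (ch in 1:3)
    expect_equal(sort(X[ch, ]), sort(as.vector(A[, , ch, ])))
})
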