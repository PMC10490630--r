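# CNN architecture: convolution blocks, shape pyramid, initialization
# determinism, parameter accounting, checkpointing.

test_that("an identity-impulse filter reproduces the pooled input", {
  # 7x7 one-hot image through a single 3x3 filter with a centered impulse
  x <- array(0, c(7, 7, 1, 1)); x[4, 5, 1, 1] <- 1
  w <- array(0, c(3, 3, 1, 1)); w[2, 2, 1, 1] <- 1
  y <- mdwhiten:::conv2d_forward(x, w, rep(0, 1))$y
  expect_equal(y, x, tolerance = 1e-6)
  # hand-computed direct convolution oracle for a random filter
  set.seed(15)
  xr <- array(rnorm(7 * 7), c(7, 7, 1, 1))
  wr <- array(rnorm(9), c(3, 3, 1, 1))
  yr <- mdwhiten:::conv2d_forward(xr, wr, 0.3)$y
  ref <- array(0, c(7, 7))
  for (i in 1:7) for (j in 1:7) {
    acc <- 0.3
    for (ki in 1:3) for (kj in 1:3) {
      si <- i + ki - 2; sj <- j + kj - 2
      if (si >= 1 && si <= 7 && sj >= 1 && sj <= 7)
        acc <- acc + xr[si, sj, 1, 1] * wr[ki, kj, 1, 1]
    }
    ref[i, j] <- acc
  }
  expect_equal(yr[, , 1, 1], ref, tolerance = 1e-5)
  # pooled impulse survives at the pooled location
  pooled <- mdwhiten:::maxpool_forward(y)$y
  expect_equal(dim(pooled), c(2L, 2L, 1L, 1L))
  expect_equal(pooled[2, 2, 1, 1], 1, tolerance = 1e-6)
})

test_that("max-pooling backward routes gradients to the argmax", {
  set.seed(16)
  x <- array(runif(6 * 6 * 2 * 3) + 0.1, c(6, 6, 2, 3))  # all active
  pf <- mdwhiten:::maxpool_forward(x, 3L, 3L)
  gy <- array(rnorm(length(pf$y)), dim(pf$y))
  gx <- mdwhiten:::maxpool_backward(pf$idx, gy, dim(x), x)
  expect_equal(sum(gx != 0), length(gy))
  expect_equal(sum(gx), sum(gy), tolerance = 1e-12)
  expect_equal(gx[pf$idx[1]], gy[1])
  # fused rectifier backward: windows whose maximum activation is zero
  # receive no gradient
  x0 <- x; x0[, , 1, 1] <- 0
  pf0 <- mdwhiten:::maxpool_forward(x0, 3L, 3L)
  gx0 <- mdwhiten:::maxpool_backward(pf0$idx, gy, dim(x0), x0)
  expect_true(all(gx0[, , 1, 1] == 0))
})

test_that("the spatial pyramid is 75 -> 25 -> 8 -> 2", {
  expect_equal(mdwhiten:::pyramid_sizes(c(75L, 75L), 3L),
               list(c(25L, 25L), c(8L, 8L), c(2L, 2L)))
})

test_that("forward produces probability rows and is seed-deterministic", {
  cfg <- model_config("bn")
  m1 <- build_model(cfg, seed = 42L)
  m2 <- build_model(cfg, seed = 42L)
  expect_identical(m1$blocks[[1]]$W, m2$blocks[[1]]$W)
  expect_identical(m1$head$W, m2$head$W)
  m3 <- build_model(cfg, seed = 43L)
  expect_false(identical(m1$head$W, m3$head$W))

  set.seed(1)
  ims <- array(runif(75 * 75 * 4) * 255, c(75, 75, 4))
  p <- predict_model(m1, ims)
  expect_equal(dim(p), c(4L, 6L))
  expect_equal(rowSums(p), rep(1, 4), tolerance = 1e-6)
})

test_that("parameter counts match closed-form shape arithmetic", {
  # conv: 3*3*1*32+32, 3*3*32*64+64, 3*3*64*128+128; head: 2*2*128*6+6
  conv_expected <- (288 + 32) + (18432 + 64) + (73728 + 128)
  head_expected <- 512 * 6 + 6
  for (kind in c("bn", "iternorm")) {
    np <- n_parameters(build_model(model_config(kind), 1L))
    expect_equal(np$conv, conv_expected)
    expect_equal(np$head, head_expected)
    expect_equal(np$norm, 2 * (32 + 64 + 128))   # scale + shift per channel
    expect_equal(np$total, conv_expected + head_expected + 448)
  }
  # rotation variant: no affine after whitening, Q reported separately
  np2 <- n_parameters(build_model(model_config("iternorm_rot"), 1L))
  expect_equal(np2$norm, 0)
  expect_equal(np2$rotation, 32^2 + 64^2 + 128^2)
})

test_that("variants differ only in their normalization modules", {
  set.seed(2)
  ims <- array(runif(75 * 75 * 3) * 255, c(75, 75, 3))
  outs <- lapply(c("bn", "iternorm", "iternorm_rot"), function(k) {
    cfg <- model_config(k)
    cfg$norm_kind[] <- "none"      # strip normalization; rest identical
    predict_model(build_model(cfg, seed = 7L), ims)
  })
  expect_equal(outs[[1]], outs[[2]])
  expect_equal(outs[[1]], outs[[3]])
})

test_that("evaluation passes are identical (dropout inactive)", {
  m <- build_model(model_config("iternorm"), 3L)
  set.seed(3)
  ims <- array(runif(75 * 75 * 5) * 255, c(75, 75, 5))
  expect_identical(predict_model(m, ims), predict_model(m, ims))
})

test_that("checkpoints round-trip bit-exactly", {
  ds <- quadrant_dataset(n_per_class = 5L)
  cfg <- train_config(batch_size = 5L, max_epochs = 2L, seed = 4L)
  fit <- train_model(build_model(model_config("iternorm_rot"), 5L), ds, cfg)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(fit$model, path)
  back <- load_checkpoint(path)
  expect_identical(back$blocks, fit$model$blocks)
  set.seed(6)
  ims <- array(runif(75 * 75 * 3) * 255, c(75, 75, 3))
  expect_identical(predict_model(back, ims), predict_model(fit$model, ims))
})
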