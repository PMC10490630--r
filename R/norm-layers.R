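#' Center an activation batch
#'
#' For a `d x m` batch `X`, returns the batch mean `mu = X 1m / m` and the
#' centered activations `XC = X - mu 1m'`.
#'
#' @param X numeric matrix, features in rows, samples in columns.
#' @return list with elements `XC` and `mu`.
#' @export
center <- function(X) {
  stopifnot(is.matrix(X), all(is.finite(X)))
  mu <- rowMeans(X)
  list(XC = X - mu, mu = mu)
}

#' Batch-normalization layer state
#'
#' Learnable per-feature scale/shift plus running inference statistics.
#'
#' @param d feature dimension.
#' @param eps diagonal loading added to the batch variances.
#' @param momentum running-statistics update weight in (0, 1).
#' @return object of class `bn_state`.
#' @export
bn_state <- function(d, eps = 1e-5, momentum = 0.1) {
  stopifnot(d >= 1, eps > 0, momentum > 0, momentum < 1)
  structure(list(kind = "bn", d = as.integer(d), eps = eps,
                 momentum = momentum,
                 alpha = rep(1, d), beta = rep(0, d),
                 running_mean = rep(0, d), running_var = rep(1, d)),
            class = "bn_state")
}

#' Batch normalization forward pass
#'
#' Training mode standardizes each feature by its batch statistics
#' (`1/m` variance convention, diagonal loading `eps`) and applies the
#' learned affine transform; running mean/variance are updated by
#' exponential moving average. Inference mode uses the running statistics.
#'
#' @param X `d x m` activation batch.
#' @param state a [bn_state()].
#' @param training logical.
#' @return list with `output` (`d x m`), updated `state`, and `cache` for
#'   [batch_norm_backward()] (training mode only).
#' @export
batch_norm <- function(X, state, training = TRUE) {
  stopifnot(inherits(state, "bn_state"), nrow(X) == state$d)
  if (training) {
    m <- ncol(X)
    if (m < 2) stop("batch normalization in training mode requires m >= 2")
    cn <- center(X)
    sig2 <- rowMeans(cn$XC^2)
    denom <- sqrt(sig2 + state$eps)
    XS <- cn$XC / denom
    out <- state$alpha * XS + state$beta
    mom <- state$momentum
    state$running_mean <- (1 - mom) * state$running_mean + mom * cn$mu
    state$running_var <- (1 - mom) * state$running_var + mom * sig2
    cache <- list(XC = cn$XC, XS = XS, denom = denom, alpha = state$alpha,
                  m = m)
    list(output = out, state = state, cache = cache)
  } else {
    XS <- (X - state$running_mean) / sqrt(state$running_var + state$eps)
    list(output = state$alpha * XS + state$beta, state = state, cache = NULL)
  }
}

#' Batch normalization backward pass
#'
#' Backpropagates through the training-mode standardization, including the
#' dependence of the batch mean and variances on the input.
#'
#' @param cache cache from [batch_norm()] in training mode.
#' @param gout gradient of the loss with respect to the layer output.
#' @return list with `gX`, `galpha`, `gbeta`.
#' @export
batch_norm_backward <- function(cache, gout) {
  galpha <- rowSums(gout * cache$XS)
  gbeta <- rowSums(gout)
  gXS <- gout * cache$alpha
  gXC <- gXS / cache$denom
  gsig2 <- rowSums(gXS * cache$XC) * (-0.5) / cache$denom^3
  gXC <- gXC + (2 / cache$m) * cache$XC * gsig2
  gX <- gXC - rowMeans(gXC)
  list(gX = gX, galpha = galpha, gbeta = gbeta)
}

#' Iterative batch-whitening layer state
#'
#' State of a whitening layer that approximates the inverse square root of
#' the trace-normalized batch covariance by Newton's iterations, with
#' running inference statistics and an optional learnable per-feature
#' affine transform after whitening.
#'
#' @param d feature dimension.
#' @param K number of Newton iterations.
#' @param eps diagonal loading of the covariance.
#' @param momentum running-statistics update weight in (0, 1).
#' @param affine logical; carry a learnable per-feature scale/shift.
#' @return object of class `iternorm_state`.
#' @export
iternorm_state <- function(d, K = 5L, eps = 1e-5, momentum = 0.1,
                           affine = TRUE) {
  stopifnot(d >= 1, K >= 1, eps > 0, momentum > 0, momentum < 1)
  structure(list(kind = "iternorm", d = as.integer(d), K = as.integer(K),
                 eps = eps, momentum = momentum, affine = affine,
                 alpha = if (affine) rep(1, d) else NULL,
                 beta = if (affine) rep(0, d) else NULL,
                 running_mean = rep(0, d),
                 running_W = diag(d)),
            class = "iternorm_state")
}

#' Iterative batch whitening (Newton's method) forward pass
#'
#' Training mode: centers the batch, forms the loaded covariance
#' `Sigma = XC XC'/m + eps I`, trace-normalizes it
#' (`SigmaN = Sigma / tr(Sigma)`), runs `K` Newton iterations
#' `P_k = (3 P_{k-1} - P_{k-1}^3 SigmaN) / 2` from `P_0 = I`, scales
#' `W = P_K / sqrt(tr(Sigma))` and whitens `XW = W XC`. Running mean and
#' whitening matrix are updated by exponential moving average. Inference
#' mode applies the running statistics: `XW = What (X - muhat 1m')`.
#' The optional affine transform is applied after whitening.
#'
#' The whole computation is differentiable; [iternorm_backward()] provides
#' the exact adjoint through every Newton iterate, the trace
#' normalization, the covariance and the centering.
#'
#' @param X `d x m` activation batch.
#' @param state an [iternorm_state()].
#' @param training logical.
#' @return list with `XW` (post-affine output), `W` (the whitening matrix
#'   used), updated `state`, and `cache` (training mode).
#' @export
iternorm_whiten <- function(X, state, training = TRUE) {
  stopifnot(inherits(state, "iternorm_state"), nrow(X) == state$d)
  d <- state$d
  if (training) {
    m <- ncol(X)
    if (m < 2) stop("whitening in training mode requires m >= 2")
    cn <- center(X)
    XC <- cn$XC
    Sigma <- tcrossprod(XC) / m + state$eps * diag(d)
    trS <- sum(diag(Sigma))
    SigmaN <- Sigma / trS
    P <- diag(d)
    iters <- vector("list", state$K)
    for (k in seq_len(state$K)) {
      P2 <- P %*% P
      P3 <- P2 %*% P
      iters[[k]] <- list(P = P, P2 = P2, P3 = P3)
      P <- 0.5 * (3 * P - P3 %*% SigmaN)
      if (!all(is.finite(P)))
        stop(sprintf("Newton iteration %d produced non-finite values", k))
    }
    W <- P / sqrt(trS)
    XW <- W %*% XC
    mom <- state$momentum
    state$running_mean <- (1 - mom) * state$running_mean + mom * cn$mu
    state$running_W <- (1 - mom) * state$running_W + mom * W
    cache <- list(XC = XC, W = W, PK = P, iters = iters, Sigma = Sigma,
                  SigmaN = SigmaN, trS = trS, m = m, K = state$K)
    out <- XW
    if (state$affine) {
      cache$XW_pre <- XW
      cache$alpha <- state$alpha
      out <- state$alpha * XW + state$beta
    }
    list(XW = out, W = W, state = state, cache = cache)
  } else {
    XW <- state$running_W %*% (X - state$running_mean)
    if (state$affine) XW <- state$alpha * XW + state$beta
    list(XW = XW, W = state$running_W, state = state, cache = NULL)
  }
}

#' Backward pass of iterative batch whitening
#'
#' Exact reverse-mode differentiation of the training-mode forward pass:
#' the adjoint is propagated through the post-whitening affine transform,
#' the product `W XC`, the `1/sqrt(tr(Sigma))` rescaling, all `K` Newton
#' iterations, the trace normalization, the covariance estimate and the
#' centering. The symmetry of the Newton iterates (polynomials in the
#' symmetric `SigmaN`) is used to simplify the per-iteration adjoints.
#'
#' @param cache cache from [iternorm_whiten()] in training mode.
#' @param gout gradient of the loss with respect to the layer output.
#' @return list with `gX` and, when the layer carries the affine
#'   transform, `galpha` and `gbeta`.
#' @export
iternorm_backward <- function(cache, gout) {
  res <- list()
  gXW <- gout
  if (!is.null(cache$alpha)) {
    res$galpha <- rowSums(gout * cache$XW_pre)
    res$gbeta <- rowSums(gout)
    gXW <- gout * cache$alpha
  }
  XC <- cache$XC
  m <- cache$m
  trS <- cache$trS
  SigmaN <- cache$SigmaN

  gW <- tcrossprod(gXW, XC)          # gXW %*% t(XC)
  gXC <- crossprod(cache$W, gXW)     # t(W) %*% gXW

  # W = P_K / sqrt(trS)
  gP <- gW / sqrt(trS)
  gtr <- -0.5 * sum(gW * cache$PK) * trS^(-1.5)

  gSN <- matrix(0, nrow(gW), ncol(gW))
  for (k in rev(seq_len(cache$K))) {
    it <- cache$iters[[k]]
    S1 <- it$P %*% SigmaN
    S2 <- it$P %*% S1
    gSN <- gSN - 0.5 * it$P3 %*% gP
    gP <- 0.5 * (3 * gP - gP %*% S2 - it$P %*% gP %*% S1 -
                   it$P2 %*% gP %*% SigmaN)
  }
  # SigmaN = Sigma / trS
  gSigma <- gSN / trS
  gtr <- gtr - sum(gSN * cache$Sigma) / trS^2
  diag(gSigma) <- diag(gSigma) + gtr
  # Sigma = XC XC' / m (+ eps I, constant)
  gXC <- gXC + (gSigma + t(gSigma)) %*% XC / m
  res$gX <- gXC - rowMeans(gXC)
  res
}

#' Unroll a convolutional activation batch
#'
#' Reshapes an `hd x wd x L x m` array of feature maps into the `d x m_eff`
#' matrix expected by the normalization layers, with the channel index as
#' the feature dimension (`d = L`) and every spatial position of every
#' sample as a column (`m_eff = m * hd * wd`). Columns are grouped by
#' sample: the columns of sample `j` occupy the contiguous block
#' `(j-1)*hd*wd + 1 .. j*hd*wd`.
#'
#' @param A numeric 4-D array `hd x wd x L x m`.
#' @return matrix `L x (m*hd*wd)` with attribute `"conv_dims"` recording
#'   the original shape.
#' @export
unroll_conv_batch <- function(A) {
  stopifnot(length(dim(A)) == 4L)
  d <- dim(A)
  X <- aperm(A, c(3L, 1L, 2L, 4L))
  dim(X) <- c(d[3], d[1] * d[2] * d[4])
  attr(X, "conv_dims") <- d
  X
}

#' Invert [unroll_conv_batch()]
#'
#' @param X matrix from [unroll_conv_batch()] (or any matrix of matching
#'   size).
#' @param dims original 4-D shape; defaults to the `"conv_dims"` attribute.
#' @return numeric array `hd x wd x L x m`.
#' @export
roll_conv_batch <- function(X, dims = attr(X, "conv_dims")) {
  stopifnot(length(dims) == 4L, length(X) == prod(dims))
  A <- X
  dim(A) <- c(dims[3], dims[1], dims[2], dims[4])
  aperm(A, c(2L, 3L, 1L, 4L))
}
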