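#' Model configuration
#'
#' Architecture of the 3-block micro-Doppler CNN: each block is a 3 x 3
#' "same"-padded convolution (32/64/128 filters), ReLU, 3 x 3 max-pooling
#' with stride 3, and a normalization layer; a dropout layer and a
#' fully-connected softmax head follow. The spatial pyramid for 75 x 75
#' input is 75 -> 25 -> 8 -> 2.
#'
#' `norm_kind` selects the normalization per block: `"bn"` (batch
#' normalization), `"iternorm"` (iterative batch whitening), or
#' `"iternorm_rot"` (whitening followed by a class-aligning rotation).
#' A single value is recycled to all three blocks; a length-3 vector
#' configures blocks individually (used by the single-layer ablation).
#' Whitening layers carry a learnable per-channel affine transform;
#' rotation layers do not (an affine would re-mix the aligned axes).
#'
#' @param norm_kind normalization kind(s); see details.
#' @param filters number of filters per block.
#' @param num_classes number of output classes.
#' @param input_size input image size `c(h, w)`.
#' @param dropout_rate dropout probability before the output layer.
#' @param K Newton iterations of the whitening layers.
#' @param eps diagonal loading for both BN and whitening.
#' @param momentum running-statistics momentum.
#' @param rot_step Cayley step size of the rotation modules.
#' @return object of class `md_model_config`.
#' @export
model_config <- function(norm_kind = "bn", filters = c(32L, 64L, 128L),
                         num_classes = 6L, input_size = c(75L, 75L),
                         dropout_rate = 0.15, K = 5L, eps = 1e-5,
                         momentum = 0.1, rot_step = 0.05) {
  norm_kind <- rep_len(norm_kind, length(filters))
  stopifnot(all(norm_kind %in% c("bn", "iternorm", "iternorm_rot", "none")),
            dropout_rate >= 0, dropout_rate < 1, num_classes >= 2)
  structure(list(norm_kind = norm_kind, filters = as.integer(filters),
                 num_classes = as.integer(num_classes),
                 input_size = as.integer(input_size),
                 dropout_rate = dropout_rate, K = as.integer(K), eps = eps,
                 momentum = momentum, rot_step = rot_step),
            class = "md_model_config")
}

# spatial size after the conv("same") + pool(3, stride 3) pyramid
pyramid_sizes <- function(input_size, n_blocks) {
  sz <- input_size
  out <- vector("list", n_blocks)
  for (i in seq_len(n_blocks)) {
    sz <- (sz - 3L) %/% 3L + 1L
    out[[i]] <- sz
  }
  out
}

make_norm_state <- function(kind, d, cfg) {
  switch(kind,
    bn = bn_state(d, eps = cfg$eps, momentum = cfg$momentum),
    iternorm = iternorm_state(d, K = cfg$K, eps = cfg$eps,
                              momentum = cfg$momentum, affine = TRUE),
    iternorm_rot = iternorm_state(d, K = cfg$K, eps = cfg$eps,
                                  momentum = cfg$momentum, affine = FALSE),
    none = NULL
  )
}

#' Build a model with seeded deterministic initialization
#'
#' Convolution and dense weights use fan-in variance scaling (He
#' initialization for the ReLU blocks, `1/fan_in` for the linear head);
#' biases start at zero; whitening/BN states at their identity
#' transformations; rotation matrices at the identity.
#'
#' @param cfg a [model_config()].
#' @param seed integer seed controlling the initialization.
#' @return object of class `md_model`.
#' @export
build_model <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "md_model_config"))
  set.seed(as.integer(seed))
  n_blocks <- length(cfg$filters)
  chans <- c(1L, cfg$filters)
  blocks <- vector("list", n_blocks)
  for (i in seq_len(n_blocks)) {
    fan_in <- 3 * 3 * chans[i]
    W <- array(stats::rnorm(3 * 3 * chans[i] * chans[i + 1],
                            sd = sqrt(2 / fan_in)),
               c(3, 3, chans[i], chans[i + 1]))
    norm <- make_norm_state(cfg$norm_kind[i], chans[i + 1], cfg)
    rot <- if (identical(cfg$norm_kind[i], "iternorm_rot"))
      rotation_state(chans[i + 1], cfg$num_classes, cfg$rot_step) else NULL
    blocks[[i]] <- list(W = W, b = rep(0, chans[i + 1]), norm = norm,
                        rot = rot)
  }
  sizes <- pyramid_sizes(cfg$input_size, n_blocks)
  feat <- prod(sizes[[n_blocks]]) * cfg$filters[n_blocks]
  headW <- matrix(stats::rnorm(feat * cfg$num_classes, sd = sqrt(1 / feat)),
                  feat, cfg$num_classes)
  structure(list(cfg = cfg, blocks = blocks,
                 head = list(W = headW, b = rep(0, cfg$num_classes)),
                 feat_dim = feat),
            class = "md_model")
}

#' @export
print.md_model <- function(x, ...) {
  cat(sprintf("md_model: %d conv blocks (%s), norms [%s], %d classes\n",
              length(x$blocks), paste(x$cfg$filters, collapse = "-"),
              paste(x$cfg$norm_kind, collapse = ", "), x$cfg$num_classes))
  np <- n_parameters(x)
  cat(sprintf("  trainable parameters: %d\n", np$total))
  invisible(x)
}

#' Count trainable parameters
#'
#' @param model an [build_model()] object.
#' @return list with per-component counts and `total` (rotation matrices,
#'   learned on the orthogonal group rather than by SGD, are reported
#'   separately and not included in `total`).
#' @export
n_parameters <- function(model) {
  conv <- sum(vapply(model$blocks,
                     function(b) length(b$W) + length(b$b), numeric(1)))
  norm <- sum(vapply(model$blocks, function(b) {
    if (is.null(b$norm)) 0 else length(b$norm$alpha) + length(b$norm$beta)
  }, numeric(1)))
  head <- length(model$head$W) + length(model$head$b)
  rot <- sum(vapply(model$blocks,
                    function(b) if (is.null(b$rot)) 0 else length(b$rot$Q),
                    numeric(1)))
  list(conv = conv, norm = norm, head = head, rotation = rot,
       total = conv + norm + head)
}

# forward through one block; returns output, cache, updated block
block_forward <- function(block, x, training, collect = FALSE) {
  cf <- conv2d_forward(x, block$W, block$b, relu = TRUE)
  a <- cf$y
  pl <- maxpool_forward(a)
  X <- unroll_conv_batch(pl$y)
  dims <- attr(X, "conv_dims")
  cache <- list(x = x, a = a, xcol = cf$xcol, pool_idx = pl$idx,
                pool_xdim = dim(a), conv_dims = dims)
  if (is.null(block$norm)) {
    Y <- X
  } else if (block$norm$kind == "bn") {
    nb <- batch_norm(X, block$norm, training)
    block$norm <- nb$state
    cache$norm <- nb$cache
    Y <- nb$output
  } else {
    nb <- iternorm_whiten(X, block$norm, training)
    block$norm <- nb$state
    cache$norm <- nb$cache
    Y <- nb$XW
    if (!is.null(block$rot)) {
      cache$XW_white <- Y          # pre-rotation whitened activations
      Y <- apply_rotation(Y, block$rot$Q)
    }
  }
  if (collect) {
    attr(Y, "conv_dims") <- dims
    cache$norm_output <- Y
  }
  out <- roll_conv_batch(Y, dims)
  list(out = out, cache = cache, block = block)
}

block_backward <- function(block, cache, gout, need_gx) {
  gY <- unroll_conv_batch(gout)
  grads <- list()
  if (is.null(block$norm)) {
    gX <- gY
  } else {
    if (!is.null(block$rot)) gY <- block$rot$Q %*% gY
    if (block$norm$kind == "bn") {
      bb <- batch_norm_backward(cache$norm, gY)
      grads$galpha <- bb$galpha; grads$gbeta <- bb$gbeta
      gX <- bb$gX
    } else {
      ib <- iternorm_backward(cache$norm, gY)
      if (!is.null(ib$galpha)) {
        grads$galpha <- ib$galpha; grads$gbeta <- ib$gbeta
      }
      gX <- ib$gX
    }
  }
  gpool <- roll_conv_batch(gX, cache$conv_dims)
  gz <- maxpool_backward(cache$pool_idx, gpool, cache$pool_xdim, cache$a)
  cb <- conv2d_backward(cache$x, block$W, gz, need_gx, cache$xcol)
  grads$gW <- cb$gw; grads$gb <- cb$gb
  if (need_gx) grads$gx <- cb$gx
  grads
}

# images: h x w x m array of raw 0..255 intensities
model_forward <- function(model, images, training = FALSE, collect = FALSE) {
  d <- dim(images)
  x <- array(images / 255, c(d[1], d[2], 1L, d[3]))
  caches <- vector("list", length(model$blocks))
  for (i in seq_along(model$blocks)) {
    bf <- block_forward(model$blocks[[i]], x, training, collect)
    model$blocks[[i]] <- bf$block
    caches[[i]] <- bf$cache
    x <- bf$out
  }
  m <- d[3]
  feat <- matrix(x, model$feat_dim, m)
  drop_mask <- NULL
  if (training && model$cfg$dropout_rate > 0) {
    keep <- 1 - model$cfg$dropout_rate
    drop_mask <- matrix(stats::rbinom(length(feat), 1, keep) / keep,
                        nrow(feat), ncol(feat))
    feat <- feat * drop_mask
  }
  logits <- crossprod(model$head$W, feat) + model$head$b
  probs <- softmax_cols(logits)
  list(probs = probs, model = model,
       cache = list(blocks = caches, feat = feat, drop_mask = drop_mask,
                    last_dims = dim(x)))
}

model_backward <- function(model, fw, labels) {
  probs <- fw$probs
  m <- ncol(probs)
  glogits <- probs / m
  glogits[cbind(labels, seq_len(m))] <-
    glogits[cbind(labels, seq_len(m))] - 1 / m
  ghW <- fw$cache$feat %*% t(glogits)
  ghb <- rowSums(glogits)
  gfeat <- model$head$W %*% glogits
  if (!is.null(fw$cache$drop_mask)) gfeat <- gfeat * fw$cache$drop_mask
  gx <- array(gfeat, fw$cache$last_dims)
  bgrads <- vector("list", length(model$blocks))
  for (i in rev(seq_along(model$blocks))) {
    bb <- block_backward(model$blocks[[i]], fw$cache$blocks[[i]], gx,
                         need_gx = i > 1L)
    bgrads[[i]] <- bb
    if (i > 1L) gx <- bb$gx
  }
  list(head = list(gW = ghW, gb = ghb), blocks = bgrads)
}

#' Class-probability predictions
#'
#' Runs the model in inference mode (running normalization statistics, no
#' dropout) over the images in batches.
#'
#' @param model an `md_model`.
#' @param images `75 x 75 x n` array of raw 0..255 intensities, or an
#'   [md_dataset()].
#' @param batch_size evaluation batch size.
#' @return `n x num_classes` matrix of class probabilities (rows sum to 1).
#' @export
predict_model <- function(model, images, batch_size = 64L) {
  if (inherits(images, "md_dataset")) images <- images$images
  n <- dim(images)[3]
  out <- matrix(0, n, model$cfg$num_classes)
  i <- 1L
  while (i <= n) {
    j <- min(n, i + batch_size - 1L)
    fw <- model_forward(model, images[, , i:j, drop = FALSE],
                        training = FALSE)
    out[i:j, ] <- t(fw$probs)
    i <- j + 1L
  }
  out
}

#' Save / load a model checkpoint
#'
#' Serializes the full model (configuration, weights, normalization and
#' rotation states) so that a reload reproduces forward outputs
#' bit-exactly on the saving platform.
#'
#' @param model an `md_model`.
#' @param path file path.
#' @return `load_checkpoint` returns the model; `save_checkpoint` the path,
#'   invisibly.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) readRDS(path)

# Change of basis accompanying a rotation-layer update. If block bi's
# output channels are re-expressed as R' x (R = Q_old' Q_new), the
# downstream linear map — the next block's convolution, or the head for
# the last block — is re-expressed in the new basis so the network
# function is exactly unchanged. `objs` is a list of same-shaped weight
# arrays (weights and their momentum buffers) to transform in place.
rotate_channel_basis_conv <- function(W, R) {
  d <- dim(W)
  M <- matrix(aperm(W, c(3L, 1L, 2L, 4L)), d[3], d[1] * d[2] * d[4])
  M2 <- crossprod(R, M)
  aperm(array(M2, c(d[3], d[1], d[2], d[4])), c(2L, 3L, 1L, 4L))
}

rotate_channel_basis_head <- function(W, R, spatial) {
  # head rows follow the (h, w, channel) flattening: channel blocks of
  # length `spatial`
  d <- dim(W)
  A <- array(W, c(spatial, d[1] / spatial, d[2]))
  M <- matrix(aperm(A, c(2L, 1L, 3L)), dim(A)[2], spatial * d[2])
  M2 <- crossprod(R, M)
  A2 <- aperm(array(M2, c(dim(A)[2], spatial, d[2])), c(2L, 1L, 3L))
  array(A2, d)
}

#' Convert whitening layers into whitening + rotation layers
#'
#' Implements the warm-start construction of the rotation-augmented model:
#' every `iternorm` block of a trained model becomes an `iternorm_rot`
#' block with `Q = I`, keeping convolution weights and running whitening
#' statistics. The post-whitening affine transform is removed (its scale
#' would re-mix the class-aligned axes); `layers` restricts the conversion
#' to a subset of blocks.
#'
#' @param model a trained `md_model` with whitening layers.
#' @param layers indices of blocks to convert; default all `iternorm`
#'   blocks.
#' @return the converted model.
#' @export
add_rotation_modules <- function(model, layers = NULL) {
  if (is.null(layers))
    layers <- which(model$cfg$norm_kind == "iternorm")
  for (i in layers) {
    st <- model$blocks[[i]]$norm
    if (is.null(st) || st$kind != "iternorm")
      stop("rotation modules can only be added after whitening layers")
    st$affine <- FALSE
    st$alpha <- NULL; st$beta <- NULL
    model$blocks[[i]]$norm <- st
    model$blocks[[i]]$rot <- rotation_state(st$d, model$cfg$num_classes,
                                            model$cfg$rot_step)
    model$cfg$norm_kind[i] <- "iternorm_rot"
  }
  model
}
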