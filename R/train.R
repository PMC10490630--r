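#' Training configuration
#'
#' Cross-entropy loss, SGD with momentum, step learning-rate decay.
#' Defaults follow the training protocol used throughout the package:
#' batch size 10, at most 30 epochs, learning rate divided by 10 every 7
#' epochs, 5 Newton iterations in the whitening layers, and a 5-epoch
#' fine-tuning phase for the rotation-augmented model started from a
#' trained whitening model.
#'
#' @param batch_size minibatch size (>= 2; normalization layers need batch
#'   statistics).
#' @param max_epochs number of training epochs.
#' @param lr_init initial learning rate.
#' @param lr_decay multiplicative decay factor.
#' @param lr_step epochs between decays.
#' @param sgd_momentum SGD momentum coefficient.
#' @param warm_epochs fine-tuning epochs for the rotation phase.
#' @param seed integer seed for shuffling and dropout.
#' @return object of class `md_train_config`.
#' @export
train_config <- function(batch_size = 10L, max_epochs = 30L, lr_init = 0.01,
                         lr_decay = 0.1, lr_step = 7L, sgd_momentum = 0.9,
                         warm_epochs = 5L, seed = 1L) {
  stopifnot(batch_size >= 2, max_epochs >= 1)
  structure(list(batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs), lr_init = lr_init,
                 lr_decay = lr_decay, lr_step = as.integer(lr_step),
                 sgd_momentum = sgd_momentum,
                 warm_epochs = as.integer(warm_epochs),
                 seed = as.integer(seed)),
            class = "md_train_config")
}

zero_like_grads <- function(model) {
  vel <- list(head = list(gW = model$head$W * 0, gb = model$head$b * 0),
              blocks = lapply(model$blocks, function(b) {
                g <- list(gW = b$W * 0, gb = b$b * 0)
                if (!is.null(b$norm) && !is.null(b$norm$alpha)) {
                  g$galpha <- b$norm$alpha * 0
                  g$gbeta <- b$norm$beta * 0
                }
                g
              }))
  vel
}

sgd_step <- function(model, grads, vel, lr, mom) {
  vel$head$gW <- mom * vel$head$gW - lr * grads$head$gW
  vel$head$gb <- mom * vel$head$gb - lr * grads$head$gb
  model$head$W <- model$head$W + vel$head$gW
  model$head$b <- model$head$b + vel$head$gb
  for (i in seq_along(model$blocks)) {
    g <- grads$blocks[[i]]
    vel$blocks[[i]]$gW <- mom * vel$blocks[[i]]$gW - lr * g$gW
    vel$blocks[[i]]$gb <- mom * vel$blocks[[i]]$gb - lr * g$gb
    model$blocks[[i]]$W <- model$blocks[[i]]$W + vel$blocks[[i]]$gW
    model$blocks[[i]]$b <- model$blocks[[i]]$b + vel$blocks[[i]]$gb
    if (!is.null(g$galpha) && !is.null(model$blocks[[i]]$norm$alpha)) {
      vel$blocks[[i]]$galpha <- mom * vel$blocks[[i]]$galpha - lr * g$galpha
      vel$blocks[[i]]$gbeta <- mom * vel$blocks[[i]]$gbeta - lr * g$gbeta
      model$blocks[[i]]$norm$alpha <-
        model$blocks[[i]]$norm$alpha + vel$blocks[[i]]$galpha
      model$blocks[[i]]$norm$beta <-
        model$blocks[[i]]$norm$beta + vel$blocks[[i]]$gbeta
    }
  }
  list(model = model, vel = vel)
}

#' Train a model
#'
#' Minimizes the cross-entropy by SGD with momentum over shuffled
#' minibatches; the learning rate is decayed by `lr_decay` every `lr_step`
#' epochs. Blocks carrying a rotation module follow an alternating
#' schedule: during each epoch the class-conditional means of the whitened
#' activations are accumulated while the network trains against a fixed
#' `Q`; at the epoch boundary (except after the final epoch) `Q` is
#' re-aligned by running the Cayley ascent to convergence on the
#' accumulated means, and the network adapts to the new basis over the
#' next epoch. Training is deterministic given `cfg$seed` (shuffling,
#' dropout) and the model's own initialization. Trailing batches of size 1
#' are dropped (batch statistics are undefined for a single sample).
#'
#' @param model an `md_model` from [build_model()].
#' @param data an [md_dataset()] (or list with `images`, `labels`).
#' @param cfg an [md_train_config][train_config()].
#' @param epochs optional override of `cfg$max_epochs`.
#' @param lr_init optional override of `cfg$lr_init`.
#' @param verbose print per-epoch loss/accuracy.
#' @return list with the trained `model` and a `history` data frame
#'   (epoch, loss, accuracy, lr).
#' @export
train_model <- function(model, data, cfg = train_config(), epochs = NULL,
                        lr_init = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "md_model"))
  images <- data$images
  labels <- as.integer(data$labels)
  n <- dim(images)[3]
  stopifnot(length(labels) == n)
  if (is.null(epochs)) epochs <- cfg$max_epochs
  if (is.null(lr_init)) lr_init <- cfg$lr_init
  set.seed(cfg$seed)
  vel <- zero_like_grads(model)
  hist <- data.frame(epoch = integer(), loss = numeric(),
                     accuracy = numeric(), lr = numeric())
  nc <- model$cfg$num_classes
  rot_blocks <- which(vapply(model$blocks,
                             function(b) !is.null(b$rot), logical(1)))
  for (ep in seq_len(epochs)) {
    lr <- lr_init * cfg$lr_decay^((ep - 1L) %/% cfg$lr_step)
    ord <- sample.int(n)
    ep_loss <- 0; ep_hits <- 0; ep_n <- 0
    # per-epoch accumulators of class-conditional whitened means
    rot_sum <- lapply(rot_blocks, function(bi)
      matrix(0, model$cfg$filters[bi], nc))
    rot_n <- lapply(rot_blocks, function(bi) rep(0, nc))
    i <- 1L
    while (i <= n) {
      j <- min(n, i + cfg$batch_size - 1L)
      idx <- ord[i:j]
      i <- j + 1L
      if (length(idx) < 2L) next   # drop-last: batch statistics undefined
      xb <- images[, , idx, drop = FALSE]
      yb <- labels[idx]
      fw <- model_forward(model, xb, training = TRUE)
      model <- fw$model
      loss <- cross_entropy(fw$probs, yb)
      grads <- model_backward(model, fw, yb)
      up <- sgd_step(model, grads, vel, lr, cfg$sgd_momentum)
      model <- up$model; vel <- up$vel
      # accumulate whitened class means for the epoch-boundary alignment
      for (k in seq_along(rot_blocks)) {
        ca <- fw$cache$blocks[[rot_blocks[k]]]
        pos <- ca$conv_dims[1] * ca$conv_dims[2]
        col_labels <- rep(yb, each = pos)
        for (cl in unique(yb)) {
          sel <- col_labels == cl
          rot_sum[[k]][, cl] <- rot_sum[[k]][, cl] +
            rowSums(ca$XW_white[, sel, drop = FALSE])
          rot_n[[k]][cl] <- rot_n[[k]][cl] + sum(sel)
        }
      }
      ep_loss <- ep_loss + loss * length(idx)
      ep_hits <- ep_hits + sum(max.col(t(fw$probs), ties.method = "first") == yb)
      ep_n <- ep_n + length(idx)
    }
    # re-align Q on the accumulated class means. The update is
    # function-preserving: the downstream weights (and their momentum
    # buffers) are re-expressed in the rotated basis, so alignment never
    # perturbs the network's input-output map.
    for (k in seq_along(rot_blocks)) {
      seen <- which(rot_n[[k]] > 0)
      if (length(seen) < 2L) next
      M <- rot_sum[[k]][, seen, drop = FALSE] /
        rep(rot_n[[k]][seen], each = nrow(rot_sum[[k]]))
      bi <- rot_blocks[k]
      st <- model$blocks[[bi]]$rot
      Q_old <- st$Q
      labs <- factor(seen, levels = seq_len(nc))
      for (it in seq_len(100L))
        st <- update_rotation(M, labs, st)
      model$blocks[[bi]]$rot <- st
      R <- crossprod(Q_old, st$Q)      # old-basis -> new-basis map
      if (bi < length(model$blocks)) {
        model$blocks[[bi + 1L]]$W <-
          rotate_channel_basis_conv(model$blocks[[bi + 1L]]$W, R)
        vel$blocks[[bi + 1L]]$gW <-
          rotate_channel_basis_conv(vel$blocks[[bi + 1L]]$gW, R)
      } else {
        spatial <- model$feat_dim / model$cfg$filters[bi]
        model$head$W <- rotate_channel_basis_head(model$head$W, R, spatial)
        vel$head$gW <- rotate_channel_basis_head(vel$head$gW, R, spatial)
      }
    }
    hist <- rbind(hist, data.frame(epoch = ep, loss = ep_loss / ep_n,
                                   accuracy = 100 * ep_hits / ep_n, lr = lr))
    if (verbose)
      message(sprintf("epoch %2d  lr %.4g  loss %.4f  acc %.1f%%",
                      ep, lr, ep_loss / ep_n, 100 * ep_hits / ep_n))
  }
  list(model = model, history = hist)
}

#' Evaluate a model on a test set
#'
#' @param model a trained `md_model`.
#' @param data an [md_dataset()].
#' @return list with `accuracy` (percent) and `confusion` (counts; rows =
#'   true class, columns = predicted class).
#' @export
evaluate_model <- function(model, data) {
  stopifnot(length(data) >= 1)
  probs <- predict_model(model, data$images)
  pred <- max.col(probs, ties.method = "first")
  truth <- as.integer(data$labels)
  nc <- model$cfg$num_classes
  confusion <- matrix(0L, nc, nc,
                      dimnames = list(true = levels(data$labels),
                                      predicted = levels(data$labels)))
  for (i in seq_along(truth))
    confusion[truth[i], pred[i]] <- confusion[truth[i], pred[i]] + 1L
  list(accuracy = 100 * sum(diag(confusion)) / sum(confusion),
       confusion = confusion)
}

#' Train one of the three model variants
#'
#' `"base"` (all-BN) and `"model1"` (all layers whitened) train from
#' scratch for `cfg$max_epochs`. `"model2"` (whitening + rotation) warm
#' starts from a fully trained `"model1"`, inserts rotation modules with
#' `Q = I` via [add_rotation_modules()], and fine-tunes for
#' `cfg$warm_epochs` epochs at `lr_init_model2`.
#'
#' @param data training [md_dataset()].
#' @param variant one of `"base"`, `"model1"`, `"model2"`.
#' @param cfg an [md_train_config][train_config()].
#' @param seed seed for model initialization (training randomness follows
#'   `cfg$seed`).
#' @param lr_init_base,lr_init_model1,lr_init_model2 per-variant initial
#'   learning rates.
#' @param warm_model optionally a pre-trained model-1 to warm start from
#'   (avoids retraining when both variants are evaluated).
#' @return as [train_model()].
#' @export
train_variant <- function(data, variant = c("base", "model1", "model2"),
                          cfg = train_config(), seed = 1L,
                          lr_init_base = 0.01, lr_init_model1 = 0.01,
                          lr_init_model2 = 0.001, warm_model = NULL) {
  variant <- match.arg(variant)
  if (variant == "base") {
    model <- build_model(model_config("bn"), seed)
    return(train_model(model, data, cfg, lr_init = lr_init_base))
  }
  if (variant == "model1") {
    model <- build_model(model_config("iternorm"), seed)
    return(train_model(model, data, cfg, lr_init = lr_init_model1))
  }
  if (is.null(warm_model)) {
    warm_model <- train_variant(data, "model1", cfg, seed,
                                lr_init_model1 = lr_init_model1)$model
  }
  model <- add_rotation_modules(warm_model)
  train_model(model, data, cfg, epochs = cfg$warm_epochs,
              lr_init = lr_init_model2)
}
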