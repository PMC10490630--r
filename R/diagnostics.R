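# Latent-space diagnostics: feature-pair correlation maps, top-activated
# signatures per class-aligned axis, and occlusion-based empirical
# receptive fields.

# normalization-layer outputs of one block for a set of images, unrolled
# to d x (n * positions); processed in batches to bound memory
collect_norm_outputs <- function(model, images, layer_index,
                                 batch_size = 64L) {
  if (inherits(images, "md_dataset")) images <- images$images
  n <- dim(images)[3]
  parts <- list()
  i <- 1L
  while (i <= n) {
    j <- min(n, i + batch_size - 1L)
    fw <- model_forward(model, images[, , i:j, drop = FALSE],
                        training = FALSE, collect = TRUE)
    parts[[length(parts) + 1L]] <- fw$cache$blocks[[layer_index]]$norm_output
    i <- j + 1L
  }
  dims <- attr(parts[[1]], "conv_dims")
  list(X = do.call(cbind, parts), positions = dims[1] * dims[2])
}

#' Feature-pair correlation map at a normalization layer output
#'
#' Collects the output of the normalization module of one block over a
#' test set (inference mode), unrolls it to `d x (samples * positions)`
#' following the same convention as the normalization layers, and returns
#' the absolute Pearson correlation of every feature pair. Features with
#' (near-)zero variance yield correlation 0 by convention and are listed
#' in the `"constant_features"` attribute.
#'
#' @param model a trained `md_model`.
#' @param data an [md_dataset()] or image array.
#' @param layer_index block index (1..3).
#' @return `d x d` matrix of absolute correlations, class
#'   `md_correlation_map`.
#' @export
feature_correlations <- function(model, data, layer_index) {
  co <- collect_norm_outputs(model, data, layer_index)
  X <- co$X
  sds <- apply(X, 1, stats::sd)
  const <- which(sds < 1e-12)
  cm <- matrix(0, nrow(X), nrow(X))
  ok <- setdiff(seq_len(nrow(X)), const)
  if (length(ok) >= 2)
    cm[ok, ok] <- abs(stats::cor(t(X[ok, , drop = FALSE])))
  diag(cm)[ok] <- 1
  attr(cm, "constant_features") <- const
  attr(cm, "layer_index") <- layer_index
  class(cm) <- c("md_correlation_map", class(cm))
  cm
}

#' Mean absolute off-diagonal correlation
#'
#' Summary statistic of a correlation map: the mean of `|r|` over all
#' off-diagonal feature pairs.
#'
#' @param cm matrix from [feature_correlations()].
#' @return scalar.
#' @export
mean_offdiag <- function(cm) {
  d <- nrow(cm)
  (sum(cm) - sum(diag(cm))) / (d * (d - 1))
}

# spatial-mean activation of each sample on each channel at one layer:
# samples x d matrix
axis_activations <- function(model, images, layer_index) {
  co <- collect_norm_outputs(model, images, layer_index)
  pos <- co$positions
  n <- ncol(co$X) / pos
  acts <- matrix(0, n, nrow(co$X))
  for (i in seq_len(n))
    acts[i, ] <- rowMeans(co$X[, ((i - 1) * pos + 1):(i * pos), drop = FALSE])
  acts
}

#' Top-activated signature per class-aligned latent axis
#'
#' For each class axis (the first `Nc` channels of a rotation-augmented
#' layer), finds the test signature with the maximal activation, where a
#' sample's activation on an axis is the spatial mean of that channel's
#' normalization output. Ties break toward the lowest sample index.
#'
#' @param model a trained `md_model` (meaningful for the
#'   rotation-augmented variant, whose axes are class-aligned).
#' @param data an [md_dataset()].
#' @param layer_index block index (1..3).
#' @return data frame with one row per class axis: `axis`, `axis_class`,
#'   `sample_index`, `true_label`, `activation`, and logical `match`.
#' @export
top_activated <- function(model, data, layer_index) {
  acts <- axis_activations(model, data$images, layer_index)
  nc <- model$cfg$num_classes
  classes <- levels(data$labels)
  idx <- vapply(seq_len(nc), function(a) which.max(acts[, a]), integer(1))
  data.frame(axis = seq_len(nc), axis_class = classes,
             sample_index = idx,
             true_label = as.character(data$labels[idx]),
             activation = acts[cbind(idx, seq_len(nc))],
             match = classes == as.character(data$labels[idx]))
}

#' Occlusion-based empirical receptive field
#'
#' Slides a square masking patch over the image on a regular grid and
#' records, for every position, the reduction in the activation of one
#' latent axis (spatial-mean channel activation at the given layer). The
#' patch is filled with seeded uniform noise spanning the image's
#' intensity range (`fill = "noise"`), or zeros (`fill = "zero"`).
#' With the default 32-pixel patch and stride 5 on a 75 x 75 image the
#' grid has `floor((75 - 32) / 5) + 1 = 9` positions per side, i.e. 81
#' mask positions.
#'
#' @param model a trained `md_model`.
#' @param image a single `75 x 75` matrix of raw 0..255 intensities.
#' @param layer_index block index (1..3).
#' @param axis channel/axis index.
#' @param patch mask side length in pixels.
#' @param stride mask stride in pixels.
#' @param fill `"noise"` or `"zero"`.
#' @param seed seed for the noise fill.
#' @param quantile highlight threshold: positions whose reduction exceeds
#'   this quantile form the `highlight` mask.
#' @return list with `reduction` (grid matrix), `base_activation`,
#'   `highlight` (logical grid), `patch`, `stride`.
#' @export
empirical_receptive_field <- function(model, image, layer_index, axis,
                                      patch = 32L, stride = 5L,
                                      fill = c("noise", "zero"), seed = 1L,
                                      quantile = 0.9) {
  fill <- match.arg(fill)
  stopifnot(length(dim(image)) == 2L)
  h <- nrow(image); w <- ncol(image)
  gh <- (h - patch) %/% stride + 1L
  gw <- (w - patch) %/% stride + 1L
  base <- axis_activations(model,
                           array(image, c(h, w, 1L)), layer_index)[1, axis]
  set.seed(as.integer(seed))
  rng <- range(image)
  masked <- array(0, c(h, w, gh * gw))
  k <- 0L
  for (gj in seq_len(gw)) {
    for (gi in seq_len(gh)) {
      k <- k + 1L
      img <- image
      ri <- ((gi - 1L) * stride + 1L):((gi - 1L) * stride + patch)
      rj <- ((gj - 1L) * stride + 1L):((gj - 1L) * stride + patch)
      img[ri, rj] <- if (fill == "noise")
        matrix(stats::runif(patch * patch, rng[1], rng[2]), patch) else 0
      masked[, , k] <- img
    }
  }
  acts <- axis_activations(model, masked, layer_index)[, axis]
  red <- matrix(base - acts, gh, gw)
  thr <- stats::quantile(red, quantile)
  list(reduction = red, base_activation = base,
       highlight = red >= thr, patch = patch, stride = stride)
}
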