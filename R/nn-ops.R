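# Thin R wrappers over the compiled convolution/pooling kernels plus the
# small dense/softmax pieces of the network. All activations are 4-D
# arrays (h, w, channels, m).

# returns list(y, xcol); `xcol` is an opaque cache reused by the backward
# pass; with `relu = TRUE` the activation is fused into the output copy
conv2d_forward <- function(x, w, b, relu = FALSE) {
  if (dim(x)[3] != dim(w)[3])
    stop("conv2d: input channel count does not match the filter bank")
  conv2d_fwd_cpp(x, w, b, relu)
}

conv2d_backward <- function(x, w, gy, need_gx = TRUE, xcol = NULL) {
  conv2d_bwd_cpp(x, w, gy, need_gx, xcol)
}

maxpool_forward <- function(x, size = 3L, stride = 3L) {
  maxpool_fwd_cpp(x, as.integer(size), as.integer(stride))
}

# `act` (the pre-pool, post-ReLU map) fuses the ReLU backward into the
# scatter: zero activations receive no gradient
maxpool_backward <- function(idx, gy, xdim, act) {
  maxpool_bwd_cpp(idx, gy, as.integer(xdim), act)
}

relu <- function(x) relu_fwd_cpp(x)

softmax_cols <- function(z) {
  z <- z - matrix(apply(z, 2, max), nrow(z), ncol(z), byrow = TRUE)
  e <- exp(z)
  e / matrix(colSums(e), nrow(z), ncol(z), byrow = TRUE)
}

# mean cross-entropy of column-probabilities vs integer labels (1-based)
cross_entropy <- function(probs, labels) {
  m <- ncol(probs)
  -mean(log(pmax(probs[cbind(labels, seq_len(m))], 1e-12)))
}
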