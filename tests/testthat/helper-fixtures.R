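# Shared fixtures. Expensive objects are memoized in an option-held
# environment so every test file reuses one instance per session.

cache_fixture <- function(name, fn) {
  cache <- getOption("mdwhiten.fixture.cache")
  if (is.null(cache)) {
    cache <- new.env(parent = emptyenv())
    options(mdwhiten.fixture.cache = cache)
  }
  if (!exists(name, envir = cache)) assign(name, fn(), envir = cache)
  get(name, envir = cache)
}

# small synthetic corpus: 4 subjects, 9 signatures per class
tiny_dataset <- function() {
  cache_fixture("tiny_ds", function()
    generate_dataset(n_subjects = 4L, per_class = 9L, seed = 101L))
}

# full default corpus (33 subjects, 95 per class, 570 total), seed 1
default_dataset <- function() {
  cache_fixture("default_ds", function() generate_dataset(seed = 1L))
}

# 2-class linearly separable toy images: bright quadrant top-left vs
# bottom-right, mapped onto the first two activity labels
quadrant_dataset <- function(n_per_class = 12L, seed = 5L) {
  set.seed(seed)
  n <- 2L * n_per_class
  imgs <- array(0L, c(75, 75, n))
  labs <- character(n)
  cls <- activity_classes()[1:2]
  for (i in seq_len(n)) {
    k <- (i - 1L) %% 2L + 1L
    img <- matrix(stats::rbinom(75 * 75, 1, 0.02) * 80, 75, 75)
    if (k == 1L) img[1:35, 1:35] <- img[1:35, 1:35] + 150 else
      img[41:75, 41:75] <- img[41:75, 41:75] + 150
    imgs[, , i] <- pmin(img, 255L)
    labs[i] <- cls[k]
  }
  labs <- factor(labs, levels = activity_classes())
  structure(list(images = imgs, labels = labs,
                 subject = rep(1L, n), repetition = rep(1L, n)),
            class = "md_dataset")
}

# eigen-decomposition whitening oracle with the same diagonal loading
eigen_whitening_oracle <- function(X, eps = 1e-5) {
  XC <- X - rowMeans(X)
  Sigma <- tcrossprod(XC) / ncol(X) + eps * diag(nrow(X))
  e <- eigen(Sigma, symmetric = TRUE)
  W <- e$vectors %*% (t(e$vectors) / sqrt(e$values))
  list(W = W, XW = W %*% XC, Sigma = Sigma)
}

# random activation batch resembling normalized layer outputs: iid normal
# features with per-feature offsets
random_batch <- function(d, m) {
  matrix(stats::rnorm(d * m), d, m) + stats::runif(d, -2, 2)
}
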