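# STFT spectrogram and grayscale export.

sp8 <- spectrogram_params(window_length = 8L, hop = 3L, dft_size = 16L)

test_that("spectrogram of silence is zero and frame count follows the hop", {
  D <- compute_spectrogram(rep(0 + 0i, 40), sp8)
  expect_true(all(D == 0))
  expect_equal(nrow(D), 1L + (40L - 8L) %/% 3L)
  expect_equal(ncol(D), 16L)
  expect_error(compute_spectrogram(rep(0i, 5), sp8), "shorter")
})

test_that("a complex tone peaks at the nearest Doppler bin in every frame", {
  spr <- spectrogram_params(window_length = 16L, hop = 4L, dft_size = 64L,
                            window = rep(1, 16))
  f0 <- 0.203            # cycles per sample
  v <- exp(2i * pi * f0 * (0:99))
  D <- compute_spectrogram(v, spr)
  freqs <- doppler_frequencies(spr, 1)
  for (k1 in seq_len(nrow(D))) {
    pk <- freqs[which.max(D[k1, ])]
    expect_lt(abs(pk - f0), 1 / 64 + 1e-12)
  }
})

test_that("each frame equals a directly computed windowed DFT", {
  set.seed(3)
  v <- complex(real = rnorm(30), imaginary = rnorm(30))
  D <- compute_spectrogram(v, sp8)
  for (k1 in seq_len(nrow(D))) {
    seg <- v[(k1 - 1L) * 3L + 1:8] * sp8$window
    ref <- vapply(0:15, function(k2)
      Mod(sum(seg * exp(-2i * pi * (0:7) * k2 / 16)))^2, numeric(1))
    ref <- ref[c(9:16, 1:8)]   # centered axis
    expect_equal(D[k1, ], ref, tolerance = 1e-10)
  }
})

test_that("export contract: 75 x 75, full 0..255 range, constant maps to 0", {
  set.seed(1)
  sp <- spectrogram_params(window_length = 32L, hop = 4L, dft_size = 128L)
  v <- complex(real = rnorm(400), imaginary = rnorm(400))
  D <- compute_spectrogram(v, sp)
  img <- export_signature(D, sp, prf = 1000, doppler_lim = c(-400, 400))
  expect_equal(dim(img), c(75L, 75L))
  expect_identical(min(img), 0L)
  expect_identical(max(img), 255L)

  Dc <- matrix(1, 50, 128)
  imgc <- export_signature(Dc, sp, prf = 1000, doppler_lim = c(-400, 400))
  expect_true(all(imgc == 0L))

  expect_error(export_signature(D, sp, prf = 1000,
                                doppler_lim = c(10000, 20000)),
               "degenerate")
})

test_that("constant-velocity scatterer traces the analytic Doppler ridge", {
  p <- radar_params()
  vr <- -0.9     # approaching; fD = -2 fc vr / c > 0
  sc <- scatterer(function(t) 3.4 + vr * t,
                  velocity_fn = function(t) rep_len(vr, length(t)))
  s <- simulate_baseband(list(sc), p)
  g <- range_gate(list(sc), p)
  v <- sum_range_bins(compute_range_map(s, p), g$p1, g$p2)
  # no zero padding: one DFT bin equals the window's Doppler resolution
  spn <- spectrogram_params(window_length = 256L, hop = 2L, dft_size = 256L)
  D <- compute_spectrogram(v, spn)
  freqs <- doppler_frequencies(spn, p$prf)
  ridge <- freqs[apply(D, 1, which.max)]
  fd <- -2 * p$fc * vr / 299792458
  nf <- nrow(D)
  core <- ridge[round(0.1 * nf):round(0.9 * nf)]   # central 80% of frames
  binw <- p$prf / spn$dft_size
  expect_gte(mean(abs(core - fd) <= binw), 0.8)
})
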