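#' Short-time Fourier transform parameters
#'
#' Window, hop and DFT size used to turn the range-gated slow-time signal
#' into a micro-Doppler spectrogram. Defaults follow common practice for
#' 1 kHz-PRF activity radar: Hanning window of 256 samples, hop 2 (254
#' samples overlap) and a zero-padded 2048-point DFT.
#'
#' @param window_length window length N in slow-time samples.
#' @param hop frame advance h in samples.
#' @param dft_size zero-padded DFT length (>= `window_length`).
#' @param window window samples; defaults to `signal::hanning(window_length)`.
#' @return an object of class `spectrogram_params`.
#' @export
spectrogram_params <- function(window_length = 256L, hop = 2L,
                               dft_size = 2048L, window = NULL) {
  stopifnot(window_length >= 2, hop >= 1, dft_size >= window_length)
  if (is.null(window)) window <- signal::hanning(window_length)
  stopifnot(length(window) == window_length)
  structure(list(window = as.numeric(window),
                 window_length = as.integer(window_length),
                 hop = as.integer(hop), dft_size = as.integer(dft_size)),
            class = "spectrogram_params")
}

#' Spectrogram (squared-magnitude STFT) of a complex slow-time signal
#'
#' Computes `D(k1, k2) = |sum_n v(n + k1 h) w(n) exp(-j 2 pi n k2 / Nf)|^2`
#' over all frames for which the full window fits, with `Nf = dft_size`.
#' The Doppler axis is DFT-shifted so that zero Doppler sits at the center
#' column; column `k` corresponds to frequency `(k - 1 - Nf/2) * prf / Nf`
#' when the slow-time sample rate is `prf`.
#'
#' @param v complex (or numeric) slow-time vector.
#' @param sp a [spectrogram_params()] object.
#' @return real matrix with one row per frame (time) and `dft_size` columns
#'   (centered Doppler); attribute `"hop"` records the frame advance.
#' @export
compute_spectrogram <- function(v, sp) {
  stopifnot(inherits(sp, "spectrogram_params"))
  n <- sp$window_length
  if (length(v) < n) stop("signal shorter than the analysis window")
  nframes <- 1L + (length(v) - n) %/% sp$hop
  seg <- matrix(0 + 0i, sp$dft_size, nframes)
  starts <- (seq_len(nframes) - 1L) * sp$hop
  even <- sp$dft_size %% 2L == 0L
  # for even DFT sizes, modulating the window by (-1)^n shifts the output
  # bins by Nf/2, i.e. performs the zero-Doppler centering inside the FFT
  w <- if (even) sp$window * rep_len(c(1, -1), n) else sp$window
  for (k in seq_len(nframes))
    seg[seq_len(n), k] <- v[starts[k] + seq_len(n)] * w
  ft <- stats::mvfft(seg)
  spec <- Re(ft)^2 + Im(ft)^2
  if (!even) {
    half <- sp$dft_size %/% 2L
    spec <- spec[c((half + 1L):sp$dft_size, 1L:half), , drop = FALSE]
  }
  out <- t(spec)
  attr(out, "hop") <- sp$hop
  out
}

#' Doppler frequencies of the centered spectrogram columns
#'
#' @param sp a [spectrogram_params()] object.
#' @param prf slow-time sample rate (pulse repetition frequency) in Hz.
#' @return numeric vector of length `dft_size`.
#' @export
doppler_frequencies <- function(sp, prf) {
  nf <- sp$dft_size
  (seq_len(nf) - 1L - nf %/% 2L) * prf / nf
}

#' Export a spectrogram as a 75 x 75 grayscale micro-Doppler signature
#'
#' Maps the spectrogram to decibels (`20 * log10(D + floor)`), clips to a
#' fixed dynamic range below the peak, crops the Doppler extent (and
#' optionally the time extent), bilinearly rescales to `out_size`, and
#' linearly maps intensities to integers 0..255 (a constant image maps to
#' 0). The returned image has Doppler on the vertical axis (positive
#' Doppler up) and time on the horizontal axis.
#'
#' @param D spectrogram matrix from [compute_spectrogram()] (rows = frames).
#' @param sp the [spectrogram_params()] used to compute `D`.
#' @param prf slow-time sample rate in Hz.
#' @param doppler_lim two-element vector, Doppler crop in Hz.
#' @param time_frac two-element vector in `[0, 1]`, fraction of frames kept.
#' @param dynamic_range_db clip depth below the peak, in dB of `20 log10`.
#' @param out_size output image size (rows, cols).
#' @return integer matrix `out_size`, values 0..255, with attributes
#'   `doppler_lim` and `n_frames`.
#' @export
export_signature <- function(D, sp, prf, doppler_lim = c(-250, 250),
                             time_frac = c(0, 1), dynamic_range_db = 60,
                             out_size = c(75L, 75L)) {
  stopifnot(is.matrix(D), nrow(D) >= 1, ncol(D) >= 1)
  freqs <- doppler_frequencies(sp, prf)
  fsel <- which(freqs >= doppler_lim[1] & freqs <= doppler_lim[2])
  t0 <- max(1L, 1L + floor(time_frac[1] * nrow(D)))
  t1 <- min(nrow(D), ceiling(time_frac[2] * nrow(D)))
  if (length(fsel) == 0L || t0 > t1) stop("degenerate crop region")
  sub <- D[t0:t1, fsel, drop = FALSE]

  db <- 20 * log10(sub + 1e-12)
  db <- pmax(db, max(db) - dynamic_range_db)
  # orient: rows = Doppler (positive up), cols = time
  img <- t(db)[rev(seq_along(fsel)), , drop = FALSE]

  # EBImage uses (x, y) = (col, row) ordering: transpose in, transpose out
  resized <- EBImage::resize(EBImage::Image(t(img)), w = out_size[2],
                             h = out_size[1])
  img <- t(EBImage::imageData(resized))
  rng <- range(img)
  # a spread at rounding level means the input was constant
  if (rng[2] - rng[1] <= 1e-9 * max(abs(rng), 1)) rng[2] <- rng[1]
  out <- if (rng[2] > rng[1]) {
    round((img - rng[1]) / (rng[2] - rng[1]) * 255)
  } else matrix(0, nrow(img), ncol(img))
  storage.mode(out) <- "integer"
  attr(out, "doppler_lim") <- doppler_lim
  attr(out, "n_frames") <- t1 - t0 + 1L
  out
}
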