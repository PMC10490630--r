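#' FMCW radar waveform parameters
#'
#' Bundles the parameters of a frequency-modulated continuous-wave (FMCW)
#' radar operating in sawtooth chirp mode. The chirp rate is derived as
#' `bandwidth / chirp_duration` and the fast-time sample rate as
#' `samples_per_chirp / chirp_duration` (one beat-note record per chirp).
#'
#' Defaults mirror a 5.8 GHz healthcare sensing radar: 400 MHz sweep, 1 ms
#' chirps, 128 fast-time samples per chirp, 2000 chirps (2 s dwell, 1 kHz
#' pulse repetition frequency).
#'
#' @param fc carrier frequency in Hz.
#' @param bandwidth swept bandwidth in Hz.
#' @param chirp_duration chirp (pulse repetition) interval in seconds.
#' @param samples_per_chirp number of fast-time samples (range bins) N1.
#' @param num_chirps number of slow-time samples (chirps) N2.
#' @return an object of class `radar_params`.
#' @export
radar_params <- function(fc = 5.8e9, bandwidth = 400e6, chirp_duration = 1e-3,
                         samples_per_chirp = 128L, num_chirps = 2000L) {
  stopifnot(fc > 0, bandwidth > 0, chirp_duration > 0,
            samples_per_chirp >= 2, num_chirps >= 2)
  p <- list(
    fc = fc,
    bandwidth = bandwidth,
    chirp_duration = chirp_duration,
    chirp_rate = bandwidth / chirp_duration,
    n1 = as.integer(samples_per_chirp),
    n2 = as.integer(num_chirps),
    fs = samples_per_chirp / chirp_duration,
    prf = 1 / chirp_duration
  )
  class(p) <- "radar_params"
  p
}

#' @export
print.radar_params <- function(x, ...) {
  cat("FMCW radar parameters\n")
  cat(sprintf("  carrier        : %.3f GHz\n", x$fc / 1e9))
  cat(sprintf("  bandwidth      : %.0f MHz\n", x$bandwidth / 1e6))
  cat(sprintf("  chirp duration : %.3f ms (PRF %.0f Hz)\n",
              x$chirp_duration * 1e3, x$prf))
  cat(sprintf("  fast x slow    : %d x %d samples\n", x$n1, x$n2))
  invisible(x)
}

#' Moving point scatterer
#'
#' A point reflector described by its slow-time trajectories: a range
#' trajectory `r(t)` (meters), an amplitude trajectory `A(t)` (unitless,
#' non-negative), and optionally an analytic radial-velocity trajectory
#' `dr/dt` used for the Doppler term. When `velocity_fn` is omitted the
#' radial velocity is obtained by central finite differences of `range_fn`.
#'
#' @param range_fn function of time (s) returning range (m), vectorized.
#' @param amplitude amplitude trajectory: either a single non-negative
#'   number or a vectorized function of time.
#' @param velocity_fn optional function of time returning `dr/dt` (m/s).
#' @return an object of class `scatterer`.
#' @export
scatterer <- function(range_fn, amplitude = 1, velocity_fn = NULL) {
  stopifnot(is.function(range_fn))
  amp_fn <- if (is.function(amplitude)) amplitude else {
    stopifnot(amplitude >= 0)
    a <- amplitude
    function(t) rep_len(a, length(t))
  }
  if (is.null(velocity_fn)) {
    dt <- 1e-4
    velocity_fn <- function(t) (range_fn(t + dt) - range_fn(t - dt)) / (2 * dt)
  }
  structure(list(range_fn = range_fn, amplitude_fn = amp_fn,
                 velocity_fn = velocity_fn),
            class = "scatterer")
}

#' Simulate the dechirped complex baseband return
#'
#' Superimposes the complex baseband returns of a set of point scatterers on
#' the fast-time x slow-time grid. Each scatterer contributes
#' \deqn{A_i \exp\{j 2\pi[(f_{D,i} - \alpha\tau_i)\,t - f_c \tau_i]\}}
#' with two-way delay \eqn{\tau_i = 2 r_i / c} and Doppler shift
#' \eqn{f_{D,i} = -2 f_c \dot r_i / c}. The stop-and-hop convention is used:
#' \eqn{\tau_i} and \eqn{f_{D,i}} are held fixed within a chirp and
#' re-evaluated at the start of every chirp, so articulated motion enters
#' through the slow-time phase history \eqn{-2\pi f_c \tau_i(t_2)}.
#'
#' @param scatterers list of [scatterer()] objects (may be empty).
#' @param params a [radar_params()] object.
#' @return complex matrix of dim `c(n1, n2)` (fast time in rows).
#' @export
simulate_baseband <- function(scatterers, params) {
  stopifnot(inherits(params, "radar_params"))
  n1 <- params$n1; n2 <- params$n2
  if (length(scatterers) == 0L) return(matrix(0 + 0i, n1, n2))
  sT <- matrix(0 + 0i, n2, n1)                     # transposed for locality
  t_slow <- (seq_len(n2) - 1) * params$chirp_duration
  cc <- 299792458
  for (sc in scatterers) {
    stopifnot(inherits(sc, "scatterer"))
    r <- sc$range_fn(t_slow)
    v <- sc$velocity_fn(t_slow)
    a <- sc$amplitude_fn(t_slow)
    if (!all(is.finite(r)) || !all(is.finite(v)) || !all(is.finite(a)))
      stop("scatterer trajectory produced non-finite values")
    if (any(r <= 0)) stop("scatterer range trajectory must stay positive")
    tau <- 2 * r / cc
    fd <- -2 * params$fc * v / cc
    # phase(n1, n2) = 2*pi*((fd - alpha*tau) * t_fast - fc * tau);
    # along fast time the phasor advances geometrically per chirp, so one
    # complex multiply per fast-time sample replaces an exp() per element
    fast_freq <- fd - params$chirp_rate * tau       # length n2
    cur <- a * exp(-2i * pi * params$fc * tau)      # fast-time sample 0
    step <- exp(2i * pi * fast_freq / params$fs)
    for (i1 in seq_len(n1)) {
      sT[, i1] <- sT[, i1] + cur
      cur <- cur * step
    }
  }
  t(sT)
}

#' Range map via fast-time DFT
#'
#' Applies the normalized discrete Fourier transform along fast time,
#' `R(p, n2) = (1/N1) sum_n1 s(n1, n2) exp(-j 2 pi p n1 / N1)`, yielding one
#' range profile per chirp. Range-bin indices `p` are zero-based DFT bins.
#'
#' Note the sign convention: with the dechirped baseband phase
#' `-2 pi alpha tau t`, a scatterer with beat frequency `alpha * tau`
#' appears at the conjugate bin `N1 - alpha * tau * chirp_duration`
#' (modulo N1). [range_to_bin()] maps a physical range to the bin where its
#' return peaks under this convention.
#'
#' @param s complex fast x slow matrix from [simulate_baseband()].
#' @param params a [radar_params()] object.
#' @return complex matrix of the same shape (rows = range bins).
#' @export
compute_range_map <- function(s, params) {
  stopifnot(inherits(params, "radar_params"))
  if (nrow(s) != params$n1 || ncol(s) != params$n2)
    stop("baseband matrix shape does not match radar parameters")
  stats::mvfft(s) / params$n1
}

#' Map a physical range to its peak range bin
#'
#' Returns the zero-based fast-time DFT bin at which a return from range
#' `r` peaks in [compute_range_map()] output (the conjugate of the beat
#' frequency bin `alpha * tau * chirp_duration`; see the sign convention
#' described there).
#'
#' @param r range in meters (vectorized).
#' @param params a [radar_params()] object.
#' @return integer vector of zero-based bin indices in `0..N1-1`.
#' @export
range_to_bin <- function(r, params) {
  cc <- 299792458
  beat_bins <- params$chirp_rate * (2 * r / cc) * params$chirp_duration
  as.integer((params$n1 - round(beat_bins)) %% params$n1)
}

#' Sum a range map over the range bins of interest
#'
#' Collapses the range dimension by summing rows `p1..p2` (inclusive,
#' zero-based DFT bin indices), producing the slow-time signal whose
#' short-time Fourier transform is the micro-Doppler signature.
#'
#' @param R complex range map (rows = range bins).
#' @param p1,p2 zero-based first and last range bin, `p1 <= p2`.
#' @return complex vector of length `ncol(R)`.
#' @export
sum_range_bins <- function(R, p1, p2) {
  stopifnot(p1 >= 0, p2 < nrow(R))
  if (p1 > p2) stop("p1 must not exceed p2")
  rows <- (p1:p2) + 1L
  if (length(rows) == 1L) R[rows, ] else colSums(R[rows, , drop = FALSE])
}

#' Default range gate for a set of scatterers
#'
#' Evaluates the scatterer range trajectories over the dwell, converts the
#' extent to range bins (conjugate-bin convention of [compute_range_map()])
#' and pads by one guard bin on each side.
#'
#' @param scatterers list of [scatterer()] objects.
#' @param params a [radar_params()] object.
#' @param guard number of guard bins added on each side.
#' @return list with zero-based elements `p1`, `p2`.
#' @export
range_gate <- function(scatterers, params, guard = 1L) {
  t_slow <- (seq_len(params$n2) - 1) * params$chirp_duration
  rng <- range(unlist(lapply(scatterers, function(sc) range(sc$range_fn(t_slow)))))
  bins <- range_to_bin(rng, params)   # larger range -> smaller conjugate bin
  p1 <- max(0L, min(bins) - as.integer(guard))
  p2 <- min(params$n1 - 1L, max(bins) + as.integer(guard))
  list(p1 = p1, p2 = p2)
}
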