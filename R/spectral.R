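# Band filtering, analytic-signal phase/envelope extraction, Welch PSD.

#' Design a zero-phase band-pass filter
#'
#' Linear-phase FIR band-pass designed by frequency sampling
#' ([signal::fir2()]) with a flat passband covering `[f_lo, f_hi]` and
#' explicit transition bands outside it, so that a component at the nominal
#' band edge is passed at (close to) unit gain while one octave outside the
#' band is attenuated by more than 20 dB.  Applied with group-delay
#' compensation the filter is exactly zero-phase (symmetric taps).
#'
#' The transition bands extend `max(2, 0.2 * (f_hi - f_lo))` Hz beyond a
#' small (5% of bandwidth) flat-band extension, but never below half the
#' lower edge (this pins the low-side stopband at one octave below
#' `f_lo`).  The filter order follows the transition width
#' (`3.3 * fs / width`, the Hamming-window rule) and is capped so that the
#' group delay fits comfortably inside the signal.
#'
#' @param fs sampling rate (Hz).
#' @param f_lo,f_hi band edges (Hz), `0 < f_lo < f_hi < fs/2`.
#' @param n_sig length (samples) of the signal the filter will be applied
#'   to; caps the filter order.
#' @return numeric vector of FIR coefficients (odd length, symmetric).
#' @keywords internal
fir_bandpass <- function(fs, f_lo, f_hi, n_sig) {
  nyq <- fs / 2
  if (f_lo <= 0 || f_hi <= f_lo)
    stop("invalid band: need 0 < f_lo < f_hi")
  if (f_hi >= nyq)
    stop("f_hi (", f_hi, " Hz) must be below the Nyquist frequency (",
         nyq, " Hz)")
  bw <- f_hi - f_lo
  ext <- 0.05 * bw
  w_lo <- max(min(f_lo / 2 - ext, max(2, 0.2 * bw)), 0.2)
  w_hi <- max(min(max(2, 0.2 * bw), nyq - (f_hi + ext) - 1e-9), 0.2)
  ord <- ceiling(3.3 * fs / min(w_lo, w_hi))
  ord <- min(ord, 2 * floor((n_sig - 1) / 6))
  if (ord < 8) stop("signal too short to design a band-pass filter")
  if (ord %% 2 == 1) ord <- ord + 1
  f <- c(0, max(f_lo - ext - w_lo, 0) / nyq, max(f_lo - ext, 0.005) / nyq,
         min(f_hi + ext, nyq * 0.999) / nyq,
         min((f_hi + ext + w_hi) / nyq, 1), 1)
  m <- c(0, 0, 1, 1, 0, 0)
  # collapse degenerate points (band close to Nyquist)
  if (f[5] >= 1 - 1e-12) { f <- c(f[1:4], 1); m <- c(0, 0, 1, 1, 0) }
  as.numeric(signal::fir2(ord, f, m))
}

#' Zero-phase band-pass filtering
#'
#' Filters `x` through a linear-phase FIR band-pass (see [fir_bandpass()])
#' and compensates the group delay, giving a zero-phase response: no phase
#' distortion at any frequency, which is essential before instantaneous
#' phase estimation.  Edge transients remain at both ends of the output
#' (the reason phase/amplitude series are trimmed with [trim_edges()]
#' downstream).
#'
#' @param x numeric signal vector.
#' @param f_lo,f_hi band edges in Hz.
#' @param fs sampling rate in Hz.
#' @return filtered signal, same length as `x`.
#' @examples
#' fs <- 1000
#' t <- (0:(2 * fs - 1)) / fs
#' x <- sin(2 * pi * 6 * t) + sin(2 * pi * 60 * t)
#' y <- bandpass(x, 3, 8, fs)   # keeps the 6 Hz component
#' @export
bandpass <- function(x, f_lo, f_hi, fs) {
  if (!is.numeric(x) || length(x) < 32)
    stop("x must be a numeric signal of at least 32 samples")
  h <- fir_bandpass(fs, f_lo, f_hi, length(x))
  d <- (length(h) - 1) / 2
  n <- length(x); m <- length(h)
  # FFT convolution padded to a 2-3-5-smooth length (arbitrary lengths
  # can hit near-prime sizes where the mixed-radix FFT degrades badly)
  L <- stats::nextn(n + m - 1, c(2, 3, 5))
  y <- Re(stats::fft(stats::fft(c(x, numeric(L - n))) *
                       stats::fft(c(h, numeric(L - m))),
                     inverse = TRUE)) / L
  y[(d + 1):(d + n)]
}

# analytic signal via the frequency-domain Hilbert construction
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Instantaneous phase of a narrow-band signal
#'
#' Phase of the analytic signal (frequency-domain Hilbert transform), in
#' radians in `[-pi, pi)`.  Phase 0 corresponds to the positive peak of the
#' oscillation (cosine convention).  Input should already be band-passed;
#' phase of a broadband signal is not meaningful.
#'
#' @param x numeric vector, a band-passed signal.
#' @return phase series in radians; all-`NA` (with a warning) for an
#'   all-zero input, where phase is undefined.
#' @seealso [extract_amplitude()], [bandpass()]
#' @export
extract_phase <- function(x) {
  if (all(x == 0)) {
    warning("all-zero signal: phase is undefined")
    return(rep(NA_real_, length(x)))
  }
  ph <- Arg(analytic_signal(x))
  ph[ph >= pi] <- ph[ph >= pi] - 2 * pi
  ph
}

#' Amplitude envelope of a narrow-band signal
#'
#' Modulus of the analytic signal.  For `a * sin(2 pi f t)` the envelope is
#' `a` (away from the signal ends).
#'
#' @param x numeric vector, a band-passed signal.
#' @return non-negative envelope series, same length as `x`.
#' @export
extract_amplitude <- function(x) {
  Mod(analytic_signal(x))
}

#' Trim filter edge transients
#'
#' Removes `trim_ms` milliseconds from both ends of a series, the standard
#' guard against filter edge effects before phase/amplitude statistics.
#'
#' @param x numeric vector.
#' @param fs sampling rate in Hz.
#' @param trim_ms milliseconds to drop from each end (default 50).
#' @return `x` shortened by `2 * trim_ms * fs / 1000` samples.
#' @export
trim_edges <- function(x, fs, trim_ms = 50) {
  k <- round(trim_ms * fs / 1000)
  if (length(x) <= 2 * k)
    stop("series of ", length(x), " samples is too short to trim ",
         trim_ms, " ms (", k, " samples) from each end")
  if (k == 0) return(x)
  x[(k + 1):(length(x) - k)]
}

#' Welch power spectral density
#'
#' Averaged modified periodogram: Hann-windowed segments of `window_s`
#' seconds with 50% overlap, one-sided density scaled so that the
#' integral of the PSD over frequency equals the signal variance
#' (Parseval).
#'
#' @param x numeric signal of at least `window_s` seconds.
#' @param fs sampling rate in Hz.
#' @param window_s segment length in seconds (default 1).
#' @param overlap fractional segment overlap (default 0.5).
#' @return data.frame with columns `freq` (Hz) and `power` (units^2 / Hz).
#' @export
psd_welch <- function(x, fs, window_s = 1, overlap = 0.5) {
  L <- round(window_s * fs)
  if (length(x) < L)
    stop("need at least ", window_s, " s of signal (", L, " samples)")
  hop <- max(1L, round(L * (1 - overlap)))
  starts <- seq(1L, length(x) - L + 1L, by = hop)
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(L - 1)) / (L - 1))
  scale <- fs * sum(w^2)
  nf <- floor(L / 2) + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + L - 1L)]
    seg <- (seg - mean(seg)) * w
    P <- Mod(stats::fft(seg))^2 / scale
    acc <- acc + P[1:nf]
  }
  pw <- acc / length(starts)
  # fold negative frequencies into the one-sided density
  if (L %% 2 == 0) pw[2:(nf - 1L)] <- 2 * pw[2:(nf - 1L)]
  else pw[2:nf] <- 2 * pw[2:nf]
  data.frame(freq = (0:(nf - 1L)) * fs / L, power = pw)
}

#' Integrated band power from a PSD
#'
#' Rectangular integration of the PSD over `[band[1], band[2]]`.
#'
#' @param psd data.frame from [psd_welch()].
#' @param band length-2 numeric, band edges in Hz.
#' @return scalar power (signal units squared).
#' @export
band_power <- function(psd, band) {
  stopifnot(is.data.frame(psd), all(c("freq", "power") %in% names(psd)),
            length(band) == 2, band[1] < band[2])
  if (band[1] < min(psd$freq) - 1e-9 || band[2] > max(psd$freq) + 1e-9)
    stop("band [", band[1], ", ", band[2], "] Hz lies outside the PSD range")
  df <- psd$freq[2] - psd$freq[1]
  sel <- psd$freq >= band[1] & psd$freq <= band[2]
  sum(psd$power[sel]) * df
}
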