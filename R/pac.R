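# Phase-amplitude coupling: binned amplitude distributions, the
# KL-distance modulation index, comodulograms, cross-trial distribution
# correlation, circular-shift surrogates, and channel selection.

#' Phase-amplitude distribution
#'
#' Bins the instantaneous phase of the slow band into `n_bins` equal
#' intervals (default 18 bins of 20 degrees covering \[-180, 180)), takes
#' the mean fast-band envelope within each bin, and normalizes the bin
#' means to sum to one.  The resulting vector P is the object the
#' modulation index and the cross-trial correlation statistic operate on:
#' under no coupling P is flat, under coupling it concentrates around the
#' preferred phase.
#'
#' @param phase numeric vector of phases in radians in `[-pi, pi)`.
#' @param amplitude numeric vector of envelope values (same length).
#' @param n_bins number of phase bins (default 18, i.e. 20 degree bins).
#' @return object of class `"pa_distribution"`: list with `p` (bin
#'   masses summing to 1), `bin_edges` and `bin_centers` in degrees, and
#'   `n` (samples used).
#' @examples
#' ph <- seq(-pi, pi - 1e-9, length.out = 3600)
#' pad <- phase_amplitude_distribution(ph, 1 + cos(ph))
#' modulation_index(pad)
#' @export
phase_amplitude_distribution <- function(phase, amplitude, n_bins = 18) {
  if (length(phase) != length(amplitude))
    stop("phase and amplitude series must have equal length")
  ok <- is.finite(phase) & is.finite(amplitude)
  phase <- phase[ok]; amplitude <- amplitude[ok]
  if (!length(phase)) stop("no finite phase/amplitude samples")
  if (any(amplitude < 0)) stop("amplitude envelope must be non-negative")
  width <- 360 / n_bins
  deg <- phase * 180 / pi
  deg[deg >= 180] <- deg[deg >= 180] - 360
  deg[deg < -180] <- deg[deg < -180] + 360
  bin <- pmin(floor((deg + 180) / width) + 1L, n_bins)
  counts <- tabulate(bin, n_bins)
  if (any(counts == 0)) {
    empty <- which(counts == 0)
    centers <- -180 + width * (empty - 0.5)
    stop("empty phase bin(s) at ", paste(centers, collapse = ", "),
         " degrees; use a longer epoch")
  }
  sums <- numeric(n_bins)
  agg <- rowsum(amplitude, bin)
  sums[as.integer(rownames(agg))] <- agg[, 1]
  m <- sums / counts
  structure(list(p = m / sum(m),
                 bin_edges = seq(-180, 180, by = width),
                 bin_centers = -180 + width * (seq_len(n_bins) - 0.5),
                 n = length(phase)),
            class = "pa_distribution")
}

#' @export
print.pa_distribution <- function(x, ...) {
  cat("Phase-amplitude distribution:", length(x$p), "bins of",
      360 / length(x$p), "deg,", x$n, "samples\n")
  cat("  peak bin center:", x$bin_centers[which.max(x$p)], "deg;  MI =",
      signif(modulation_index(x), 4), "\n")
  invisible(x)
}

as_p_vector <- function(P) {
  if (inherits(P, "pa_distribution")) P$p
  else if (is.numeric(P)) P
  else stop("P must be a pa_distribution or a numeric vector of bin masses")
}

#' Modulation index (normalized KL distance from uniformity)
#'
#' The Kullback-Leibler distance of the phase-amplitude distribution P
#' from the uniform distribution, normalized by its maximum `log(N)`:
#' `MI = (log N - H(P)) / log N`, with Shannon entropy
#' `H(P) = -sum(p * log(p))` (natural log, `0 * log 0 = 0`).  MI is 0 iff
#' P is uniform (no coupling) and 1 iff P is a point mass (all fast-band
#' amplitude at one phase bin).  MI is invariant to amplitude scaling and
#' to cyclic rotation of P, so it measures coupling strength but not the
#' preferred phase.
#'
#' @param P a `"pa_distribution"` or a numeric probability vector.
#' @return scalar in `[0, 1]`.
#' @export
modulation_index <- function(P) {
  p <- as_p_vector(P)
  if (any(p < 0)) stop("P has negative bin masses")
  if (abs(sum(p) - 1) > 1e-6)
    stop("P is not normalized: sum = ", format(sum(p), digits = 10))
  n <- length(p)
  nz <- p > 0
  H <- -sum(p[nz] * log(p[nz]))
  (log(n) - H) / log(n)
}

#' Modulation index for one frequency pair
#'
#' The full single-pair chain: band-pass the signal in the phase band and
#' the amplitude band, extract instantaneous phase and envelope, trim
#' `trim_ms` from both ends of each series (filter edge effects), bin into
#' the phase-amplitude distribution, and return its modulation index.
#'
#' @param x numeric signal (at least 1 s).
#' @param fs sampling rate in Hz.
#' @param f_p_band length-2 numeric, phase (slow) band in Hz.
#' @param f_A_band length-2 numeric, amplitude (fast) band in Hz.
#' @param trim_ms edge trim in ms (default 50).
#' @param n_bins phase bins (default 18).
#' @return scalar modulation index.
#' @export
mi_for_pair <- function(x, fs, f_p_band, f_A_band, trim_ms = 50,
                        n_bins = 18) {
  if (length(x) < fs) stop("need at least 1000 ms of signal")
  ph <- trim_edges(extract_phase(bandpass(x, f_p_band[1], f_p_band[2], fs)),
                   fs, trim_ms)
  am <- trim_edges(
    extract_amplitude(bandpass(x, f_A_band[1], f_A_band[2], fs)),
    fs, trim_ms)
  modulation_index(phase_amplitude_distribution(ph, am, n_bins))
}

#' Default comodulogram frequency grids
#'
#' Phase-frequency centers 2-20 Hz in 1 Hz steps (19 values) and
#' amplitude-frequency centers 20-180 Hz in 5 Hz steps (33 values).
#'
#' @return list with `phase_freqs` and `amp_freqs`.
#' @export
default_comodulogram_grid <- function() {
  list(phase_freqs = seq(2, 20, by = 1), amp_freqs = seq(20, 180, by = 5))
}

#' Comodulogram: MI over a phase-by-amplitude frequency grid
#'
#' Computes [mi_for_pair()] for every (phase frequency, amplitude
#' frequency) pair on the grid; phase bands are `center +/- phase_halfbw`
#' and amplitude bands `center +/- amp_halfbw`.  The amplitude half-width
#' (default 15 Hz) is wide enough to pass the modulation sidebands at
#' `f_A +/- f_p` that carry the coupling.  Each band is filtered once and
#' reused across the grid.
#'
#' Cells whose amplitude band reaches the Nyquist frequency are set to
#' `NA` (flagged invalid, never silently zero).
#'
#' @param x numeric signal (at least 1 s).
#' @param fs sampling rate in Hz.
#' @param phase_freqs,amp_freqs grid centers in Hz (defaults per
#'   [default_comodulogram_grid()]).
#' @param phase_halfbw,amp_halfbw half bandwidths in Hz (defaults 1, 15).
#' @param trim_ms edge trim in ms (default 50).
#' @param n_bins phase bins (default 18).
#' @return object of class `"comodulogram"`: list with `mi` (matrix,
#'   rows = phase frequencies, columns = amplitude frequencies),
#'   `phase_freqs`, `amp_freqs`, and the bandwidths.
#' @export
comodulogram <- function(x, fs,
                         phase_freqs = default_comodulogram_grid()$phase_freqs,
                         amp_freqs = default_comodulogram_grid()$amp_freqs,
                         phase_halfbw = 1, amp_halfbw = 15,
                         trim_ms = 50, n_bins = 18) {
  if (length(x) < fs) stop("need at least 1000 ms of signal")
  nyq <- fs / 2
  # phase series and precomputed bin indices, one per phase center
  width <- 360 / n_bins
  bins <- vector("list", length(phase_freqs))
  tabs <- vector("list", length(phase_freqs))
  for (i in seq_along(phase_freqs)) {
    fp <- phase_freqs[i]
    ph <- trim_edges(
      extract_phase(bandpass(x, max(fp - phase_halfbw, 0.25), fp + phase_halfbw, fs)),
      fs, trim_ms)
    deg <- ph * 180 / pi
    b <- pmin(floor((deg + 180) / width) + 1L, n_bins)
    bins[[i]] <- b
    tabs[[i]] <- tabulate(b, n_bins)
  }
  amps <- vector("list", length(amp_freqs))
  valid_amp <- rep(TRUE, length(amp_freqs))
  for (j in seq_along(amp_freqs)) {
    fa <- amp_freqs[j]
    if (fa + amp_halfbw >= nyq) { valid_amp[j] <- FALSE; next }
    amps[[j]] <- trim_edges(
      extract_amplitude(bandpass(x, max(fa - amp_halfbw, 1), fa + amp_halfbw, fs)),
      fs, trim_ms)
  }
  mi <- matrix(NA_real_, length(phase_freqs), length(amp_freqs),
               dimnames = list(paste0("fp_", phase_freqs),
                               paste0("fa_", amp_freqs)))
  logN <- log(n_bins)
  for (i in seq_along(phase_freqs)) {
    b <- bins[[i]]; tab <- tabs[[i]]
    if (any(tab == 0)) next  # undefined distribution, leave NA
    for (j in seq_along(amp_freqs)) {
      if (!valid_amp[j]) next
      sums <- numeric(n_bins)
      agg <- rowsum(amps[[j]], b)
      sums[as.integer(rownames(agg))] <- agg[, 1]
      m <- sums / tab
      p <- m / sum(m)
      nz <- p > 0
      mi[i, j] <- (logN + sum(p[nz] * log(p[nz]))) / logN
    }
  }
  structure(list(mi = mi, phase_freqs = phase_freqs, amp_freqs = amp_freqs,
                 phase_halfbw = phase_halfbw, amp_halfbw = amp_halfbw),
            class = "comodulogram")
}

#' @export
print.comodulogram <- function(x, ...) {
  idx <- which(x$mi == max(x$mi, na.rm = TRUE), arr.ind = TRUE)[1, ]
  cat("Comodulogram:", nrow(x$mi), "phase x", ncol(x$mi),
      "amplitude frequencies\n")
  cat("  max MI =", signif(max(x$mi, na.rm = TRUE), 4), "at fp =",
      x$phase_freqs[idx[1]], "Hz, fA =", x$amp_freqs[idx[2]], "Hz\n")
  invisible(x)
}

#' Plot a comodulogram as a pseudocolor map
#'
#' @param x a `"comodulogram"`.
#' @param ... passed to [graphics::image()].
#' @export
plot.comodulogram <- function(x, ...) {
  graphics::image(x$phase_freqs, x$amp_freqs, x$mi,
                  xlab = "phase frequency (Hz)",
                  ylab = "amplitude frequency (Hz)",
                  col = grDevices::hcl.colors(64, "viridis"), ...)
}

#' Session-standard phase-amplitude distribution
#'
#' Bin-wise mean of a set of per-trial distributions, renormalized.  Used
#' as the reference ("standard") distribution against which each trial's
#' distribution is correlated.
#'
#' @param Ps list of `"pa_distribution"` objects with identical binning.
#' @return a `"pa_distribution"`.
#' @export
standard_distribution <- function(Ps) {
  if (!length(Ps)) stop("need at least one distribution")
  Ps <- lapply(Ps, function(P)
    if (inherits(P, "pa_distribution")) P else
      phase_amplitude_distribution_from_p(P))
  nb <- vapply(Ps, function(P) length(P$p), integer(1))
  if (length(unique(nb)) != 1)
    stop("distributions have mixed bin counts: ",
         paste(unique(nb), collapse = ", "))
  m <- colMeans(do.call(rbind, lapply(Ps, `[[`, "p")))
  out <- Ps[[1]]
  out$p <- m / sum(m)
  out$n <- sum(vapply(Ps, `[[`, numeric(1), "n"))
  out
}

# wrap a bare probability vector as a pa_distribution
phase_amplitude_distribution_from_p <- function(p) {
  n_bins <- length(p)
  width <- 360 / n_bins
  structure(list(p = p / sum(p),
                 bin_edges = seq(-180, 180, by = width),
                 bin_centers = -180 + width * (seq_len(n_bins) - 0.5),
                 n = NA_integer_),
            class = "pa_distribution")
}

#' Correlation between two phase-amplitude distributions
#'
#' Correlation of the bin masses of a trial distribution against the
#' session-standard distribution.  Unlike the modulation index (rotation
#' invariant), this statistic is sensitive to the preferred phase, so it
#' measures whether coupling stays locked to the same theta phase across
#' trials.  A uniform (zero-variance) distribution has no defined
#' correlation and returns `NA` with a warning, never 0.
#'
#' @param P_trial,P_standard `"pa_distribution"` objects or probability
#'   vectors with identical binning.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return scalar in `[-1, 1]`, or `NA` if either input has zero variance.
#' @export
distribution_correlation <- function(P_trial, P_standard,
                                     method = c("pearson", "spearman")) {
  method <- match.arg(method)
  a <- as_p_vector(P_trial); b <- as_p_vector(P_standard)
  if (length(a) != length(b))
    stop("distributions have different bin counts")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("zero-variance (uniform) distribution: correlation undefined")
    return(NA_real_)
  }
  stats::cor(a, b, method = method)
}

#' Circular-shift surrogate null for the modulation index
#'
#' Breaks the phase-amplitude relationship while preserving both marginal
#' spectra: each surrogate circularly shifts the amplitude series relative
#' to the phase series by a uniform random offset of at least
#' `min_shift_ms`, then recomputes MI.  Returns the surrogate MI sample
#' and the mean surrogate distribution (which converges to flat as the
#' number of surrogates grows).
#'
#' @param phase trimmed phase series (radians).
#' @param amplitude trimmed envelope series (same length).
#' @param fs sampling rate in Hz.
#' @param n_surrogates number of surrogates (default 200).
#' @param min_shift_ms minimum shift in ms (default 100).
#' @param seed integer seed (mandatory; surrogate draws are random).
#' @param n_bins phase bins (default 18).
#' @return list with `mi` (numeric vector of surrogate MIs) and `mean_p`
#'   (the mean surrogate `"pa_distribution"`).
#' @export
surrogate_mi_null <- function(phase, amplitude, fs, n_surrogates = 200,
                              min_shift_ms = 100, seed, n_bins = 18) {
  if (missing(seed) || is.null(seed))
    stop("seed is required: surrogate generation is stochastic")
  if (length(phase) != length(amplitude))
    stop("phase and amplitude series must have equal length")
  n <- length(phase)
  min_shift <- round(min_shift_ms * fs / 1000)
  if (n <= 2 * min_shift)
    stop("series too short for circular shifts of at least ",
         min_shift_ms, " ms")
  set.seed(as.integer(seed))
  shifts <- sample(min_shift:(n - min_shift), n_surrogates, replace = TRUE)
  mis <- numeric(n_surrogates)
  acc <- numeric(n_bins)
  for (k in seq_len(n_surrogates)) {
    s <- shifts[k]
    am <- amplitude[((seq_len(n) - 1 + s) %% n) + 1]
    P <- phase_amplitude_distribution(phase, am, n_bins)
    mis[k] <- modulation_index(P)
    acc <- acc + P$p
  }
  list(mi = mis,
       mean_p = phase_amplitude_distribution_from_p(acc / n_surrogates),
       shifts = shifts)
}

#' Select the channel with the highest session-averaged MI
#'
#' Averages MI over sessions for each channel (within the frequency pair
#' of interest, computed upstream) and returns the channel with the
#' highest average.  Exact ties are broken toward the lowest channel index
#' and reported via a message.
#'
#' @param mi_by_channel numeric matrix, rows = channels (rownames are
#'   channel ids), columns = sessions; or a numeric vector of one MI per
#'   channel.
#' @return the selected channel id (rowname if present, else index).
#' @export
select_best_channel <- function(mi_by_channel) {
  if (is.vector(mi_by_channel)) mi_by_channel <- cbind(mi_by_channel)
  avg <- rowMeans(mi_by_channel, na.rm = TRUE)
  if (all(!is.finite(avg))) stop("no channel has a finite average MI")
  best <- which(avg == max(avg, na.rm = TRUE))
  if (length(best) > 1)
    message("MI tie between channels ",
            paste(names(avg)[best] %||% best, collapse = ", "),
            "; selecting the lowest")
  best <- best[1]
  if (!is.null(rownames(mi_by_channel))) rownames(mi_by_channel)[best]
  else best
}

`%||%` <- function(a, b) if (is.null(a)) b else a
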