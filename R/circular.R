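# Circular statistics for theta phases at high-frequency envelope peaks:
# mean resultant vector, Fisher confidence interval, Rayleigh test.

wrap_pi <- function(x) ((x + pi) %% (2 * pi)) - pi

#' Theta phases at high-frequency envelope peaks
#'
#' Finds local maxima of the fast-band envelope that exceed
#' `mean + threshold_sd * SD` of the envelope, and returns the slow-band
#' phase at each peak.  These angles feed the circular histogram and the
#' resultant-vector / Rayleigh statistics.  An envelope with no
#' supra-threshold peaks yields an empty sample (with a message), not an
#' error.
#'
#' @param theta_phase phase series in radians (trimmed).
#' @param hf_envelope envelope series, same length.
#' @param threshold_sd threshold in envelope SDs above the mean
#'   (default 2).
#' @return numeric vector of angles in `[-pi, pi)`; attribute
#'   `peak_index` holds the sample indices.
#' @export
phases_at_hf_peaks <- function(theta_phase, hf_envelope, threshold_sd = 2) {
  if (length(theta_phase) != length(hf_envelope))
    stop("phase and envelope series must have equal length")
  n <- length(hf_envelope)
  if (n < 3) return(numeric(0))
  d <- diff(hf_envelope)
  is_peak <- c(FALSE, d[-length(d)] > 0 & d[-1] <= 0, FALSE)
  thr <- mean(hf_envelope) + threshold_sd * stats::sd(hf_envelope)
  idx <- which(is_peak & hf_envelope > thr)
  if (!length(idx)) {
    message("no supra-threshold envelope peaks found")
    return(structure(numeric(0), peak_index = integer(0)))
  }
  structure(wrap_pi(theta_phase[idx]), peak_index = idx)
}

#' Mean resultant vector of a circular sample
#'
#' `avg_ang = atan2(sum sin, sum cos)` and resultant length
#' `r = |sum exp(i theta)| / n`.  `r = 1` iff all angles coincide; for a
#' balanced (symmetric) sample `r = 0` and the mean direction is
#' undefined (`avg_ang = NA`).
#'
#' @param angles numeric vector of angles in radians, `n >= 1`.
#' @return list with `avg_ang` (radians), `r`, and `n`.
#' @export
mean_resultant <- function(angles) {
  n <- length(angles)
  if (n < 1) stop("need at least one angle")
  C <- sum(cos(angles)); S <- sum(sin(angles))
  r <- sqrt(C^2 + S^2) / n
  avg <- if (r < 1e-12) NA_real_ else atan2(S, C)
  list(avg_ang = avg, r = r, n = n)
}

#' 95% confidence interval for the circular mean
#'
#' Fisher's large-sample interval for the mean direction, based on the
#' resultant length: half-width
#' `acos(sqrt(2n(2R^2 - n X) / (4n - X)) / R)` for `r <= 0.9` and
#' `acos(sqrt(n^2 - (n^2 - R^2) exp(X / n)) / R)` for `r > 0.9`, where
#' `R = n r` and `X` is the upper chi-squared(1) quantile at `alpha`.
#' For samples too dispersed for the interval to exist the result is
#' flagged `NA`.
#'
#' @param angles numeric vector of angles in radians, `n >= 2`.
#' @param alpha significance level (default 0.05 for a 95% CI).
#' @return list with `lo`, `hi` (radians, wrapped), `half_width`, and the
#'   mean direction `avg_ang`; all `NA` when undefined.
#' @export
circular_ci95 <- function(angles, alpha = 0.05) {
  mr <- mean_resultant(angles)
  n <- mr$n
  if (n < 2) stop("need at least 2 angles")
  if (!is.finite(mr$avg_ang) || mr$r <= 0) {
    warning("resultant length ~ 0: confidence interval undefined")
    return(list(lo = NA_real_, hi = NA_real_, half_width = NA_real_,
                avg_ang = mr$avg_ang))
  }
  R <- n * mr$r
  X <- stats::qchisq(1 - alpha, df = 1)
  arg <- if (mr$r <= 0.9) {
    inner <- 2 * n * (2 * R^2 - n * X) / (4 * n - X)
    if (inner < 0) NA_real_ else sqrt(inner) / R
  } else {
    inner <- n^2 - (n^2 - R^2) * exp(X / n)
    if (inner < 0) NA_real_ else sqrt(inner) / R
  }
  if (!is.finite(arg) || arg > 1) {
    warning("sample too dispersed: confidence interval undefined")
    return(list(lo = NA_real_, hi = NA_real_, half_width = NA_real_,
                avg_ang = mr$avg_ang))
  }
  d <- acos(pmin(arg, 1))
  list(lo = wrap_pi(mr$avg_ang - d), hi = wrap_pi(mr$avg_ang + d),
       half_width = d, avg_ang = mr$avg_ang)
}

#' Rayleigh test of circular uniformity
#'
#' Tests a circular sample against uniformity (unimodal alternative).
#' `z = n r^2`; the p-value uses the standard small-sample correction
#' `p = exp(sqrt(1 + 4n + 4(n^2 - R^2)) - (1 + 2n))` with `R = n r`.
#'
#' @param angles numeric vector of angles in radians (meaningful for
#'   `n >= 5`).
#' @return list with `z`, `p`, `r`, and `n`.
#' @export
rayleigh_test <- function(angles) {
  mr <- mean_resultant(angles)
  n <- mr$n
  R <- n * mr$r
  z <- R^2 / n
  p <- exp(sqrt(1 + 4 * n + 4 * (n^2 - R^2)) - (1 + 2 * n))
  list(z = z, p = min(p, 1), r = mr$r, n = n)
}

#' Full circular summary
#'
#' Mean resultant vector, Fisher 95% CI, and Rayleigh test in one call;
#' the standard descriptive set for a circular histogram of phases.
#'
#' @param angles numeric vector of angles in radians.
#' @return object of class `"circular_summary"`: list with `n`,
#'   `avg_ang`, `r`, `ci95` (lo, hi), `rayleigh_z`, `rayleigh_p`.
#' @export
circular_summary <- function(angles) {
  mr <- mean_resultant(angles)
  ci <- if (mr$n >= 2 && is.finite(mr$avg_ang))
    circular_ci95(angles) else list(lo = NA_real_, hi = NA_real_)
  rt <- rayleigh_test(angles)
  structure(list(n = mr$n, avg_ang = mr$avg_ang, r = mr$r,
                 ci95 = c(lo = ci$lo, hi = ci$hi),
                 rayleigh_z = rt$z, rayleigh_p = rt$p),
            class = "circular_summary")
}

#' @export
print.circular_summary <- function(x, ...) {
  cat("Circular summary: n =", x$n, "\n")
  cat(sprintf("  avgAng = %.1f deg, r = %.3f, 95%% CI [%.1f, %.1f] deg\n",
              x$avg_ang * 180 / pi, x$r, x$ci95[["lo"]] * 180 / pi,
              x$ci95[["hi"]] * 180 / pi))
  cat(sprintf("  Rayleigh z = %.3f, p = %.3g\n", x$rayleigh_z,
              x$rayleigh_p))
  invisible(x)
}
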