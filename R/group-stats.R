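# Nonparametric group comparisons: Kruskal-Wallis with Dunn's post hoc,
# Mann-Whitney U (with normal-approximation Z), Spearman correlation.
# Thin, well-specified wrappers over stats:: routines; only Dunn's
# pairwise z-tests are computed here (no installed package provides
# them).

#' Kruskal-Wallis test with Dunn's pairwise comparisons
#'
#' Omnibus Kruskal-Wallis H test across three or more groups (via
#' [stats::kruskal.test()]), followed by Dunn's rank-based pairwise
#' z-tests with tie correction and Bonferroni adjustment across all
#' pairs.  Two-group comparisons are directed to [mann_whitney()].
#'
#' @param samples named list of numeric vectors (one per group, each
#'   `n >= 2`), or a numeric vector combined with `groups`.
#' @param groups optional grouping factor when `samples` is a vector.
#' @param p_adjust adjustment method for the pairwise p-values
#'   (default `"bonferroni"`).
#' @return list of class `"pacnav_test"`: `statistic` (H), `df`, `p`,
#'   and `posthoc` (data.frame `pair`, `z`, `p_adj`, `significant`).
#' @examples
#' kruskal_wallis_dunn(list(a = c(1, 2, 3), b = c(11, 12, 13),
#'                          c = c(21, 22, 23)))
#' @export
kruskal_wallis_dunn <- function(samples, groups = NULL,
                                p_adjust = "bonferroni") {
  if (!is.list(samples)) {
    stopifnot(!is.null(groups), length(groups) == length(samples))
    samples <- split(as.numeric(samples), groups)
  }
  k <- length(samples)
  if (k < 3)
    stop("fewer than 3 groups: use mann_whitney() for two-group ",
         "comparisons")
  if (any(vapply(samples, length, integer(1)) < 2))
    stop("every group needs at least 2 observations")
  if (is.null(names(samples))) names(samples) <- paste0("g", seq_len(k))
  kw <- stats::kruskal.test(samples)

  x <- unlist(samples, use.names = FALSE)
  g <- rep(names(samples), vapply(samples, length, integer(1)))
  N <- length(x)
  rk <- rank(x)
  mean_rank <- tapply(rk, g, mean)[names(samples)]
  n_i <- tapply(rk, g, length)[names(samples)]
  ties <- table(rk)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  pairs <- utils::combn(names(samples), 2)
  z <- p_raw <- numeric(ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1, j]; b <- pairs[2, j]
    se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / n_i[[a]] + 1 / n_i[[b]]))
    z[j] <- (mean_rank[[a]] - mean_rank[[b]]) / se
    p_raw[j] <- 2 * stats::pnorm(-abs(z[j]))
  }
  p_adj <- stats::p.adjust(p_raw, method = p_adjust)
  posthoc <- data.frame(pair = paste(pairs[1, ], pairs[2, ], sep = " - "),
                        z = z, p_adj = p_adj,
                        significant = p_adj < 0.05)
  structure(list(method = "Kruskal-Wallis with Dunn's post hoc",
                 statistic = unname(kw$statistic), df = unname(kw$parameter),
                 p = kw$p.value, groups = names(samples),
                 posthoc = posthoc),
            class = "pacnav_test")
}

#' Mann-Whitney U test with normal-approximation Z
#'
#' Two-sided rank-sum test via [stats::wilcox.test()] (exact p where
#' feasible).  Reports both orientations of U (the conventional minimum
#' and `u_a`, the statistic of the first sample) and the tie-corrected
#' normal-approximation `Z = (U_a - n_a n_b / 2) / sigma`, whose sign
#' flips when the samples are swapped.
#'
#' @param a,b numeric vectors.
#' @return list of class `"pacnav_test"`: `statistic` (min-orientation
#'   U), `u_a`, `z`, `p`, `n`.
#' @export
mann_whitney <- function(a, b) {
  stopifnot(length(a) >= 1, length(b) >= 1)
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = NULL,
                                            correct = TRUE))
  na <- length(a); nb <- length(b)
  u_a <- unname(wt$statistic)
  u_min <- min(u_a, na * nb - u_a)
  x <- c(a, b); N <- na + nb
  ties <- table(rank(x))
  sigma2 <- na * nb / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  z <- if (sigma2 > 0) (u_a - na * nb / 2) / sqrt(sigma2) else NA_real_
  structure(list(method = "Mann-Whitney U", statistic = u_min, u_a = u_a,
                 z = z, p = wt$p.value, n = c(na, nb)),
            class = "pacnav_test")
}

#' Spearman rank correlation
#'
#' Rank correlation with tie handling via [stats::cor.test()]; constant
#' input has no defined rank correlation and returns `NA` with a warning.
#'
#' @param x,y numeric vectors of equal length `>= 3`.
#' @return list with `rho`, `p`, `n`.
#' @export
spearman_cor <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant input: rank correlation undefined")
    return(list(rho = NA_real_, p = NA_real_, n = length(x)))
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' @export
print.pacnav_test <- function(x, ...) {
  cat(x$method, "\n")
  if (!is.null(x$df))
    cat(sprintf("  statistic = %.4g, df = %d, p = %.4g\n", x$statistic,
                as.integer(x$df), x$p))
  else
    cat(sprintf("  U = %.4g, Z = %.4g, p = %.4g\n", x$statistic,
                x$z, x$p))
  if (!is.null(x$posthoc)) {
    cat("  pairwise (adjusted):\n")
    print(x$posthoc, row.names = FALSE)
  }
  invisible(x)
}
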