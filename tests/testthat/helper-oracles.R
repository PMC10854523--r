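# Independent oracles and samplers used across the test files.

# von Mises sampler (Best & Fisher 1979 rejection algorithm); independent
# of any package code.
rvm <- function(n, mu, kappa) {
  if (kappa == 0) return(stats::runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  rho <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 0
  while (i < n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1])
    f <- (1 + rho * z) / (rho + z)
    cc <- kappa * (rho - f)
    if (u[2] < cc * (2 - cc) || log(cc) - log(u[2]) + 1 - cc >= 0) {
      i <- i + 1
      s <- if (u[3] < 0.5) -1 else 1
      out[i] <- ((s * acos(f) + mu + pi) %% (2 * pi)) - pi
    }
  }
  out
}

# brute-force KL(P || U) / log N by direct summation (the oracle the
# modulation index must match)
mi_bruteforce <- function(p) {
  n <- length(p)
  u <- 1 / n
  s <- 0
  for (j in seq_len(n)) if (p[j] > 0) s <- s + p[j] * log(p[j] / u)
  s / log(n)
}

# smallest absolute angular difference, radians
ang_diff <- function(a, b) {
  d <- (a - b + pi) %% (2 * pi) - pi
  abs(d)
}

# shared fixture geometry for flight tests (~1.9 km release-loft)
test_release <- c(113.540, 34.820)
test_loft <- c(113.555, 34.830)
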