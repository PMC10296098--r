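# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Piecewise visible-spectrum mapping, written out independently.
oracle_pwm <- function(lambda, gamma = 0.8) {
  if (lambda >= 380 && lambda < 440) {
    rgb <- c((440 - lambda) / 60, 0, 1)
  } else if (lambda < 490) {
    rgb <- c(0, (lambda - 440) / 50, 1)
  } else if (lambda < 510) {
    rgb <- c(0, 1, (510 - lambda) / 20)
  } else if (lambda < 580) {
    rgb <- c((lambda - 510) / 70, 1, 0)
  } else if (lambda < 645) {
    rgb <- c(1, (645 - lambda) / 65, 0)
  } else {
    rgb <- c(1, 0, 0)
  }
  f <- if (lambda < 420) 0.3 + 0.7 * (lambda - 380) / 40 else
    if (lambda > 700) 0.3 + 0.7 * (780 - lambda) / 80 else 1
  ifelse(rgb == 0, 0, round(255 * (rgb * f)^gamma))
}

# Brute-force trapezoid quadrature on an arbitrary fine grid.
oracle_quadrature <- function(f, a, b, n = 200001L) {
  x <- seq(a, b, length.out = n)
  y <- f(x)
  h <- (b - a) / (n - 1L)
  h * (sum(y) - (y[1L] + y[n]) / 2)
}

# Closed-form implicit solution of the Michaelis-Menten progress curve:
# KM * log(S0/S) + (S0 - S) = a * Vmax * t, solved for S by bisection.
oracle_mm_progress <- function(t, s0, km, vmax, activity = 1) {
  vapply(t, function(tt) {
    g <- function(s) km * log(s0 / s) + (s0 - s) - activity * vmax * tt
    if (g(s0 * 1e-12) < 0) return(s0 * 1e-12)
    stats::uniroot(g, c(s0 * 1e-12, s0), tol = 1e-18)$root
  }, numeric(1))
}

# Normal-equation OLS.
oracle_ols <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  sxx <- sum(x^2); sxy <- sum(x * y)
  slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  intercept <- (sy - slope * sx) / n
  resid <- y - intercept - slope * x
  list(slope = slope, intercept = intercept,
       residual_sd = sqrt(sum(resid^2) / (n - 2)),
       r2 = 1 - sum(resid^2) / sum((y - mean(y))^2))
}

# Line-level validator for the stream dialect (brute force, used by the
# fuzzing test): a body line is valid iff it has exactly `ncol` comma fields
# that all parse as finite numbers.
oracle_valid_line <- function(line, ncol = 4L) {
  f <- trimws(strsplit(line, ",", fixed = TRUE)[[1L]])
  if (length(f) != ncol) return(FALSE)
  v <- suppressWarnings(as.numeric(f))
  !anyNA(v) && all(is.finite(v))
}

# The seven twofold substrate levels of the optimization series, in mol/L.
substrate_levels <- function() mmol_per_L(2 / 2^(0:6))

# A small deterministic control stream used by several analysis tests.
twin_control_stream <- function(...) {
  run_assay(ellman_scenario(...))
}
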