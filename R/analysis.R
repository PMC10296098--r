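#' Endpoint evaluation of a frequency stream
#'
#' The endpoint statistic of the assay: the absolute difference between the
#' mean of the first `k` readings and the mean of the `k` readings nearest
#' the end of the evaluation window. Means of at least ten readings are used
#' by default, matching how streamed values are aggregated per calibrator.
#'
#' @param stream a [frequency_stream()] spanning at least `window_s`.
#' @param window_s evaluation window (s, default 300 = 5 min).
#' @param k readings averaged at each end (default 10).
#' @return nonnegative frequency difference in Hz.
#' @export
endpoint_delta <- function(stream, window_s = 300, k = 10) {
  stopifnot(inherits(stream, "frequency_stream"))
  # allow the last reading to fall short of the window by one reading interval
  slack <- if (nrow(stream) > 1L) 2 * max(diff(stream$time_s)) else 0
  if (nrow(stream) < k || max(stream$time_s) + slack < window_s) {
    stop("stream does not span the ", window_s,
         " s evaluation window with at least ", k, " readings", call. = FALSE)
  }
  first <- mean(stream$lightLevel[seq_len(k)])
  idx <- order(abs(stream$time_s - window_s))[seq_len(k)]
  last <- mean(stream$lightLevel[idx])
  abs(first - last)
}

#' Drop the initial mixing artifact from a stream
#'
#' Removes all records before `t_cut_s`; the remainder is unchanged. Kinetic
#' evaluation uses the data from 2:30 after the start of the observation.
#'
#' @param stream a [frequency_stream()].
#' @param t_cut_s cut time (s, default 150).
#' @return the trimmed `frequency_stream`.
#' @export
trim_initial_artifact <- function(stream, t_cut_s = 150) {
  stopifnot(inherits(stream, "frequency_stream"))
  keep <- stream$time_s >= t_cut_s
  if (!any(keep)) {
    stop("no records remain after trimming at ", t_cut_s, " s", call. = FALSE)
  }
  out <- stream[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("frequency_stream", "data.frame")
  out
}

#' Convert streamed frequencies to absorbance
#'
#' Beer-Lambert inversion of the light-to-frequency reading:
#' `A = log10((blank - dark) / (lightLevel - dark))`.
#'
#' @param stream a [frequency_stream()].
#' @param blank_hz blank (zero-absorbance) output frequency; defaults to the
#'   stream's `blank_rate_hz` attribute when present.
#' @param dark_hz dark output frequency subtracted from both terms.
#' @return numeric vector of absorbances (OD), one per record.
#' @export
stream_to_absorbance <- function(stream, blank_hz = NULL, dark_hz = 0) {
  stopifnot(inherits(stream, "frequency_stream"))
  if (is.null(blank_hz)) blank_hz <- attr(stream, "blank_rate_hz")
  if (is.null(blank_hz)) {
    stop("blank_hz not supplied and the stream carries no blank_rate_hz",
         call. = FALSE)
  }
  net <- stream$lightLevel - dark_hz
  if (any(net <= 0)) stop("lightLevel at or below the dark rate", call. = FALSE)
  log10((blank_hz - dark_hz) / net)
}

#' Linear (kinetic) evaluation of a frequency stream
#'
#' Ordinary least squares of `lightLevel` — or of the blank-referenced
#' absorbance when `to_absorbance = TRUE` — against time. The slope of the
#' linear segment tracks the enzymatic rate.
#'
#' @param stream a [frequency_stream()] with at least 3 records.
#' @param to_absorbance fit `log10(blank/lightLevel)` instead of raw Hz.
#' @param blank_hz,dark_hz passed to [stream_to_absorbance()].
#' @return an object of class `linear_fit`: a list with `slope` (per s),
#'   `intercept`, `r2`, `residual_sd` and `n`.
#' @export
kinetic_slope <- function(stream, to_absorbance = FALSE, blank_hz = NULL,
                          dark_hz = 0) {
  stopifnot(inherits(stream, "frequency_stream"))
  if (nrow(stream) < 3L) {
    stop("need at least 3 records for a kinetic fit", call. = FALSE)
  }
  if (stats::var(stream$time_s) == 0) {
    stop("degenerate stream: zero time variance", call. = FALSE)
  }
  y <- if (to_absorbance) {
    stream_to_absorbance(stream, blank_hz, dark_hz)
  } else {
    stream$lightLevel
  }
  linear_fit(stream$time_s, y)
}

#' Ordinary least-squares line
#'
#' @param x,y numeric vectors of equal length (n >= 3).
#' @return an object of class `linear_fit`.
#' @export
linear_fit <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  fit <- stats::lm(y ~ x)
  sy <- suppressWarnings(summary(fit))  # perfect fits warn harmlessly
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r2 = if (stats::var(y) == 0) 1 else sy$r.squared,
                 residual_sd = sy$sigma,
                 n = length(x)),
            class = "linear_fit")
}

#' @export
print.linear_fit <- function(x, ...) {
  cat(sprintf("Linear fit: slope %.6g, intercept %.6g, r2 %.4f (n = %d)\n",
              x$slope, x$intercept, x$r2, x$n))
  invisible(x)
}

#' Fit the Michaelis-Menten saturation model
#'
#' Least-squares fit of `y = Vmax * S / (KM + S)`, initialized at
#' `Vmax0 = max(y)` and `KM0 =` the substrate level whose response is nearest
#' `Vmax0 / 2`. Responses are rescaled internally for conditioning; `KM` is
#' unaffected. A Gauss-Newton (`port`) fit is tried first, falling back to a
#' direct Nelder-Mead minimization of the sum of squares on log-parameters;
#' if both fail the error reports the initialization used.
#'
#' @param s substrate concentrations (>= 4 distinct values).
#' @param y responses (rates, endpoint differences, slope magnitudes...).
#' @return an object of class `mm_fit`: a list with `vmax`, `km` (input
#'   units), `r2`, `fitted`, `data` and `poorly_identified` (`TRUE` when the
#'   fitted `KM` is at or beyond the largest substrate level, i.e. the curve
#'   never bends inside the design).
#' @export
fit_michaelis_menten <- function(s, y) {
  stopifnot(length(s) == length(y))
  if (length(unique(s)) < 4L) {
    stop("need at least 4 distinct substrate levels", call. = FALSE)
  }
  if (stats::var(y) == 0) {
    stop("degenerate responses: all values equal", call. = FALSE)
  }
  yscale <- max(abs(y))
  ys <- y / yscale
  vmax0 <- max(ys)
  km0 <- s[which.min(abs(ys - vmax0 / 2))]
  if (km0 <= 0) km0 <- stats::median(s)
  dat <- data.frame(s = s, ys = ys)
  fit <- tryCatch(
    stats::nls(ys ~ vmax * s / (km + s), data = dat,
               start = list(vmax = vmax0, km = km0),
               algorithm = "port",
               lower = c(vmax = 1e-12, km = 1e-12),
               control = stats::nls.control(maxiter = 200, warnOnly = FALSE)),
    error = function(e) NULL)
  if (!is.null(fit)) {
    est <- stats::coef(fit)
  } else {
    ss <- function(p) sum((ys - exp(p[1]) * s / (exp(p[2]) + s))^2)
    opt <- tryCatch(
      stats::optim(c(log(vmax0), log(km0)), ss,
                   control = list(maxit = 5000, reltol = 1e-14)),
      error = function(e) NULL)
    if (is.null(opt)) {
      stop(sprintf(
        "Michaelis-Menten fit did not converge (init Vmax0 = %.4g, KM0 = %.4g)",
        vmax0 * yscale, km0), call. = FALSE)
    }
    est <- c(vmax = exp(opt$par[1]), km = exp(opt$par[2]))
  }
  fitted <- unname(est["vmax"] * s / (est["km"] + s)) * yscale
  r2 <- 1 - sum((y - fitted)^2) / sum((y - mean(y))^2)
  structure(list(vmax = unname(est["vmax"]) * yscale,
                 km = unname(est["km"]),
                 r2 = r2,
                 fitted = fitted,
                 data = data.frame(s = s, y = y),
                 poorly_identified = unname(est["km"]) >= max(s)),
            class = "mm_fit")
}

#' @export
print.mm_fit <- function(x, ...) {
  cat(sprintf("Michaelis-Menten fit: Vmax %.6g, KM %.6g, r2 %.4f\n",
              x$vmax, x$km, x$r2))
  if (x$poorly_identified) {
    cat("  note: KM at or beyond the largest substrate level - poorly identified\n")
  }
  invisible(x)
}

#' @export
summary.mm_fit <- function(object, ...) {
  print(object)
  cat("\n")
  print(cbind(object$data, fitted = object$fitted), row.names = FALSE)
  invisible(object)
}

#' @export
coef.mm_fit <- function(object, ...) c(vmax = object$vmax, km = object$km)

#' @export
predict.mm_fit <- function(object, newdata = NULL, ...) {
  s <- if (is.null(newdata)) object$data$s else newdata
  object$vmax * s / (object$km + s)
}

#' Residual enzyme activity as a percentage of control
#'
#' @param signal_inhibited,signal_control matched assay responses (slope
#'   magnitudes or endpoint differences); the control must be positive.
#' @return percentage in \[0, 100\] with attribute `out_of_range` set when
#'   the raw ratio fell outside that interval before clipping.
#' @export
residual_activity <- function(signal_inhibited, signal_control) {
  if (signal_control <= 0) stop("control signal must be positive", call. = FALSE)
  pct <- 100 * signal_inhibited / signal_control
  structure(min(100, max(0, pct)), out_of_range = pct < 0 || pct > 100)
}

#' Inhibitor calibration with limit of detection
#'
#' Linear regression of the assay response against inhibitor concentration
#' (or its logarithm), with the detection limit computed as
#' `LOD = 3.3 * residual_sd / |slope|`.
#'
#' @param concs calibrator concentrations (>= 5).
#' @param responses matched responses: control-minus-sample endpoint
#'   differences or inverted slope magnitudes.
#' @param log_conc regress against `log10(conc)` instead (drops any zero
#'   calibrator).
#' @param slope_tol minimum usable |slope|; below it the response is deemed
#'   undetectable.
#' @return an object of class `calibration`: a list with `fit` (a
#'   [linear_fit()]), `lod` (concentration units of `concs`) and
#'   `calibrators`.
#' @export
inhibitor_calibration <- function(concs, responses, log_conc = FALSE,
                                  slope_tol = 1e-12) {
  stopifnot(length(concs) == length(responses))
  if (length(concs) < 5L) stop("need at least 5 calibrators", call. = FALSE)
  x <- concs
  y <- responses
  if (log_conc) {
    keep <- concs > 0
    x <- log10(concs[keep])
    y <- responses[keep]
  }
  fit <- linear_fit(x, y)
  if (abs(fit$slope) < slope_tol) {
    stop("calibration slope below tolerance: response undetectable",
         call. = FALSE)
  }
  # in log mode the LOD is expressed in the regression's x units (decades)
  lod <- 3.3 * fit$residual_sd / abs(fit$slope)
  structure(list(fit = fit, lod = lod, calibrators = concs,
                 log_conc = log_conc),
            class = "calibration")
}

#' @export
print.calibration <- function(x, ...) {
  cat(sprintf(
    "Inhibitor calibration: slope %.6g, r2 %.4f, LOD %.4g (%d calibrators)\n",
    x$fit$slope, x$fit$r2, x$lod, length(x$calibrators)))
  invisible(x)
}

#' Optimal preincubation time from a residual-activity profile
#'
#' Finds the shortest contact time at which inhibition has effectively
#' reached its plateau: the smallest multiple of `grid_s` whose residual
#' activity lies within `plateau_tol` (absolute) of the profile's final
#' value. Off-grid profile times are evaluated by linear interpolation and
#' candidate times snap upward onto the grid.
#'
#' @param profile a [preincubation_profile()] (or data frame with columns
#'   `time_s`, `residual_activity`) covering at least two grid points.
#' @param plateau_tol absolute activity tolerance (default 0.02).
#' @param grid_s time grid of the protocol (default 30 s).
#' @return optimal preincubation time in s.
#' @export
optimize_preincubation <- function(profile, plateau_tol = 0.02, grid_s = 30) {
  stopifnot(all(c("time_s", "residual_activity") %in% names(profile)))
  tmax <- max(profile$time_s)
  if (tmax < grid_s) stop("profile must cover at least two grid points",
                          call. = FALSE)
  plateau <- profile$residual_activity[which.max(profile$time_s)]
  a_of_t <- stats::approxfun(profile$time_s, profile$residual_activity,
                             rule = 2)
  candidates <- seq(0, grid_s * floor(tmax / grid_s), by = grid_s)
  ok <- abs(a_of_t(candidates) - plateau) <= plateau_tol
  if (!any(ok)) {
    stop(sprintf(
      "plateau never reached within tolerance %g (closest approach %.4g at %g s)",
      plateau_tol, min(abs(a_of_t(candidates) - plateau)),
      candidates[which.min(abs(a_of_t(candidates) - plateau))]),
      call. = FALSE)
  }
  candidates[which(ok)[1L]]
}

#' Endpoint saturation curve from the chemistry model
#'
#' Generates the twin's endpoint responses (product formed over the
#' evaluation window) across a substrate series — the synthetic input for
#' Michaelis constant recovery.
#'
#' @param s0_levels substrate concentrations after mixing (mol/L).
#' @param params an [ellman_params()] template; its `s0` is replaced per
#'   level.
#' @param activity residual enzyme activity fraction.
#' @param window_s evaluation window (s).
#' @param dt_s integration step (s).
#' @return data frame with columns `s0` and `response` (TNB formed, mol/L).
#' @export
saturation_curve_endpoint <- function(s0_levels, params = ellman_params(),
                                      activity = 1, window_s = 300,
                                      dt_s = 0.1) {
  resp <- vapply(s0_levels, function(s0) {
    p <- ellman_params(vmax_mol_L_s = params$vmax, km_mol_L = params$km,
                       epsilon_412 = params$epsilon, path_cm = params$path,
                       s0_mol_L = s0, dtnb0_mol_L = params$dtnb0)
    tr <- ellman_progress(p, activity, duration = window_s, dt = dt_s)
    tr$tnb_mol_L[nrow(tr)]
  }, numeric(1))
  data.frame(s0 = s0_levels, response = resp)
}
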