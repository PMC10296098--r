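#' Sensor configuration for the light-to-frequency detector
#'
#' Models a TSL230-class light-to-frequency converter as used by the open
#' photometer: the output is a pulse train whose rate is proportional to the
#' light power on the photodiode, plus a dark rate, and a reading integrates a
#' fixed number of pulses.
#'
#' The default calibration constant is anchored so that a blank Ellman cuvette
#' illuminated with the 412 nm colour mix at full intensity reads
#' 3.0e5 Hz — the observed order of hundreds of thousands of Hz over the
#' working absorbance range — at the default high sensitivity.
#'
#' @param sensitivity sensitivity multiplier set by the chip's S0/S1 pins;
#'   one of 1, 10, 100. Default 100 (high sensitivity).
#' @param samples pulses integrated per reading (recommended 1000-20000).
#' @param dark_rate_hz dark output frequency in Hz (default 16).
#' @param cal_constant Hz per unit transmitted power per unit sensitivity;
#'   `NULL` (default) uses the 412 nm blank anchor described above.
#' @param mode `"deterministic"` (reading reports the exact rate) or
#'   `"stochastic"` (Poisson pulse arrivals).
#' @return an object of class `sensor_config`.
#' @export
sensor_config <- function(sensitivity = 100, samples = 1000,
                          dark_rate_hz = 16, cal_constant = NULL,
                          mode = c("deterministic", "stochastic")) {
  mode <- match.arg(mode)
  if (!sensitivity %in% c(1, 10, 100)) {
    stop("sensitivity must be one of 1, 10, 100 (S0/S1 setting)", call. = FALSE)
  }
  stopifnot(samples >= 1, dark_rate_hz >= 0)
  if (is.null(cal_constant)) cal_constant <- default_cal_constant()
  stopifnot(cal_constant > 0)
  structure(list(sensitivity = sensitivity, samples = as.integer(samples),
                 dark_rate_hz = dark_rate_hz, cal_constant = cal_constant,
                 mode = mode),
            class = "sensor_config")
}

#' @export
print.sensor_config <- function(x, ...) {
  cat(sprintf(
    "Sensor config: sensitivity %g, %d samples/reading, dark %g Hz, %s mode\n",
    x$sensitivity, x$samples, x$dark_rate_hz, x$mode))
  invisible(x)
}

# cache for the anchored calibration constant (depends only on package defaults)
.photwin_cache <- new.env(parent = emptyenv())

#' Default sensor calibration constant
#'
#' Computed so that `dark + cal * 100 * P0 = 3.0e5 Hz` holds approximately for
#' the blank cuvette at the 412 nm colour mix, where `P0` is the transmitted
#' power of the default emission model with zero absorbance (the dark term is
#' negligible at this scale and the light-dependent part is anchored exactly).
#'
#' @return Hz per unit power per unit sensitivity.
#' @export
default_cal_constant <- function() {
  if (is.null(.photwin_cache$cal_constant)) {
    p0 <- transmitted_power(led_emission(wavelength_to_pwm(412)), 0)
    .photwin_cache$cal_constant <- 3e5 / (100 * p0)
  }
  .photwin_cache$cal_constant
}

#' Pulse rate for a given transmitted power
#'
#' `rate = dark_rate + cal_constant * sensitivity * power`; strictly
#' increasing in power.
#'
#' @param power transmitted power (arbitrary units, >= 0); vectorized.
#' @param config a [sensor_config()].
#' @return pulse rate(s) in Hz.
#' @export
photon_rate <- function(power, config = sensor_config()) {
  stopifnot(inherits(config, "sensor_config"))
  if (any(power < 0)) stop("power must be nonnegative", call. = FALSE)
  config$dark_rate_hz + config$cal_constant * config$sensitivity * power
}

#' Integrate one sensor reading
#'
#' A reading accumulates `samples` pulses. In deterministic mode the
#' integration time is `samples / rate` and the reported frequency is the rate
#' itself. In stochastic mode pulse arrivals form a Poisson process: the
#' elapsed time is gamma-distributed with shape `samples` and rate `rate`, and
#' the reported frequency is `samples / elapsed`; as `samples` grows the
#' reported frequency converges to the true rate.
#'
#' @param rate pulse rate in Hz (> 0).
#' @param config a [sensor_config()].
#' @param timeout_s give up if the (expected) integration time exceeds this.
#' @return a list with `elapsed_s` and `frequency_hz`.
#' @export
integrate_reading <- function(rate, config = sensor_config(),
                              timeout_s = 86400) {
  stopifnot(inherits(config, "sensor_config"))
  if (rate <= 0 || config$samples / rate > timeout_s) {
    stop("integration timed out: rate ", rate, " Hz cannot accumulate ",
         config$samples, " pulses within ", timeout_s, " s", call. = FALSE)
  }
  if (config$mode == "stochastic") {
    elapsed <- stats::rgamma(1L, shape = config$samples, rate = rate)
    list(elapsed_s = elapsed, frequency_hz = config$samples / elapsed)
  } else {
    list(elapsed_s = config$samples / rate, frequency_hz = rate)
  }
}

#' Generate a stream of back-to-back readings
#'
#' Readings are taken consecutively, each consuming its own integration time;
#' the light rate function is evaluated at the reading's start time and the
#' record is stamped with the completion time.
#'
#' @param rate_fn `function(t_seconds)` returning the pulse rate in Hz, or a
#'   single number for a constant rate.
#' @param duration stream duration in s; readings that would complete after
#'   `duration` are not emitted.
#' @param config a [sensor_config()].
#' @param seed optional integer seed for stochastic mode.
#' @param wavelength_nm value written to the `wavelengthLine` column.
#' @param intensity value written to the `lightIntensity` column.
#' @return a [frequency_stream()].
#' @export
read_sequence <- function(rate_fn, duration, config = sensor_config(),
                          seed = NULL, wavelength_nm = 412, intensity = 255) {
  stopifnot(duration > 0)
  if (!is.function(rate_fn)) {
    r0 <- rate_fn
    rate_fn <- function(t) r0
  }
  if (!is.null(seed)) set.seed(seed)
  stochastic <- config$mode == "stochastic"
  n_cap <- 1024L
  times <- numeric(n_cap)
  freqs <- numeric(n_cap)
  n <- 0L
  t <- 0
  repeat {
    rate <- rate_fn(t)
    if (rate <= 0) {
      stop("integration timed out: nonpositive rate at t = ", t, " s",
           call. = FALSE)
    }
    elapsed <- if (stochastic) {
      stats::rgamma(1L, shape = config$samples, rate = rate)
    } else {
      config$samples / rate
    }
    t_done <- t + elapsed
    # tolerate float accumulation when a reading lands exactly on the end
    if (t_done > duration * (1 + 1e-12) + 1e-12) break
    n <- n + 1L
    if (n > n_cap) {
      n_cap <- n_cap * 2L
      length(times) <- n_cap
      length(freqs) <- n_cap
    }
    times[n] <- t_done
    freqs[n] <- if (stochastic) config$samples / elapsed else rate
    t <- t_done
  }
  frequency_stream(data.frame(time_s = times[seq_len(n)],
                              lightLevel = freqs[seq_len(n)],
                              wavelengthLine = wavelength_nm,
                              lightIntensity = intensity))
}

#' Construct (and validate) a frequency stream
#'
#' The instrument's only output surface: timestamped records of the streamed
#' columns `lightLevel` (output frequency, Hz), `wavelengthLine` (colour
#' setting, nm) and `lightIntensity` (brightness setting).
#'
#' @param records a data frame with columns `time_s`, `lightLevel`,
#'   `wavelengthLine`, `lightIntensity`.
#' @return the data frame with class `frequency_stream` prepended.
#' @export
frequency_stream <- function(records) {
  required <- c("time_s", "lightLevel", "wavelengthLine", "lightIntensity")
  missing <- setdiff(required, names(records))
  if (length(missing)) {
    stop("stream is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  records <- as.data.frame(records)[required]
  if (nrow(records)) {
    if (any(diff(records$time_s) <= 0)) {
      stop("stream timestamps must be strictly increasing", call. = FALSE)
    }
    if (any(records$lightLevel < 0)) {
      stop("lightLevel must be nonnegative", call. = FALSE)
    }
    if (any(records$wavelengthLine < 400 | records$wavelengthLine > 700)) {
      stop("wavelengthLine must lie in [400, 700] nm", call. = FALSE)
    }
  }
  class(records) <- c("frequency_stream", "data.frame")
  records
}

#' @export
print.frequency_stream <- function(x, ...) {
  cat(sprintf("Frequency stream: %d readings over %.1f s", nrow(x),
              if (nrow(x)) max(x$time_s) else 0))
  if (nrow(x)) {
    cat(sprintf(", lightLevel %.4g-%.4g Hz @ %g nm",
                min(x$lightLevel), max(x$lightLevel), x$wavelengthLine[1L]))
  }
  cat("\n")
  invisible(x)
}
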