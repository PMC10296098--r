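#' Describe one simulated Ellman run
#'
#' Bundles the cuvette recipe, reaction and inhibition parameters, the
#' instrument configuration and the timing of one assay: an optional
#' preincubation of enzyme with inhibitor (no stream is emitted during it),
#' then an observation window starting at substrate addition.
#'
#' @param recipe a [cuvette_recipe()].
#' @param ellman an [ellman_params()].
#' @param inhibition an [inhibition_params()], or `NULL` for uninhibited runs.
#' @param inhibitor_mol_L inhibitor concentration in the cuvette (mol/L).
#' @param preincubation_s inhibitor-enzyme contact time before substrate
#'   addition (s, >= 0).
#' @param observation_s observation window (s, default 300 = the 5-min
#'   evaluation window).
#' @param wavelength_nm colour setting (default 412, the assay wavelength).
#' @param sensor a [sensor_config()].
#' @param seed integer seed used for stochastic-mode streams.
#' @param dt_s chemistry integration step (s).
#' @return an object of class `ellman_scenario`.
#' @export
ellman_scenario <- function(recipe = default_ellman_recipe(),
                            ellman = ellman_params(),
                            inhibition = inhibition_params(),
                            inhibitor_mol_L = 0,
                            preincubation_s = 0,
                            observation_s = 300,
                            wavelength_nm = 412,
                            sensor = sensor_config(),
                            seed = NULL,
                            dt_s = 0.1) {
  stopifnot(observation_s > 0, preincubation_s >= 0,
            wavelength_nm >= 400, wavelength_nm <= 700,
            inhibitor_mol_L >= 0)
  structure(list(recipe = recipe, ellman = ellman, inhibition = inhibition,
                 inhibitor_mol_L = inhibitor_mol_L,
                 preincubation_s = preincubation_s,
                 observation_s = observation_s,
                 wavelength_nm = wavelength_nm,
                 sensor = sensor, seed = seed, dt_s = dt_s),
            class = "ellman_scenario")
}

#' @export
print.ellman_scenario <- function(x, ...) {
  cat(sprintf(
    "Ellman scenario: %g nm, %g s preincubation + %g s observation (%s mode)\n",
    x$wavelength_nm, x$preincubation_s, x$observation_s, x$sensor$mode))
  if (x$inhibitor_mol_L > 0) {
    cat(sprintf("  inhibitor: %.3g nmol/L in cuvette\n",
                x$inhibitor_mol_L * 1e9))
  }
  cat(sprintf("  hash: %s\n", scenario_hash(x)))
  invisible(x)
}

#' Stable hash of a scenario
#'
#' Used to tag simulated streams and log runs reproducibly.
#'
#' @param scenario an [ellman_scenario()].
#' @return an md5 string.
#' @export
scenario_hash <- function(scenario) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(scenario, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}

#' Blank pulse rate of a scenario
#'
#' The deterministic rate read through a colourless cuvette (zero
#' absorbance) at the scenario's colour setting.
#'
#' @param scenario an [ellman_scenario()].
#' @return Hz.
#' @export
blank_rate <- function(scenario) {
  p0 <- transmitted_power(led_emission(
    wavelength_to_pwm(scenario$wavelength_nm)), 0)
  photon_rate(p0, scenario$sensor)
}

#' Run a virtual Ellman assay
#'
#' The full pipeline: mix the cuvette, apply the preincubation inhibition to
#' the enzyme activity, integrate the reaction progress, convert the growing
#' 412 nm absorbance to transmitted light (monochromatic at the scenario
#' wavelength by default, or through the full TNB absorption band in spectral
#' mode), convert to a pulse rate and read back-to-back sensor readings.
#' Enzyme activity during the observation window is frozen at its
#' post-preincubation value.
#'
#' @param scenario an [ellman_scenario()].
#' @param spectral if `TRUE`, transmit the whole emission spectrum through a
#'   Gaussian TNB absorption band (centre 412 nm, FWHM 70 nm) instead of the
#'   monochromatic Beer-Lambert shortcut.
#' @return a [frequency_stream()] with attributes `blank_rate_hz`,
#'   `activity`, `trace` (the underlying [ellman_progress()] trace),
#'   `scenario_hash` and `seed`.
#' @export
run_assay <- function(scenario, spectral = FALSE) {
  stopifnot(inherits(scenario, "ellman_scenario"))
  mix <- make_mix(scenario$recipe)   # validates the recipe arithmetic
  activity <- if (is.null(scenario$inhibition) ||
                  scenario$inhibitor_mol_L == 0) {
    1
  } else {
    carbamylation_residual(scenario$preincubation_s, scenario$inhibitor_mol_L,
                           scenario$inhibition)
  }
  trace <- ellman_progress(scenario$ellman, activity,
                           duration = scenario$observation_s,
                           dt = scenario$dt_s)
  a_of_t <- stats::approxfun(trace$time_s, trace$absorbance, rule = 2)
  spec <- led_emission(wavelength_to_pwm(scenario$wavelength_nm))
  if (spectral) {
    band <- tnb_band_profile(spec$wavelength)
    rate_fn <- function(t) {
      photon_rate(transmitted_power(spec, a_of_t(t) * band), scenario$sensor)
    }
  } else {
    p0 <- transmitted_power(spec, 0)
    rate_fn <- function(t) {
      photon_rate(p0 * 10^(-a_of_t(t)), scenario$sensor)
    }
  }
  stream <- read_sequence(rate_fn, scenario$observation_s, scenario$sensor,
                          seed = scenario$seed,
                          wavelength_nm = scenario$wavelength_nm)
  attr(stream, "blank_rate_hz") <- blank_rate(scenario)
  attr(stream, "activity") <- activity
  attr(stream, "trace") <- trace
  attr(stream, "scenario_hash") <- scenario_hash(scenario)
  attr(stream, "seed") <- scenario$seed
  stream
}

# Spectral absorption profile of TNB relative to its 412 nm maximum:
# Gaussian band centred at 412 nm with 70 nm FWHM.
tnb_band_profile <- function(wavelength, center = 412, fwhm_nm = 70) {
  sigma <- fwhm_nm / (2 * sqrt(2 * log(2)))
  exp(-(wavelength - center)^2 / (2 * sigma^2))
}

#' Total wall-clock time of the assay protocol
#'
#' Preincubation plus observation; sample handling is not included.
#'
#' @param scenario an [ellman_scenario()].
#' @return total protocol time in s.
#' @export
protocol_time <- function(scenario) {
  scenario$preincubation_s + scenario$observation_s
}

#' Residual-activity profile over preincubation times
#'
#' Generates the twin's residual activity versus inhibitor contact time, the
#' input to [optimize_preincubation()].
#'
#' @param inhibitor_mol_L inhibitor concentration (mol/L).
#' @param params an [inhibition_params()].
#' @param times_s contact times (s); default 0-480 s in 30 s steps, the
#'   protocol's optimization grid.
#' @return an object of class `preincubation_profile`: a data frame with
#'   columns `time_s` and `residual_activity`.
#' @export
preincubation_profile <- function(inhibitor_mol_L,
                                  params = inhibition_params(),
                                  times_s = seq(0, 480, by = 30)) {
  a <- carbamylation_residual(times_s, inhibitor_mol_L, params)
  structure(data.frame(time_s = times_s, residual_activity = a),
            class = c("preincubation_profile", "data.frame"))
}

#' Instrument state for the command interface
#'
#' @param wavelength_nm current colour setting, clamped to \[400, 700\].
#' @param shift_nm step applied by the `+`/`-` commands.
#' @param intensity brightness setting.
#' @return an object of class `instrument_state`.
#' @export
instrument_state <- function(wavelength_nm = 412, shift_nm = 5,
                             intensity = 255) {
  structure(list(wavelength_nm = min(700, max(400, wavelength_nm)),
                 shift_nm = shift_nm, intensity = intensity),
            class = "instrument_state")
}

#' @export
print.instrument_state <- function(x, ...) {
  cat(sprintf("Instrument state: %g nm (shift %g nm), intensity %g\n",
              x$wavelength_nm, x$shift_nm, x$intensity))
  invisible(x)
}

#' Apply a firmware command to the instrument state
#'
#' Single-letter serial commands: `+` and `-` shift the colour by the state's
#' `shift_nm` (clamped to \[400, 700\]); `E` sets the colour straight to the
#' 412 nm Ellman assay wavelength.
#'
#' @param state an [instrument_state()].
#' @param command one of `"+"`, `"-"`, `"E"`.
#' @return the updated `instrument_state`.
#' @export
apply_command <- function(state, command) {
  stopifnot(inherits(state, "instrument_state"))
  if (!is.character(command) || length(command) != 1L ||
      !command %in% c("+", "-", "E")) {
    stop("unknown command ", deparse(command),
         "; valid commands are '+', '-', 'E'", call. = FALSE)
  }
  wl <- switch(command,
               "+" = state$wavelength_nm + state$shift_nm,
               "-" = state$wavelength_nm - state$shift_nm,
               "E" = 412)
  state$wavelength_nm <- min(700, max(400, wl))
  state
}

#' Superimpose an initial mixing artifact on a stream
#'
#' Real runs can show a transient rise in the output frequency just after
#' substrate addition (droplets on the cuvette wall). This helper adds a
#' smooth rise-and-settle bump to the first `duration_s` seconds of a stream,
#' leaving all later records untouched — used to generate fixtures for
#' [trim_initial_artifact()].
#'
#' @param stream a [frequency_stream()].
#' @param magnitude peak height of the bump in Hz; default 3% of the first
#'   reading.
#' @param duration_s length of the perturbed span (s); must be shorter than
#'   the stream.
#' @param seed optional seed for the per-record jitter on the bump
#'   (sd = 5% of `magnitude`); `NULL` gives the deterministic bump.
#' @return the perturbed `frequency_stream`.
#' @export
simulate_artifact <- function(stream, magnitude = NULL, duration_s = 150,
                              seed = NULL) {
  stopifnot(inherits(stream, "frequency_stream"), nrow(stream) > 0)
  span <- max(stream$time_s)
  if (duration_s >= span) {
    stop("artifact duration (", duration_s,
         " s) must be shorter than the stream span (", span, " s)",
         call. = FALSE)
  }
  if (is.null(magnitude)) magnitude <- 0.03 * stream$lightLevel[1L]
  hit <- stream$time_s < duration_s
  bump <- magnitude * sin(pi * stream$time_s[hit] / duration_s)^2
  if (!is.null(seed) && magnitude != 0) {
    set.seed(seed)
    bump <- pmax(0, bump + stats::rnorm(length(bump), 0, 0.05 * magnitude))
  }
  stream$lightLevel[hit] <- stream$lightLevel[hit] + bump
  stream
}
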