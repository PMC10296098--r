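#' Convert a target wavelength to RGB PWM duties
#'
#' Maps a wavelength in the visible range to the three 8-bit PWM duty cycles
#' that make an RGB LED module imitate that colour. The default mapping is the
#' standard piecewise visible-spectrum approximation: linear channel ramps over
#' the bands 380-440-490-510-580-645-780 nm, edge intensity attenuation below
#' 420 nm and above 700 nm, and a gamma of 0.8 applied to the attenuated
#' channel value before scaling to 0-255.
#'
#' Common-anode modules invert the drive logic: the duty actually written to a
#' common-anode pin is the componentwise complement `255 - duty` of the
#' common-cathode value.
#'
#' @param lambda target wavelength in nm; must lie in \[400, 700\].
#' @param common_anode logical; if `TRUE` the returned duties are in
#'   common-anode sense (complemented).
#' @param gamma gamma-correction exponent applied to the channel value.
#' @param mapping optional replacement strategy: a `function(lambda)` returning
#'   a numeric vector `c(red, green, blue)` of channel fractions in \[0, 1\]
#'   *before* edge attenuation and gamma. Defaults to the piecewise bands
#'   above.
#' @return an object of class `pwm_triple`: an integer vector with elements
#'   `red`, `green`, `blue` in \[0, 255\] and an attribute `common_anode`.
#' @examples
#' wavelength_to_pwm(412)
#' wavelength_to_pwm(412, common_anode = TRUE)
#' @export
wavelength_to_pwm <- function(lambda, common_anode = FALSE, gamma = 0.8,
                              mapping = NULL) {
  stopifnot(is.numeric(lambda), length(lambda) == 1L, is.finite(lambda))
  if (lambda < 400 || lambda > 700) {
    stop("wavelength ", lambda, " nm is outside the supported range [400, 700] nm",
         call. = FALSE)
  }
  if (is.null(mapping)) mapping <- visible_band_fractions
  frac <- mapping(lambda)
  stopifnot(length(frac) == 3L, all(frac >= 0), all(frac <= 1))
  att <- edge_attenuation(lambda)
  duty <- ifelse(frac == 0, 0L, as.integer(round(255 * (frac * att)^gamma)))
  if (common_anode) duty <- 255L - duty
  pwm_triple(duty[1L], duty[2L], duty[3L], common_anode = common_anode)
}

#' Construct a PWM duty triple
#'
#' @param red,green,blue integer duties in \[0, 255\].
#' @param common_anode logical polarity flag.
#' @return an integer vector of class `pwm_triple`.
#' @export
pwm_triple <- function(red, green, blue, common_anode = FALSE) {
  duty <- as.integer(c(red, green, blue))
  if (anyNA(duty) || any(duty < 0L) || any(duty > 255L)) {
    stop("PWM duties must be integers in [0, 255]", call. = FALSE)
  }
  names(duty) <- c("red", "green", "blue")
  structure(duty, common_anode = isTRUE(common_anode), class = "pwm_triple")
}

#' Flip the electrical polarity of a PWM triple
#'
#' Common-anode and common-cathode representations are componentwise
#' complements; applying this twice returns the original triple.
#'
#' @param pwm a [pwm_triple()].
#' @return the complemented `pwm_triple` with the polarity flag toggled.
#' @export
pwm_complement <- function(pwm) {
  stopifnot(inherits(pwm, "pwm_triple"))
  pwm_triple(255L - pwm[["red"]], 255L - pwm[["green"]], 255L - pwm[["blue"]],
             common_anode = !attr(pwm, "common_anode"))
}

#' @export
print.pwm_triple <- function(x, ...) {
  pol <- if (attr(x, "common_anode")) "common-anode" else "common-cathode"
  cat(sprintf("PWM triple (%s): R=%d G=%d B=%d\n", pol,
              x[["red"]], x[["green"]], x[["blue"]]))
  invisible(x)
}

# Piecewise channel fractions of the visible-spectrum approximation.
visible_band_fractions <- function(lambda) {
  r <- g <- b <- 0
  if (lambda < 440) {
    r <- -(lambda - 440) / (440 - 380); b <- 1
  } else if (lambda < 490) {
    g <- (lambda - 440) / (490 - 440); b <- 1
  } else if (lambda < 510) {
    g <- 1; b <- -(lambda - 510) / (510 - 490)
  } else if (lambda < 580) {
    r <- (lambda - 510) / (580 - 510); g <- 1
  } else if (lambda < 645) {
    r <- 1; g <- -(lambda - 645) / (645 - 580)
  } else {
    r <- 1
  }
  c(r, g, b)
}

# Intensity falls off linearly towards the edges of the visible range.
edge_attenuation <- function(lambda) {
  if (lambda < 420) {
    0.3 + 0.7 * (lambda - 380) / (420 - 380)
  } else if (lambda > 700) {
    0.3 + 0.7 * (780 - lambda) / (780 - 700)
  } else {
    1
  }
}

#' Default emission peaks of the modelled RGB LED module
#'
#' Peak centres and widths follow the source characterization of the KS0032
#' module: maxima at 458, 520 and 630 nm with full widths at half maximum of
#' 33, 27 and 17 nm. The relative amplitudes (blue 1.00, green 0.55,
#' red 0.80) are a package choice, set so a 435 nm-imitating mix emits more
#' total flux than a 555 nm mix, consistent with the module's observed
#' behaviour.
#'
#' @return a data frame with columns `channel`, `center`, `fwhm`, `amplitude`.
#' @export
default_channel_peaks <- function() {
  data.frame(channel   = c("blue", "green", "red"),
             center    = c(458, 520, 630),
             fwhm      = c(33, 27, 17),
             amplitude = c(1.00, 0.55, 0.80),
             stringsAsFactors = FALSE)
}

#' Default wavelength grid for emission spectra
#'
#' @param from,to,by grid limits and step in nm.
#' @return numeric vector of wavelengths.
#' @export
default_grid <- function(from = 380, to = 780, by = 0.5) seq(from, to, by = by)

#' Construct an emission spectrum
#'
#' @param wavelength strictly increasing wavelength grid (nm).
#' @param intensity nonnegative intensities (arbitrary units), same length.
#' @return an object of class `emission_spectrum`.
#' @export
emission_spectrum <- function(wavelength, intensity) {
  stopifnot(is.numeric(wavelength), is.numeric(intensity),
            length(wavelength) == length(intensity))
  if (any(diff(wavelength) <= 0)) {
    stop("wavelength grid must be strictly increasing", call. = FALSE)
  }
  if (any(intensity < 0)) stop("intensities must be nonnegative", call. = FALSE)
  structure(list(wavelength = wavelength, intensity = intensity),
            class = "emission_spectrum")
}

#' @export
print.emission_spectrum <- function(x, ...) {
  cat(sprintf("Emission spectrum: %d points, %.1f-%.1f nm, peak %.3g a.u.\n",
              length(x$wavelength), min(x$wavelength), max(x$wavelength),
              max(x$intensity)))
  invisible(x)
}

#' Model the LED emission spectrum for a PWM setting
#'
#' Each channel contributes a Gaussian peak scaled by its duty fraction:
#' `I(lambda) = sum_c (duty_c / 255) * A_c * exp(-(lambda - mu_c)^2 / (2 sigma_c^2))`
#' with `sigma_c = fwhm_c / (2 sqrt(2 log 2))`. Duties are interpreted in
#' common-cathode sense; a common-anode triple is complemented first.
#'
#' @param pwm a [pwm_triple()].
#' @param peaks data frame of channel peaks as in [default_channel_peaks()].
#' @param grid wavelength grid (nm), strictly increasing.
#' @return an [emission_spectrum()].
#' @export
led_emission <- function(pwm, peaks = default_channel_peaks(),
                         grid = default_grid()) {
  stopifnot(inherits(pwm, "pwm_triple"))
  stopifnot(all(c("channel", "center", "fwhm", "amplitude") %in% names(peaks)))
  if (any(peaks$fwhm <= 0) || any(peaks$amplitude <= 0)) {
    stop("peak fwhm and amplitude must be positive", call. = FALSE)
  }
  if (attr(pwm, "common_anode")) pwm <- pwm_complement(pwm)
  duty <- c(red = pwm[["red"]], green = pwm[["green"]], blue = pwm[["blue"]])
  intensity <- numeric(length(grid))
  for (i in seq_len(nrow(peaks))) {
    ch <- peaks$channel[i]
    sigma <- peaks$fwhm[i] / (2 * sqrt(2 * log(2)))
    intensity <- intensity + (duty[[ch]] / 255) * peaks$amplitude[i] *
      exp(-(grid - peaks$center[i])^2 / (2 * sigma^2))
  }
  emission_spectrum(grid, intensity)
}

#' Full width at half maximum of a spectrum
#'
#' Finds the global maximum and the two half-maximum crossings around it,
#' linearly interpolated between grid points.
#'
#' @param spectrum an [emission_spectrum()] with a unique positive maximum.
#' @return width in nm.
#' @export
fwhm <- function(spectrum) {
  stopifnot(inherits(spectrum, "emission_spectrum"))
  w <- spectrum$wavelength
  y <- spectrum$intensity
  ymax <- max(y)
  if (ymax <= 0) stop("spectrum has no positive peak", call. = FALSE)
  ipk <- which.max(y)
  half <- ymax / 2
  # left crossing
  il <- ipk
  while (il > 1L && y[il] > half) il <- il - 1L
  if (y[il] > half) stop("spectrum never falls below half maximum on the left",
                         call. = FALSE)
  left <- interp_crossing(w[il], w[il + 1L], y[il], y[il + 1L], half)
  # right crossing
  ir <- ipk
  n <- length(y)
  while (ir < n && y[ir] > half) ir <- ir + 1L
  if (y[ir] > half) stop("spectrum never falls below half maximum on the right",
                         call. = FALSE)
  right <- interp_crossing(w[ir - 1L], w[ir], y[ir - 1L], y[ir], half)
  right - left
}

interp_crossing <- function(x0, x1, y0, y1, target) {
  if (y1 == y0) return(x1)
  x0 + (target - y0) * (x1 - x0) / (y1 - y0)
}

#' Light power transmitted through an absorbing sample
#'
#' Integrates `I(lambda) * 10^(-A(lambda))` over the spectrum's grid by the
#' trapezoidal rule — the spectral generalization of Beer-Lambert detection.
#'
#' @param spectrum an [emission_spectrum()].
#' @param absorbance either a single nonnegative number, a numeric vector on
#'   the spectrum's grid, or a `function(lambda)` returning absorbance (OD).
#' @return transmitted power in the spectrum's (arbitrary) units.
#' @export
transmitted_power <- function(spectrum, absorbance = 0) {
  stopifnot(inherits(spectrum, "emission_spectrum"))
  w <- spectrum$wavelength
  if (is.function(absorbance)) {
    a <- absorbance(w)
  } else if (length(absorbance) == 1L) {
    a <- rep(absorbance, length(w))
  } else {
    a <- absorbance
  }
  if (length(a) != length(w)) {
    stop("absorbance must match the spectral grid (", length(w), " points)",
         call. = FALSE)
  }
  if (any(a < 0)) stop("absorbance must be nonnegative", call. = FALSE)
  pracma::trapz(w, spectrum$intensity * 10^(-a))
}
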