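---
title: "Modelling an open RGB-LED photometer and its Ellman cholinesterase assay"
author: "photwin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling an open RGB-LED photometer and its Ellman cholinesterase assay}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(photwin)
```

## What the twin models

An open-hardware photometer of the kind photwin emulates has three physical
stages. A colour-programmable RGB LED imitates a target wavelength by mixing
its red, green and blue channels through 8-bit PWM duties. The light crosses
a cuvette in which the Ellman reaction develops a yellow colour:
acetylcholinesterase (AChE) hydrolyses acetylthiocholine, the released
thiocholine cleaves DTNB, and the TNB product absorbs near 412 nm. A
light-to-frequency sensor on the far side emits a pulse train whose frequency
is proportional to the light power reaching it, so the streamed frequency
falls as colour forms. Carbamate pesticides such as carbofuran inhibit AChE,
which is the detection principle: less colour per minute means more
inhibitor.

photwin reproduces each stage as a composable model so the entire analysis
workflow — endpoint and kinetic evaluation, Michaelis–Menten fitting,
inhibitor calibration with detection limits, preincubation optimization —
can be exercised, tested and taught without hardware.

## The optics model

`wavelength_to_pwm()` uses the standard piecewise visible-spectrum
approximation: linear channel ramps over the bands
380–440–490–510–580–645–780 nm, a linear intensity fall-off below 420 nm and
above 700 nm, and a gamma of 0.8, scaled to 0–255 and rounded. The mapping is
exposed as a replaceable strategy (`mapping` argument) because PWM tables
differ between firmwares; common-anode modules are handled by the
componentwise complement `255 - duty`.

`led_emission()` represents each channel as a Gaussian peak. Centres and
widths default to the measured characterization of the KS0032 module —
458/33, 520/27 and 630/17 nm (centre/FWHM) — and intensity is linear in the
duties. The relative channel amplitudes are only available graphically, so
the package fixes them at blue 1.00, green 0.55, red 0.80; this makes a
435 nm-imitating mix emit more total flux than a 555 nm mix, matching the
module's observed behaviour, and is configurable where a different module is
being modelled. The default grid is 380–780 nm at 0.5 nm; `fwhm()` measures
widths by half-maximum crossings with linear interpolation, so its
resolution is one grid step.

`transmitted_power()` integrates `I(lambda) * 10^(-A(lambda))` by the
trapezoidal rule. The monochromatic shortcut used by default in the twin
applies the 412 nm absorbance to the whole beam; the `spectral = TRUE` mode
of `run_assay()` instead transmits the full spectrum through a Gaussian TNB
band (centre 412 nm, FWHM 70 nm). The monochromatic path is the reference
because it makes the Beer–Lambert round trip exact and is how a practitioner
reduces the data; the spectral mode exists to study band-averaging bias.

## The sensor model

`photon_rate()` is affine: `rate = dark + cal * sensitivity * power`. The
dark rate defaults to 16 Hz, the documented dark response of the detector.
The calibration constant is anchored so a blank Ellman cuvette at the 412 nm
colour and high sensitivity (the default; multiplier 100) reads 3.0e5 Hz,
placing the working range in the observed hundreds of kilohertz. A
per-wavelength responsivity curve is deliberately not modelled: it is folded
into the calibration constant, which is what single-wavelength calibration
does on the bench.

A reading integrates a fixed pulse count (`samples`, default 1000,
recommended 1000–20000). In deterministic mode the reported frequency is the
rate itself and the integration time is `samples / rate`; in stochastic mode
pulse arrivals are a Poisson process, so the integration time is
gamma-distributed with shape `samples` and the reported frequency is
`samples / elapsed`. This reproduces the instrument's two practical
behaviours: cadence is proportional to light level (dark readings at 16 Hz
take minutes each), and relative counting noise shrinks as `1/sqrt(samples)`.
`read_sequence()` takes readings back-to-back, evaluating the light level at
each reading's start time — the quantity the counter actually integrates
from — and stamping the record at completion.

## The chemistry model

Substrate depletion follows `dS/dt = -a * Vmax * S / (KM + S)` with the
post-preincubation residual activity `a` frozen during the observation
window (the protocol treats residual activity as the measured quantity, and
further inhibition during the 5-min read is negligible at the calibrated
contact times). DTNB cleavage is treated as instantaneous and 1:1, so
`TNB = S0 - S` and `A412 = eps * l * TNB` with `eps = 14150` L/(mol cm), the
standard Ellman literature value, and a 1 cm path. The default cuvette is the
working recipe (0.4 mmol/L DTNB, 1 mmol/L substrate after mixing); since
DTNB is sub-stoichiometric to full turnover, traces carry a
`chromogen_limited` flag when the product would outrun the chromogen —
irrelevant in the calibrated 0.5–1 OD range but flagged for safety.

The integrator is fixed-step 4th-order Runge–Kutta (`deSolve`, `dt = 0.1` s),
verified in the tests against the implicit closed-form progress curve
`KM ln(S0/S) + (S0 - S) = a Vmax t` to 1e-6 relative. The default `Vmax` of
2.6e-7 mol/L/s makes the uninhibited default cuvette cross 0.5 OD between 2
and 5 min and end near 0.99 OD at 5 min, the range the enzyme concentrate is
targeted to.

Carbamylation is pseudo-first-order,
`a(t) = a_inf + (1 - a_inf) exp(-ki [I] t)`: adequate at nanomolar to
sub-micromolar carbamate concentrations, where the Michaelis complex of the
inhibition reaction is far from saturation. The floor `a_inf = 0.11` places
the plateau at 11% residual activity. The rate constant `ki = 1.5e4`
L mol^-1 s^-1 was chosen jointly with the plateau optimizer's definition:
at 0.5 umol/L carbofuran the residual activity at 7 min is 14.8% — inside
the 10–15% band observed at maximal inhibitory effect — and 7 min (420 s) is
the first 30-s grid point whose activity lies within the default plateau
tolerance (0.02 absolute) of the profile's final value at 8 min. A slightly
faster constant would move the detected optimum to 6 min without changing
the 7-min residual band, so the pair (floor, rate) is pinned by both printed
observations at once.

## The analysis pipeline

Two evaluation regimes mirror bench practice. The *endpoint* statistic
(`endpoint_delta()`) subtracts the mean of the ten readings nearest the end
of the 5-min window from the mean of the first ten. The *kinetic* statistic
(`kinetic_slope()`) is the OLS slope of the stream — of the raw frequency,
or of the blank-referenced absorbance `log10((blank - dark)/(f - dark))`
when `to_absorbance = TRUE`. Raw-frequency slopes are compressed at high
optical density by the exponential Beer–Lambert response, so quantitative
comparisons (residual activity, saturation fitting) should use the
absorbance conversion; the raw slope remains available because it is what
the live stream shows. Kinetic evaluation trims the first 150 s
(`trim_initial_artifact()`): real streams often rise briefly after substrate
addition (droplets on the cuvette wall), and `simulate_artifact()` generates
matching fixtures.

`fit_michaelis_menten()` fits `y = Vmax S / (KM + S)` by nonlinear least
squares (Gauss–Newton with a Nelder–Mead fallback), initialized at
`Vmax0 = max(y)` and `KM0` = the level nearest half-maximal response, with
responses rescaled internally for conditioning. Fits whose `KM` lands at or
beyond the largest substrate level are flagged `poorly_identified` rather
than rejected: linear-looking data cannot pin `KM` from below. Residuals are
unweighted.

`inhibitor_calibration()` regresses the response (control-minus-sample
endpoint difference, or inverted slope magnitude — both are exposed) on
concentration and reports `LOD = 3.3 * sd_residual / |slope|`, the ICH-style
regression formulation. Regression on log-concentration is available as an
option; linear is the default. `optimize_preincubation()` defines the
plateau as the profile's last value (not a fitted asymptote — robust to
profiles that never reach a clean exponential tail) and returns the first
grid time within tolerance, snapping upward onto the 30 s protocol grid.

## Problem sizes and synthetic study conditions

The package's own verification runs use the protocol's published sizes: the
seven twofold substrate levels 0.03125–2 mmol/L, nine twofold carbofuran
calibrators giving 2.4–625 nmol/L in the cuvette, 5-min observation windows
with a 150 s kinetic trim, and preincubation profiles over 0–480 s in 30 s
steps.

Recovery of a Michaelis constant from *endpoint* data is only exact in the
initial-rate regime: with realistic turnover, substrate depletion at the low
end of the series biases the apparent `KM` upward. The noise-free recovery
checks therefore run the chemistry at quasi-initial-rate turnover
(`Vmax = 1e-10` mol/L/s, under 0.1% depletion at the lowest level), which
isolates the pipeline's correctness from the protocol's intrinsic
depletion bias; the stochastic recovery check runs at `Vmax = 1e-8` with
Poisson counting noise at 10^4 samples per reading and accepts the ~2–4%
depletion bias inside its 10% band.

What the twin does *not* emulate — and what passing tests therefore do not
establish about real hardware: LED temperature drift and PWM flicker,
absolute radiometry, sensor spectral responsivity, serial-timing jitter,
spontaneous substrate hydrolysis, product inhibition, enzyme denaturation,
and matrix effects in field samples. Detection limits computed on simulated
streams characterize the counting-statistics floor of the design, not the
device-specific noise of any physical build.

## Numerical choices and degenerate inputs

* Integration: RK4 at `dt = 0.1` s; conservation `S + TNB = S0` holds to
  1e-9 relative along every trace.
* Stream cadence: a reading that would complete a float-epsilon beyond the
  requested duration is kept; streams enforce strictly increasing
  timestamps, nonnegative frequencies and wavelengths in 400–700 nm.
* `fwhm()` errors on flat or all-zero spectra (no peak) rather than
  guessing.
* Zero total volume, nonpositive dilution factors, negative powers or
  absorbances, rates of zero (integration timeout) and streams too short
  for their window all raise immediate domain errors.
* Wavelength commands clamp at the 400/700 nm bounds (no wrap-around);
  `E` resets to the 412 nm assay colour.
* File I/O writes `%.17g` so write/read round trips are bit-exact; the
  decimal separator is fixed to the dot.

## Known limitations

The carbamylation constants are anchored to two printed observations (the
10–15% residual band at 7 min and the 7-min plateau optimum), not to an
independently measured rate constant; absolute inhibitor sensitivities of
the twin should be read as order-of-magnitude. The monochromatic detection
path slightly overstates contrast relative to the spectral mode at high OD.
Endpoint `KM` values from realistic-turnover runs are apparent constants,
biased by depletion exactly as their bench counterparts are.
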