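# photwin

A digital twin of an open-hardware photometer — a colour-programmable RGB
LED shining through a cuvette onto a light-to-frequency sensor — together
with the complete Ellman cholinesterase analysis pipeline that runs on top
of it.

The package is for people who build, validate or teach low-cost photometric
biosensing: it lets you exercise the whole assay workflow (substrate
optimization, Michaelis–Menten fitting, carbamate-inhibitor calibration
with detection limits, preincubation-time optimization, instrument stream
parsing) without any hardware, and gives simulation-backed fixtures for
testing analysis code against known ground truth.

## The model in brief

* **Optics** — a requested wavelength λ ∈ [400, 700] nm is mapped to 8-bit
  PWM duties by the standard piecewise visible-spectrum approximation
  (gamma 0.8, edge attenuation), and the LED output is a sum of Gaussian
  channel peaks (centres/FWHM 458/33, 520/27, 630/17 nm).
* **Chemistry** — Michaelis–Menten substrate depletion
  dS/dt = −a·V<sub>max</sub>·S/(K<sub>M</sub> + S), instantaneous 1:1 DTNB
  cleavage, A₄₁₂ = ε·l·(S₀ − S) with ε = 14150 L mol⁻¹ cm⁻¹;
  carbamate inactivation is pseudo-first-order,
  a(t) = a<sub>∞</sub> + (1 − a<sub>∞</sub>)·e^(−k<sub>i</sub>[I]t).
* **Detection** — Beer–Lambert transmittance drives a pulse rate
  f = f<sub>dark</sub> + c·s·P; each reading integrates a fixed pulse count,
  with Poisson counting statistics in stochastic mode.
* **Analysis** — endpoint Δf and artifact-trimmed kinetic slopes, nonlinear
  Michaelis–Menten fitting, residual activity, inhibitor calibration with
  LOD = 3.3·σ<sub>resid</sub>/|slope|, and plateau detection for the
  preincubation optimum.

## Worked example

```r
library(photwin)

## the 412 nm Ellman colour as PWM duties
wavelength_to_pwm(412)
#> PWM triple (common-cathode): R=123 G=0 B=226

## a control run and a 100 nmol/L carbofuran run, Poisson sensor noise
ctrl <- run_assay(ellman_scenario(
  sensor = sensor_config(samples = 10000, mode = "stochastic"), seed = 42))
ctrl
#> Frequency stream: 3554 readings over 299.8 s, lightLevel 3.062e+04-3.055e+05 Hz @ 412 nm

inh <- run_assay(ellman_scenario(
  inhibitor_mol_L = nmol_per_L(100), preincubation_s = 420,
  sensor = sensor_config(samples = 10000, mode = "stochastic"), seed = 42))

endpoint_delta(ctrl)   # Hz lost to colour formation in 5 min
#> [1] 268730
endpoint_delta(inh)    # the inhibited cuvette develops less colour
#> [1] 220218

## kinetic regime: trim the mixing artifact window, fit absorbance vs time
kinetic_slope(trim_initial_artifact(ctrl), to_absorbance = TRUE, dark_hz = 16)
#> Linear fit: slope 0.00327128, intercept 0.00237676, r2 0.9989 (n = 866)

## preincubation optimum for 0.5 umol/L carbofuran on the 30 s grid
optimize_preincubation(preincubation_profile(umol_per_L(0.5)))
#> [1] 420        # seconds, i.e. 7 min

## recover a Michaelis constant from a noise-free endpoint saturation curve
s <- mmol_per_L(2 / 2^(0:6))
sat <- saturation_curve_endpoint(s, ellman_params(vmax_mol_L_s = 1e-10))
fit_michaelis_menten(sat$s0, sat$response)
#> Michaelis-Menten fit: Vmax 3.00002e-08, KM 0.00011601, r2 1.0000
```

The endpoint difference of ~2.7 × 10⁵ Hz corresponds to the ~1 OD developed
by the uninhibited cuvette in 5 min; the absorbance slope of
3.27 × 10⁻³ OD/s over the trimmed window tracks the enzymatic rate; and the
recovered K<sub>M</sub> of 1.16 × 10⁻⁴ mol/L (0.116 mmol/L) is the value the
curve was generated with.

A command-line front end over the same functions lives at
`inst/cli/photwin.R` (subcommands `simulate`, `analyze`, `fit-mm`,
`calibrate`, `preincubation`, `spectrum`).

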