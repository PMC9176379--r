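---
title: "Methods: diffuse optical assessment of tissue and body composition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diffuse optical assessment of tissue and body composition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dosicomp)
```

## The measurement problem

Diffuse optical spectroscopic imaging (DOSI) combines frequency-domain
photon migration — intensity-modulated laser diodes at 690, 785 and
835 nm, with amplitude and phase recorded over a range of modulation
frequencies at a 28 mm source–detector separation — with broadband
(650–1000 nm) continuous-wave (CW) reflectance spectroscopy. From these
two measurements one can recover, at every wavelength, the tissue
absorption coefficient $\mu_a$ and reduced scattering coefficient
$\mu_s'$ (both mm$^{-1}$), and from the broadband absorption the
concentrations of the dominant near-infrared chromophores: oxygenated
and de-oxygenated hemo+myoglobin (HbMbO$_2$, HbMbR, in $\mu$M), water
and fat (percent volume fraction). Derived quantities are the total
heme concentration THbMb = HbMbO$_2$ + HbMbR and the tissue oxygen
saturation StO$_2$ = 100·HbMbO$_2$/THbMb.

Because subcutaneous adipose tissue and the muscle beneath it have very
different compositions — muscle is heme- and water-rich, adipose is
lipid-rich — the measured signal over a layered limb or abdominal site
is a depth-weighted blend of the two. That blending is what makes a
single surface measurement informative about the thickness of the
skin+adipose layer (SATT, measured in cm by ultrasound) and, across
several sites, about whole-body composition as assessed by DXA
(dual-energy x-ray absorptiometry).

## Photon diffusion model

The forward model (`fd_forward`, and its zero-frequency CW limit) is
the standard semi-infinite diffusion Green's function with an
extrapolated boundary: an isotropic source at depth
$z_0 = 1/(\mu_a + \mu_s')$ and a negative image source mirrored about
the extrapolated boundary at $z_b = 2AD$, where $D = 1/3(\mu_a+\mu_s')$
and $A$ is computed from an effective internal reflection coefficient
$R_\mathrm{eff} = 0.493$ for tissue refractive index 1.4. The complex
wavenumber is $k = \sqrt{(\mu_a + i\omega/v)/D}$ with $v$ the speed of
light in tissue. Amplitude is the modulus of the complex reflectance
and phase the (unwrapped) negative argument, so phase is a positive lag
that vanishes as the modulation frequency goes to zero.

Inversion (`fd_invert`) fits this model to multi-frequency amplitude
and phase jointly by Levenberg–Marquardt on log-transformed parameters.
Amplitude enters in self-normalized (relative) mode — data and model
are both divided by their value at the lowest modulation frequency —
because absolute instrument throughput is not modelled; the residual
vector concatenates log-amplitude and phase misfits, each divided by a
noise scale (defaults: 1% amplitude, 0.1° phase) so the two blocks are
commensurate. The synthetic instrument uses modulation frequencies
50–400 MHz in 50 MHz steps, a typical frequency-domain sweep.

Broadband absorption (`broadband_mua`) is recovered per wavelength from
the CW spectrum: $\mu_s'(\lambda)$ is supplied by the scattering power
law fitted to the frequency-domain wavelengths, the unknown CW
throughput is calibrated by least squares against the frequency-domain
absorption values used as anchors, and $\mu_a$ is then solved for by
bisection (the CW model is strictly decreasing in $\mu_a$; 60 bisection
iterations on a log bracket, i.e. machine-precision for practical
purposes). Wavelengths whose reflectance is unattainable by any
positive $\mu_a$ are flagged and filled by linear interpolation.

## Spectral model

Scattering follows the Mie-type power law
$$\mu_s'(\lambda) = A_{500}\,(\lambda/500\,\mathrm{nm})^{-b},$$
with amplitude $A_{500}$ (mm$^{-1}$, the value at 500 nm) and
scattering power $b$. We store $b$ so that positive values mean
scattering decreasing with wavelength, the behaviour of normal tissue;
published tables sometimes print the exponent with the opposite sign,
and `scatter_params(..., sign_convention = "table")` negates on ingest.
`fit_powerlaw` is the standard log–log linear regression: it is exact
on noiseless power-law input, interpolates with two points, and is
exactly scale-equivariant.

Absorption composes linearly over the four chromophore basis spectra.
The bundled extinction library (`nir_extinction_library`) is a
*synthetic compilation*: shape-preserving splines through coarse
control points that reproduce the canonical features of the published
extinction literature — the oxy/deoxy heme isosbestic point near
800 nm, the lipid peak near 930 nm, the water peak near 970 nm — at
magnitudes that place heme-rich muscle near
$\mu_a(800\,\mathrm{nm}) \approx 0.025$ mm$^{-1}$. It is intended for
simulation and round-trip analysis, not as a metrological reference;
every test of the decomposition is relative to the same library.
Decomposition (`decompose_mua`) is non-negative least squares
(Lawson–Hanson active set): non-negativity is physically forced, and an
all-zero spectrum decomposes to an all-zero composition rather than an
error. Units throughout: heme in $\mu$M, water and fat as percent of
the pure-substance absorption. Temperature or pH shifts of the water
and lipid spectra, and minor absorbers (collagen, melanin,
cytochromes), are out of scope.

## Optical fat and lean fractions

The composition metrics are
$$\mathrm{OFF} = \frac{\mathrm{Fat}}{\mathrm{THbMb} + \mathrm{Water} +
\mathrm{Fat}}, \qquad \mathrm{OLF} = \frac{\mathrm{THbMb} +
\mathrm{Water}}{\mathrm{THbMb} + \mathrm{Water} + \mathrm{Fat}},$$
with OFF + OLF = 100%. The ratio deliberately mixes units — THbMb in
$\mu$M against water and fat in percent — which is workable only
because tissue THbMb happens to share the 0–200 numeric range of the
percent scales. `compute_off` therefore guards its inputs: heme must
look like $\mu$M and water/fat like percent, and mis-scaled inputs are
rejected rather than silently ratioed. OFF is reported in percent by
default (a `scale = "fraction"` option exists). On the reference
endmember compositions, lean tissue gives OFF 0.6% / OLF 99.4% and fat
tissue OFF 68.7% / OLF 31.3%.

Ten anatomical sites (biceps short/long head; four peri-navel abdominal
sites; vastus lateralis and rectus femoris; medial and lateral
gastrocnemius) are measured in triplicate and averaged into four
regions (biceps, abdomen, quadriceps, calf). Replicates are averaged
within site, then sites within region, field-wise on the chromophores
and scattering parameters; OFF/OLF are computed from the region-mean
chromophores rather than averaged over per-site metrics (a
`mean_of_metrics` mode exists for sensitivity checks). Whether
replicate averaging should happen at the optical-property or
chromophore level is not determined by the data we emulate; we average
at the chromophore level, which is the level at which the metrics are
defined.

## SATT prediction

SATT relates to quadriceps OFF through a single-term exponential,
$$\mathrm{SATT} = a\,e^{b\cdot\mathrm{OFF}},$$
with OFF on the **fraction** (0–1) scale — the scale is forced by the
magnitudes of the reference coefficients ($a = 0.2856$ cm,
$b = 2.214$; at OFF = 0.687 the prediction is $\approx 1.31$ cm,
whereas a percent-scale $b$ would explode the exponential.
`fit_satt` minimizes residuals in SATT space (not log-SATT; the choice
is a genuine free parameter and SATT-space least squares treats thick
and thin layers with equal absolute weight), by Levenberg–Marquardt
initialized from the log-linear regression. Predictions above 1 cm are
flagged: penetration depth is roughly one third of the 28 mm
source–detector separation, so thicker layers are beyond the method's
sensitivity. Alternative functional forms are deliberately not
explored. Agreement is summarized by Bland–Altman analysis
(`bland_altman`): bias = mean(predicted − measured), limits of
agreement at ±1.96 sample SD.

## Whole-body composition prediction

DXA's three-compartment model gives fat%, LST% and bone% as mass
fractions summing to 100. Whole-body fat% (LST%) is predicted from OFF
(OLF) at the four regions by a Gaussian identity-link linear model —
ordinary least squares with intercept, predictors on the percent
scale — trained on an 80% split (79 of 99 participants at the default
cohort size) drawn by uniform random sampling with a recorded seed and
reused for both targets. Evaluation on the held-out 20% reports the
Bland–Altman summary; any overlap between evaluation and training ids
raises a leakage error. Bone composition is not modelled optically:
near-infrared light at these separations is not expected to be
sensitive to bone mineral.

## Screening statistics

`screen_parameters` computes per-parameter Spearman (or Pearson)
correlations of the seven optical parameters (THbMb, StO$_2$, water,
fat, $A_{500}$, $b$, $\mu_s'(800)$) against SATT, with two-sided
p-values by the t approximation (adequate at the n ≈ 99 scale; a
permutation option exists for small n), average ranks for ties, the
Bonferroni-adjusted threshold $\alpha/n_\mathrm{tests}$, and the
retention rule *significant and $R^2 > 0.5$*. The family size is an
explicit argument because the threshold depends on whether one counts
six or seven comparisons in a family; the default is the number of
parameters actually screened.

## The synthetic cohort

No raw participant data ship with the package, so `generate_cohort`
creates a cohort with the statistical structure the analysis assumes:

* **Two-layer mixing.** Each site's true composition is
  $w\cdot\mathrm{fat\ endmember} + (1-w)\cdot\mathrm{lean\ endmember}$,
  with endmember defaults taken from the observed extremes (lean:
  THbMb 125.2 $\mu$M, StO$_2$ 67.1%, water 73.0%, fat 1.1%, $A_{500}$
  0.87, $b$ 1.28; fat: THbMb 19.4 $\mu$M, StO$_2$ 63.0%, water 11.3%,
  fat 67.3%, $A_{500}$ 0.85, $b$ 0.42). StO$_2$ mixes as the
  THbMb-weighted average (the saturation of the pooled heme), which is
  equivalent to mixing HbMbO$_2$ and HbMbR linearly.
* **Mixing weight.** $w = 1 - \exp(-(\mathrm{SATT}/z_0)^s)$ with
  $z_0 = 0.93$ cm (one third of the 28 mm separation, the penetration
  rule of thumb). The generator default $s = 3$ sharpens the
  transition so a 0.25 cm layer reads nearly pure muscle and a 1.55 cm
  layer nearly pure adipose, matching the observed endmember OFFs of
  ≈0.6% and ≈68.7% and giving the cohort an OFF span of roughly
  0.5–70%; the plain exponential ($s = 1$, the `mixing_weight`
  default) saturates too slowly to reach either extreme. The true
  depth weighting of a layered medium is instrument-dependent; this
  weight is a modelling choice, not a measured quantity.
* **SATT.** Quadriceps SATT is log-normal (meanlog log 0.70 cm, sdlog
  0.42), clamped to the observed 0.2–1.6 cm range; other sites scale
  it by fixed anatomical multipliers (abdomen 1.5, biceps 0.8, calf
  0.7, RF 1.12 vs VL 0.90 — rectus femoris runs thicker than vastus
  lateralis) with 15% site-level log-normal variation.
* **Noise.** Replicate CV 3% on every field; participant-site field CV
  10% on the chromophores; StO$_2$ ±3.5 points; scattering power 70%
  multiplicative CV and $A_{500}$ drawn *independently* of SATT
  (mean 0.86, CV 13%). These scatter-parameter choices are deliberate:
  they reproduce the observed screening regime in which THbMb, water
  and fat correlate strongly with SATT ($R^2 \approx 0.8$–0.95) while
  StO$_2$, $A_{500}$, $b$ and $\mu_s'(800)$ stay below the $R^2 = 0.5$
  retention bar (≈0.07, ≈0.01, ≈0.17 and ≈0.10 at the defaults) —
  a flat 10% CV on the scattering power would instead make $b$ a
  strong SATT correlate, a regime the emulated study did not observe.
* **DXA.** Whole-body fat% is planted as an affine function of the
  four region OFFs (intercept 12; coefficients 0.10, 0.15, 0.10, 0.05
  for biceps, abdomen, quadriceps, calf) plus Gaussian residual noise
  (SD 3 percent points), floored at 0.5% as a physical guard that the
  default coefficients essentially never trigger; bone% is ≈5%, LST%
  is the remainder, and masses are back-computed from dressing
  demographics. The planted model is exactly recoverable by
  `fit_bodycomp` on noiseless data.
* **Coupling option.** `satt_coupling = c(a, b)` overwrites the
  quadriceps SATT record with $a e^{b\,\mathrm{OFF}}$ so the
  exponential SATT model is planted exactly.

`generate_measurements` pushes any true composition through the
spectral and diffusion forward models to produce synthetic instrument
data, with optional multiplicative amplitude noise, additive phase
noise and CW noise.

What the generator does **not** emulate: real anatomical heterogeneity
within a site, layered (rather than mixed) light transport, ultrasound
or DXA measurement error, instrument drift and calibration-phantom
error, demographic structure (age and sex are table dressing with no
planted sub-cohort effects). Passing tests therefore demonstrate that
the analysis pipeline is internally correct and recovers structure it
assumes — not that those assumptions hold in vivo.

## Numerical choices and problem sizes

Nonlinear fits use Levenberg–Marquardt (`minpack.lm`) at tolerance
1e-15, max 200–500 iterations; the frequency-domain inversion
parameterizes $\log\mu_a$, $\log\mu_s'$ so iterates stay positive;
NNLS tolerance is the solver default (machine-scale). Degenerate
inputs are defined rather than accidental: constant SATT fits return
$(a = c, b = 0)$; constant screen columns return an undefined-
correlation flag, never retained; a single held-out participant yields
a Bland–Altman with undefined limits; zero pooled variance with equal
means gives p = 1.

The packaged test suite exercises the stochastic claims at these
sizes, chosen to give comfortable statistical margins: 500 replicates
for exponential-model recovery (n = 79, log-normal noise σ = 0.15);
200 seeds for the retention screen (n = 99) and for the whole-body
Bland–Altman magnitudes; 200 trials for noisy spectral decomposition;
40 trials for the noisy full measurement chain (whose median
per-chromophore error is required under 5%), with the noiseless chain
checked to 2% absolute in OFF. The across-seed aggregation for the
whole-body evaluation uses the mean of |bias| and of the limit-of-
agreement half-width: with 20 held-out participants and residual SD 3%,
a per-seed bias bound of 1% would be violated by sampling alone in a
substantial fraction of seeds, so the mean across seeds is the
meaningful summary of the planted structure.

## Known limitations

* The extinction compilation is synthetic; absolute chromophore values
  from real instrument data would require the instrument's own basis
  spectra.
* The semi-infinite homogeneous forward model is the community
  standard for this geometry but is mis-specified for strongly layered
  tissue; the package models that mis-specification only through the
  endmember-mixing abstraction.
* The CW anchor-calibration scheme is one defensible reading of
  broadband absorption recovery; alternatives (e.g. spectrally
  constrained fitting) are not implemented.
* Predictions beyond ≈1 cm SATT are flagged as beyond the sensitivity
  limit rather than corrected.
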