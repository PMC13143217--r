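---
title: "Models and methods behind grousevision"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind grousevision}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grousevision)
```

`grousevision` chains six analysis stages — pigment fitting, cone
sensitivity modelling, contrast-sensitivity estimation, detection geometry,
visual-field arithmetic and marker contrast analysis — into one reproducible
account of an avian visual system, with the black grouse parameter set as
the default. This vignette explains each model, the assumptions it leans
on, the parameters that matter, and the numerical and design decisions
taken where more than one defensible choice existed.

## The visual-pigment template and λ_max fitting

A vertebrate visual pigment's absorbance curve is well described by the
Govardovskii A1 template, a fixed parametric shape indexed solely by its
peak wavelength λ_max. The α band is

$$S(\lambda) = \frac{1}{e^{A(a-x)} + e^{B(b-x)} + e^{C(c-x)} + D},
\qquad x = \lambda_{max}/\lambda,$$

with A = 69.7, B = 28, C = −14.9, D = 0.674, b = 0.922, c = 1.104 and
$a = 0.8795 + 0.0459\,e^{-(\lambda_{max}-300)^2/11940}$. The β band — the
secondary short-wavelength absorbance of the retinal chromophore — is a
Gaussian with peak $189 + 0.315\,\lambda_{max}$ nm, bandwidth
$-40.5 + 0.195\,\lambda_{max}$ nm and amplitude 0.26 relative to the α
peak. Spectra are evaluated on a 300–800 nm grid at 0.1 nm and
renormalized to a grid maximum of exactly 1; the argmax can sit a few
tenths of a nanometre short of the nominal λ_max (a property of the
template, most visible below ~400 nm), which is why peaks and cutoffs are
reported to 0.1 nm internally and rounded to 1 nm only in reports.

**β-band default.** The β band is ON by default for fitting and
perception-range work: violet-sensitive SWS1 pigments absorb measurably in
the near-UV, and dropping the shoulder would understate short-wavelength
sensitivity. Every function takes `beta_band = FALSE` for the α-only
reading, because published fits do not always state which convention they
used and the difference matters at short wavelengths.

**Fitting.** `fit_lambda_max()` minimizes the sum of squared residuals
between an observed spectrum and the template over a fit window, by a 1 nm
grid search across the avian cone range (330–620 nm) followed by
`stats::optimize()` refinement to 0.01 nm. Two details deserve emphasis:

* *Nuisance parameters.* By default the template's amplitude and a
  constant baseline are profiled out in closed form at every candidate
  λ_max (`nuisance = "scale_offset"`). The naive alternative — dividing
  the data by its maximum and comparing curves directly — anchors the fit
  to a single noisy grid point: at realistic noise (sd 0.02 on a peak-1
  scale) that shifts the fitted peak systematically by several tenths of a
  nanometre, larger than the estimator's own standard deviation, and a
  confidence interval built around such an estimate rarely contains the
  truth. Profiling scale and offset removes the bias at no cost when the
  data are clean; `"scale"` and `"none"` remain available.
* *Fit window.* With `window = NULL`, a pilot fit over the full spectrum
  locates the peak and the final fit uses [pilot − 60, pilot + 100] nm.
  The asymmetry avoids the β band and short-wavelength instrument edge
  while keeping the information-rich long limb.

Degenerate inputs are refused rather than fitted: a spectrum whose maximum
sits at a window edge, or whose peak stands less than 0.1 (normalized
units) above the window endpoints, has no interior λ_max to estimate and
raises an error, as does a candidate search that terminates on its
boundary.

**Bootstrap.** `bootstrap_lambda_max()` treats the aliquot replicate as the
exchangeable unit: each of `n_boot` draws resamples replicates with
replacement, averages them and refits (the fit window is frozen from the
point estimate so all refits answer the same question; refits search
±40 nm around it). With a single replicate the fallback is a residual
bootstrap around the fitted curve. The 95% interval is the *expanded
percentile* interval: the percentile probabilities are widened by
$z' = t_{n-1,0.975}\sqrt{n/(n-1)}$ before reading the bootstrap quantiles.
With a handful of replicates — the realistic regime for purified-pigment
spectroscopy — the plain 2.5/97.5 percentile interval is known to
undercover, because the bootstrap both shrinks the spread estimate by
$(n-1)/n$ and ignores the Student-t inflation; the package's own coverage
test (100 seeded repetitions of 7 replicates at noise sd 0.02) sits inside
the expected band with the expansion and well below it without.
`ci_method = "percentile"` restores the plain interval, and is what the
n = 1 residual bootstrap always uses.

## Oil droplets and effective cone sensitivity

Single-cone oil droplets are carotenoid long-pass filters. Their
transmission is modelled as a logistic cut-on in wavelength,
$T(\lambda) = 1/(1+e^{-k(\lambda-\lambda_{mid})})$, which is 0.5 at
λ_mid by construction, with λ_mid the droplet's 50% transmission
wavelength. Defaults: the transparent T-type of SWS1 cones transmits
fully; the C-type λ_mid is tied to its SWS2 pigment by the empirical
relation $0.82\,\lambda_{max}+75$; Y and R types default to 523 and
586 nm (Galliformes microspectrophotometry values); slopes default to
k = 0.15 per nm (C) and 0.12 per nm (Y/R). The logistic is one reasonable
reading of a cut-on described by a log-unit-per-nanometre steepness; the
functional form sits behind a single constructor (`droplet_transmission()`)
so an alternative ramp can be swapped in without touching anything
downstream.

Effective sensitivity is the pointwise product of pigment absorbance and
droplet transmission. Two normalization scales coexist and the package is
explicit about which is used where:

* the returned `sensitivity` spectrum is renormalized to peak 1 (for
  plotting and comparison);
* the 5% *cutoffs* are referenced to the **pigment** peak, not the
  product's own maximum. A cut-on droplet transmits essentially fully on
  the long-wavelength limb, so the pigment alone sets the upper perception
  limit; referencing 5% to a heavily attenuated product peak would stretch
  both limbs outward and invent sensitivity the cone does not have.

The whole-eye perception range takes its lower bound from the SWS1
pigment's short-limb 5% crossing and its upper bound from the LW
pigment's long-limb crossing. With the β band on, the SWS1 short limb
never falls to 5% within the grid — the β shoulder keeps near-UV
absorbance high — and the lower bound is reported as `NA`: in a real eye
that bound is set by ocular-media (cornea/lens) transmission, which is
outside this model (and unmeasured for the black grouse). The upper bound
is insensitive to this choice.

## Contrast sensitivity from reflex trials

Each spatial-frequency × contrast combination is presented five times; a
response is reliable when the optocollic reflex occurred at least four
times; the threshold contrast at a frequency is the lowest reliable level,
and sensitivity is its inverse. These rules are implemented literally
(`reliable_response()`, `csf_points()`), with frequencies that never reach
a reliable level retained and flagged rather than dropped silently.

The per-individual CSF records the peak sensitivity, its frequency (lowest
frequency on ties) and the high cut-off frequency — the frequency at which
sensitivity falls to 1, i.e. where only a full-contrast grating is just
detectable. The cut-off is found by log–log linear interpolation between
the bracketing points of the descending limb, or extrapolation of its two
highest-frequency points when sensitivity stays above 1 throughout; with
fewer than two descending points there is no cut-off to report. Group
summaries average per-individual peaks arithmetically and average
sensitivities (not thresholds) at frequencies shared by all individuals,
matching how mean CSF curves are conventionally drawn. Report rounding
uses round-half-down to two decimals (0.955 prints as 0.95); exact values
are retained internally.

The synthetic observer in `simulate_ocr_trials()` responds exactly when
its true sensitivity meets 1/contrast, with an optional independent lapse
probability, and its stimulus direction sequence is pseudorandom with at
most three consecutive repeats. The default 12-level contrast ladder spans
the tested range 0.012–0.99 roughly log-spaced and includes 0.06, the
level at which a sensitivity of 16.67 thresholds; the exact per-frequency
ladder of any given experiment can be passed in instead.

## Detection geometry

The chain is deliberately elementary; its value is in being assembled,
anchored and dimensionally checked in one place.

| quantity | relation | default inputs |
|---|---|---|
| axial length | AL = 1.66·CD | CD = 8.00 mm |
| spatial resolution | SR = (9.81/13.28)·AL | — |
| detection distance | D = v·t | v = 16.04 m s⁻¹, t = 2 s |
| marker spacing | d = 2D·tan(θ/2) | θ = 28° |
| object width | w = D·tan(1/(2·SR)°)·ℓ | ℓ = 1 (5 at low light) |

The axial-length and acuity regressions come from the eye-allometry
literature and are carried here as calibrated anchors: both operations
must reproduce the worked diurnal-bird pair (8.00 mm → 13.28 mm →
9.81 cpd), and the acuity relation is taken proportional to axial length —
the optics rationale being that acuity scales with posterior nodal
distance, itself proportional to axial length at fixed receptor spacing.
The marker-spacing relation uses the half-angle form tan(θ/2), the form
consistent with the rest of the geometry: two markers subtending the
binocular overlap θ at distance D sit 2D·tan(θ/2) apart. Flight speed is
an input parameter (the default is the body-mass-predicted cruising speed
for a ~1.07 kg grouse); the mass→speed allometry itself is not
reimplemented here. The factor 2 in the width limit reflects acuity being
expressed in cycles per degree, one cycle spanning two resolvable bars;
the 5× low-light factor encodes the roughly five-fold decline of spatial
resolution between bright daylight and dusk/overcast conditions.

## Visual fields

Perimeter measurements are taken at a finite radius R while the eye sits
e/2 off the median plane, so each boundary azimuth is corrected to an
infinite viewing distance by explicit planar geometry per elevation: the
perimeter point at measured azimuth φ lies at (R sin φ, R cos φ), the eye
at (e/2, 0), and the corrected azimuth is the direction of the ray between
them. The construction is exactly invertible (`perimeter_azimuth()`),
which both the tests and the synthetic generator exploit: the generator
works backwards from an infinity-referred truth so the pipeline's
correction recovers it identically. The correction is the identity as
e → 0 or R → ∞.

Azimuths follow one convention throughout: measured from the bill-forward
direction, positive toward the measured eye's side, so a converged
boundary crossing the median plane is negative and the binocular width at
an elevation is −(a_left + a_right), floored at zero. Elevations blocked
by the bill holder are interpolated as the mean of the widths immediately
above and below and flagged as such. The horizontal plane decomposes as
cyclopean = binocular + 2·lateral and blind = 360° − cyclopean, an exact
identity the tests enforce; the vertical extent of the binocular field is
measured between the linear zero crossings of the width profile.

## Marker contrasts

Each marker material's reflectance spectrum (300–780 nm at 1 nm) reduces
to its arithmetic mean — deliberately unweighted: no illuminant, no
receptor weighting — and materials are compared by Michelson contrast with
an absolute-value numerator so the matrix is symmetric and unsigned.
Detectability compares the inverse contrast against the species' peak
contrast sensitivity with an inclusive threshold (1/C_m ≤ 16.67 counts as
detectable). Diffuse and diffuse-plus-specular components are analysed
separately, never mixed in one matrix; single-material markers are
excluded as carrying no internal contrast; reflectances above 100%
(fluorescent materials) pass through untouched.

## The synthetic-data module

Every stage has a seeded generator producing inputs with the statistical
structure the stage assumes: replicate absorbance spectra are template +
independent Gaussian noise per grid point (noise sd 0.02 on the peak-1
scale by default, with replicate counts 7/6/3/7 across SWS1/SWS2/Rh2/LW —
the aliquot counts of the black grouse measurements); reflex trials come from the deterministic
threshold observer above; reflectance spectra are smooth
baseline-plus-Gaussian-bump profiles; visual-field boundary tables are
generated by inverting the infinity correction from a truth map whose
horizontal sector values (28° binocular, 162.5° lateral) and 40° maximum
overlap at +30° elevation mirror the measured bird.

What the generators do **not** emulate: correlated instrument noise, stray
light and detector-changeover steps in spectra; attention, fatigue or
criterion drift in the behavioural observer (only an iid lapse rate);
eye-movement amplitude and pecten shadowing in the visual-field apparatus;
specular BRDF structure in reflectance. Passing tests therefore establish
that the pipeline recovers known parameters under clean, independent noise
— not that it is robust to every instrumental pathology of real data.

## Problem sizes and determinism

Default problem sizes were chosen so a complete synthetic run is a
seconds-scale desk computation: 0.1 nm spectral grids (5001 points), 1 nm
fitting grids, 200 bootstrap draws in the routine pipeline configuration
(1000 for report-scale intervals, as in the README example), and a
coverage simulation of 100 repetitions × 200 draws in the test suite.
Every stochastic step takes an explicit integer seed, derived per stage
from the single master seed, and restores the caller's RNG state on exit;
identical configurations reproduce reports bit for bit. Grid argmax ties
break to the lowest wavelength.

## Known limitations

* Ocular-media transmission is absent; the modelled short-wavelength
  perception bound is template-only and reported as `NA` when the β band
  keeps the SWS1 limb above 5%.
* A2 chromophore templates, rod/double-cone channels and receptor-noise
  chromatic discrimination are out of scope; the marker analysis is purely
  achromatic.
* The eye-allometry regressions are single-anchor calibrations; outside
  the neighbourhood of the anchoring eye size they should be treated as
  scaling guides, not measurements.
* The droplet cut-on slope parameterization is one defensible reading of
  a steepness quoted in log units per nanometre; the form is isolated so
  alternatives can be compared.
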