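---
title: "Models of complementary afterimage colours: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models of complementary afterimage colours}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coneadapt)
```

This vignette is the package's own account of the science it implements:
the candidate models of afterimage colour, the colorimetric scaffolding
underneath them, the tunable parameters and the conventions adopted where
several were defensible, what the synthetic observer does and does not
emulate, and the package's known limitations.

## The problem

A complementary afterimage is the illusory colour seen on a neutral field
after sustained fixation of a coloured inducer. Different sites of
chromatic adaptation along the visual hierarchy imply different afterimage
colours, so precise measurements of afterimage hue and chroma discriminate
between mechanisms. All models here answer the same question in the same
frame: *given an inducer, what CIELUV hue azimuth and chroma does the grey
probe take on?* Common to all of them, the probe's colour signal is
computed under local adaptation to the inducer and then re-embedded under
global adaptation to the grey background.

## Colorimetry

Everything runs from tristimulus-level colorimetry on a calibrated
three-primary display (`monitor_model()`): xyY primaries at full drive, a
shared gamma exponent, the white point, and a neutral background whose
luminance is derived from its target lightness (L\* = 70 by default) — the
background is computed from the CIE lightness function, never hard-coded.

* **Cone excitations.** The XYZ-to-LMS transform uses the 2-degree
  physiologically based (Stockman–Sharpe) fundamentals via the published
  cone-fundamental tristimulus matrix, inverted and rescaled so that
  L + M equals luminance and the equal-energy white has S = L + M. The
  field size is not dictated by the task; 2 degrees matches foveal
  fixation. Because the Weber-contrast model is provably invariant to
  per-channel rescaling (and this is property-tested), any documented
  scaling convention gives identical predictions; the matrix travels with
  `cone_fundamentals()` objects and is echoed in pipeline metadata so
  alternates can be swapped and reported.
* **DKL plane.** Isoluminant cone-opponent coordinates are cone contrasts
  relative to the background (`dL/Lbg - dM/Mbg`, `dS/Sbg`), each axis
  rescaled so that ±1 touches the monitor gamut at the background
  luminance. The two half-axes of a real display differ slightly; the
  smaller extent is used so both signs of ±1 are realisable, and the
  scaling constants are stored in the `dkl_axes()` object.
* **CIELUV / CIELAB** follow the standard formulas with the display white
  as reference; hue azimuth is `atan2(v*, u*)` in degrees,
  counterclockwise, 0° along +u\*, range [0, 360). All user-facing hue I/O
  is in degrees.
* **Gamut.** A colour is in gamut when its linear drives lie in
  [-tol, 1 + tol] with tol = 1e-6. "Maximum chroma" is resolved per hue,
  per monitor, at call time by bisection to 1e-4.

At isoluminance, u'v' chromaticity is a projective image of the cone
plane: straight lines through the background map to straight lines through
the neutral point. This is why subtractive adaptation in DKL and in CIELUV
predict *identical* hues (tested to 1e-6 degrees) while predicting
different chromas.

## The models

**Cone adaptation** (`predict_cone_adaptation()`). Weber-law contrast
coding per cone class: `CC = (bgLMS - iLMS) / iLMS`, afterimage
excitations `bgLMS (1 + CC) = bgLMS^2 / iLMS`. The multiplicative inverse
means the least-adapted cone dominates, producing three hue clusters,
three chroma peaks, six zero crossings of the deviation-from-opponency
curve, non-reciprocity, and a first-order (small-strength) limit equal to
the subtractive model — each of these is a property test. The predicted
excitations are generally not isoluminant with the background, so by
default the predicted chromaticity is projected back onto the
background-L\* plane before chroma is read out (hue is unaffected; the
unprojected coordinates remain in the `native` field).

**Cone-opponent adaptation** (`predict_cone_opponent()`). Subtractive:
the background's opponent signal is zero, so the prediction is the
reflection of the (effective) adapting colour through the origin of the
DKL plane. An optional half-wave-rectified route through single-signed
mechanisms is provided and is algebraically a no-op, kept because the
distinction matters physiologically even though it does not change
predictions.

**Appearance transforms** (`predict_appearance_model()`). The grey
background's coordinates are computed in the chosen space with the
effective inducer as adapting white, and the corresponding colour under
the display white is reported. For CIELUV this is u'v' subtraction; for
CIELAB the white-substitution reduces to a von-Kries scaling of XYZ
ratios; for CIECAM02 the CAT02 transform is used with the degree of
adaptation from the CIECAM02 formula (average surround, F = 1, adapting
luminance = background luminance / 5, all overridable). Only the
adaptation-transform route is implemented — the adaptation transform is
the substance of the CIECAM02 prediction and the full appearance-model
correlates add free viewing-condition parameters without changing the
qualitative prediction; the choice is recorded here and in the defaults.

**Munsell opponency** (`predict_munsell()`). The inducer is located in
Munsell coordinates by interpolation in CIELAB over a renotation-style
table, the hue 50 steps away on the 100-step circle is taken at the same
value and chroma, and mapped back out. Conventions not fixed by the
system itself: the lookup uses the tabulated value plane nearest the
background L\*, and the inducer's interpolated Munsell chroma is retained
for the opponent; both are echoed in the prediction's `native` metadata.
The package ships `synthetic_munsell_table()`, a smooth invertible
stand-in that reproduces the renotation *layout* (hue pages at 2.5 steps,
value rows, chroma columns) but not the measured renotation colorimetry —
it exists so the interpolation machinery is fully exercised without the
external data file, and a real renotation file in the standard
(hue-label, value, chroma, x, y, Y) layout plugs into
`read_munsell_renotation()` unchanged.

**Hering opponency** (`predict_hering()`). The inducer's fractional
position between its two neighbouring unique-hue prototypes is transferred
to the opponent pair (red–green, yellow–blue). Prototypes are
observer-specific empirical quantities, so they are a required argument
with no baked-in default azimuths. Hering opponency makes no chroma
prediction.

### Partial adaptation

Afterimages are less saturated than their inducers, so adaptation is
modelled as partial: every model adapts to an *effective adapting colour*
that keeps the inducer's hue but replaces its chroma with the adaptation
strength — 27.0 CIELUV chroma units (the grand average of afterimage
chroma adjustments) for CIELUV-sampled inducers and 0.47 gamut-scaled
radius for DKL-sampled ones. Setting a strength to `NA` requests complete
adaptation. Chroma-series analyses (afterimage hue as a function of
inducer chroma) use complete adaptation, because a fixed strength would
make every prediction independent of inducer chroma and the chroma-series
question degenerate. Strength 0 reduces every model to a grey
(chroma-zero) prediction, which is an identity test.

## The analysis pipeline

The statistics mirror standard practice for circular hue data:

* deviations from opponency: signed circular difference from
  inducer + 180°, in (-180, 180];
* hue histograms: left-closed bins tiling [0, 360), first edge at 0
  (24 bins of 15° by default; centre-aligned bins would be an alternative
  convention, edge-aligned is implemented);
* circular running means (window 9 for the smoothed-fit variance
  estimate), mass-preserving;
* Pearson correlations with Fisher-z 95% intervals and t-distribution
  p values (via `cor.test`);
* one-sample t tests of signed deviations with Cohen's d = t/√n and a
  Bonferroni-corrected alpha for the test family (signed rather than
  absolute deviations: confidence intervals of both signs only arise for
  signed data);
* paired t tests on per-participant mean absolute errors and exact
  two-tailed binomial sign tests across inducers for model comparison;
* z-scoring of chroma (sample-sd convention, recorded in metadata) so
  that only hue-dependent chroma variation is compared across models;
* the chroma-series analysis: per inducer hue, the circular mean of
  afterimage hues across chroma levels defines a reference line;
  measurements and predictions are each referred to their own line.

Histogram model simulation draws wrapped-Gaussian response noise around
each predicted hue (1e5 draws per inducer by default, so Monte-Carlo
error is far below the bin resolution). The response-noise sigma is not a
quantity the models fix; when not supplied it is estimated as the standard
deviation of measured deviations, with a configuration override.

`hue_clusters()` operationalises the "three hue clusters" signature: it
counts circular local maxima of the lightly smoothed (3-bin) histogram
whose density exceeds 1.35 times the deepest smoothed trough. The
thresholds derive from two computable quantities: the cone model's
analytic hue density has peak/trough ratios above about 1.5 (broad humps
peaking at only 1.15–1.5 times uniform, which is why an absolute
peak-height criterion fails), while Poisson counting noise on a flat
histogram at study-scale trial counts keeps the smoothed max/min ratio
near 1.2.

## The synthetic observer

`observer_config()` + the `simulate_*` functions generate datasets with
the statistical structure the analyses assume: true afterimage = a chosen
generative model's prediction; responses add wrapped-Gaussian hue noise
(default sigma 10°, of the order of hue discrimination scatter in
adjustment tasks) and rectified-Gaussian chroma noise (default sigma 5
CIELUV units, roughly a fifth of the mean afterimage chroma); the
forced-choice task snaps the noisy hue to the nearest of nine comparison
hues (opponent ±0, 10, ..., 40°, ties to the lower azimuth) and skips
trials with probability 0.02, matching the reported skip rate. Defaults
for sample sizes follow the study designs they emulate (e.g. 72 inducers
in 5° steps, 45 measurements per colour, 216 hue-by-chroma stimuli).

What the generator deliberately does **not** emulate: adjustment dynamics
(coarse/fine key presses, re-adaptation wiping), temporal decay of
afterimages, individual cone sensitivities, response biases, or any
deviation of real observers from the generative model. Passing
model-recovery tests therefore shows that the *pipeline* identifies the
generating mechanism under realistic noise — it is evidence about the
analysis code, not about human observers.

Model recovery (`run_model_recovery()`) simulates adjustment datasets,
aggregates per inducer (circular mean within participant, then across —
pooled aggregation is available via `pool = "all"`), computes per-model
absolute hue errors, and reports the winning model with sign tests
against it. Under the default conditions (72 inducers, sigma 10°, 10
repetitions) the generating model is preferred at p < 0.01 in about 97%
of seeded runs, measured over 300 seeds in the test suite; 300 runs keep
the Monte-Carlo standard error of that rate below one percentage point.

## Numerical choices and degenerate inputs

* Conversions are exact inverses to 1e-9 across the gamut interior
  (property-tested on 1000 random rendered colours).
* Achromatic predictions (chroma < 1e-9) carry an `NA` hue rather than an
  arbitrary angle.
* Circular means raise an error on zero resultant vectors (e.g. {0°,
  180°}) instead of returning an arbitrary direction; single-chroma-level
  hues are excluded from the chroma-series analysis with a warning.
* Degenerate statistics (constant vectors, all-tied signs) raise errors;
  the chroma-series wrapper reports `NULL` correlations for noise-free
  edge cases rather than failing the whole analysis.
* Gamut-boundary searches bracket to 1e-4 chroma units; the DKL axis
  scaling bisects to ~1e-18 relative precision (60 halvings).
* Seeds: every stochastic function takes an explicit seed;
  `add_response_noise()` restores the caller's RNG state.

## Problem sizes

The shipped tests run the full pipeline at the study's own scales (72
inducers, 216 chroma-series stimuli, up to 45 repetitions) and use 300
seeded recovery runs and 1e5-draw noise simulations; the complete suite
executes in under two minutes on a single CPU, and the acceptance script
in seconds. These sizes were chosen to keep Monte-Carlo error well below
every tested tolerance.

## Limitations

* Everything is tristimulus-level: no spectral computation, no individual
  cone sensitivities (a single standard observer), no photopigment
  kinetics or bleaching fractions — the Weber-contrast abstraction is the
  modelling boundary.
* Temporal dynamics of adaptation and afterimage decay are out of scope;
  the models describe the near-maximum-adaptation state.
* The synthetic Munsell table is a geometric stand-in; quantitative
  Munsell-opponency predictions for real colours require the actual
  renotation file.
* The CIECAM02 prediction is the CAT02 corresponding-colour step, not the
  full appearance model.
* Display rendering, gamma measurement and hardware calibration are out
  of scope; the monitor model trusts its configuration.
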