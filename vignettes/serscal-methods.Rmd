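---
title: "Window-restricted PLSR calibration of SERS spectra: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Window-restricted PLSR calibration of SERS spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(serscal)
```

## The problem

Potassium sorbate (PS) and sodium benzoate (SB) are the workhorse
antiseptics of acidic foods, frequently dosed together. Surface-enhanced
Raman scattering (SERS) makes their trace spectra measurable, and the band
intensities grow with concentration, so a regression from spectrum to
concentration is possible. Two things make the naive approach (one peak,
one straight line) unreliable: the enhancement delivered by a nanostructured
substrate varies from spot to spot, and in PS/SB mixtures the two analytes'
characteristic peak sections overlap, so the channels that calibrate one
analyte always contain signal from the other, varying over a wide range.

`serscal` implements the remedy used in practice: multivariate calibration
by partial least squares regression (PLSR) on the intensity of *all*
channels inside the target analyte's characteristic-peak windows.

## The calibration model

The fitting function `plsr_fit()` is a from-scratch univariate-response
NIPALS PLS1. The calibration spectra (rows of the observing matrix $X$)
and concentrations $y$ are mean-centered — no variance scaling, no baseline
correction, no smoothing; centering is the only pretreatment. For each
component $k$ on the deflated data,

$$w_k = \frac{X_c^\top y_c}{\lVert X_c^\top y_c\rVert},\quad
t_k = X_c w_k,\quad
p_k = \frac{X_c^\top t_k}{t_k^\top t_k},\quad
q_k = \frac{y_c^\top t_k}{t_k^\top t_k},$$

after which $X_c \leftarrow X_c - t_k p_k^\top$ and
$y_c \leftarrow y_c - q_k t_k$. The weight $w_k$ is, analytically, the unit
direction maximizing the covariance of the score $t_k = X_c w$ with the
response — the property that lets the model separate target-correlated
variation from interferent variation. With $A$ components the coefficient
is $b = W(P^\top W)^{-1}q$ and a prediction is
$\hat y = (x - \bar x)^\top b + \bar y$. Predictions are not clipped at
zero: blank samples may legitimately predict slightly negative, and that is
reported as-is.

For PLS1 these quantities have closed forms per component (no inner
iteration), the scores are mutually orthogonal and the weights orthonormal;
the test suite verifies both to tolerances 1e-8 and 1e-10, and checks that
using all components reproduces the minimum-norm least-squares solution.

### Choosing the number of latent variables

The studies this package emulates do not state how many components their
commercial chemometrics software used, so the package makes its own,
conventional choice: leave-one-sample-out cross-validation over candidate
counts $1..A_{\max}$ with $A_{\max} = \min(n-2,\ 10)$, selecting the
smallest count whose RMSECV is minimal. Two numerical details:

* ties are decided toward the smaller model, and "tie" means RMSECV within
  `max(1e-12, 1e-9 * min, 1e-10 * sd(y))` of the minimum — on noise-free
  data every count past the true rank gives an RMSECV that is zero up to
  rounding, and without the response-scaled slack the selection would
  wander among numerically identical minima;
* when a left-out fold's deflation terminates early (rank exhausted), the
  largest achievable count stands in for the missing ones.

### Degenerate inputs

When the residual covariance $\lVert X_c^\top y_c\rVert$ falls below
1e-12 of its initial scale, extraction stops early and the model keeps the
components found, with an `early_stop` flag — fitting a rank-1 problem with
`ncomp = 3` is not an error. Singular $(P^\top W)$ systems (not reachable
through the standard algebra, but possible with pathological inputs) fall
back to an SVD pseudo-inverse with relative cutoff 1e-10. All linear
algebra is double precision.

### Reported metrics

RMSE is the plain root-mean-square error in mg/L. R² is the **squared
Pearson correlation** between predicted and actual concentrations — the R²
of the predicted-versus-actual line — rather than $1 - SS_{res}/SS_{tot}$.
The two differ when predictions carry bias; the Pearson form is what a
"linear relation between two series of concentrations" describes, and it is
the definition under which the reference (R², RMSE) pairs for the
single-analyte study are mutually consistent. `r_squared()` implements the
Pearson form; both numbers are cheap to compute from the returned
prediction tables if the sum-of-squares form is wanted.

## The synthetic spectrum generator

No measured spectra are available to distribute, so `simulate_dataset()`
generates spectra carrying exactly the statistical structure the analysis
assumes:

$$I(\nu) = g \sum_a r(c_a)\, \phi_a(\nu) + \mathrm{baseline}(\nu) + \varepsilon(\nu)$$

* $\phi_a$ — each analyte's unit-concentration profile, a sum of
  **Lorentzian** bands (the natural line shape of Raman transitions;
  pseudo-Voigt was deliberately omitted as needless flexibility here).
* $r(c)$ — linear by default; optionally Langmuir,
  $r(c) = c\,c_{50}/(c_{50}+c)$, to emulate adsorption saturation.
* $g$ — one log-normal factor per spectrum, $\log g \sim N(0, \sigma_m^2)$:
  replicate spectra are taken at randomly chosen substrate positions, and
  spot-to-spot enhancement variability multiplies the whole spectrum at
  once. Its mean is $e^{\sigma_m^2/2}$, which a property test verifies
  empirically. One global factor per spectrum, not per analyte:
  competitive-adsorption effects are out of scope.
* $\varepsilon$ — iid Gaussian channel noise with s.d. equal to
  `sigma_add_frac` times the maximum clean intensity over the design, so
  all spectra of a dataset share one instrument noise floor.
* baseline — optional random cubic scaled to `baseline_amplitude`; off by
  default because the emulated workflow applies no baseline correction.

### Parameters and defaults

| parameter | default | units | rationale |
|---|---|---|---|
| axis | 400–1800, step 2 | cm⁻¹ | typical portable-Raman fingerprint region |
| PS bands | (1640, 12, 1.0), (1380, 10, 0.6), (1140, 10, 0.4) | (cm⁻¹, cm⁻¹, a.u. per mg/L) | synthetic stand-ins |
| SB bands | (1600, 10, 1.0), (1026, 8, 0.5), (1002, 6, 0.9) | — | synthetic stand-ins |
| `sigma_mult` | 0.03 | — | modest spot-to-spot variability |
| `sigma_add_frac` | 0.005 | fraction of clean max | weak instrument noise |
| `baseline_amplitude` | 0 | intensity | no baseline correction emulated |
| `saturation_c50` | off | mg/L | linear response regime |
| replicates | 5 | spectra/sample | five spectra per sample at random positions |
| window multiplier `k` | 3 | HWHM units | covers the visually prominent extent of a Lorentzian band |

The band positions are **invented**: the real characteristic peak sections
of PS and SB are only available graphically in the source material, so the
defaults make no claim to match them. What matters for the method is their
*topology*: the strongest PS band (1640 cm⁻¹) and the strongest SB band
(1600 cm⁻¹) are close enough that the `k = 3` windows
([1604, 1676] for PS's top band vs. SB's band at 1600) overlap, recreating
the overlapping-section regime that makes mixture calibration interesting.
Window intervals are closed; channel membership is decided on the printed
wavenumber with no interpolation, and overlapping intervals merge.

### Designs

`single_analyte_design()` is the 8-level PS series
{0.3, 0.5, 0.8, 1, 3, 5, 8, 10} mg/L; `mixture_design()` is the
36-composition full factorial PS × SB over {0, 1, 5, 10, 50, 100} mg/L,
numbered in blocks of constant SB with PS ascending — sample 21 is
(PS 5, SB 10), sample 36 is (PS 100, SB 100). Blank (0 mg/L) rows stay in
calibration and evaluation.

### What the generator does not emulate

Electromagnetic enhancement physics, adsorption kinetics, instrument
response functions, wavenumber miscalibration, cosmic-ray spikes, and any
matrix effect of a real food sample. Passing tests therefore demonstrate
that the *algorithmic chain* behaves correctly under the assumed
measurement model — linear response, multiplicative site variability,
additive noise — not that a given real substrate and spectrometer would
achieve the same figures.

## The three emulated studies

`reproduce_all()` runs, per seed pair:

1. **Single-analyte PS** — calibrate on the 8-level series, validate on an
   independently simulated series of the same levels;
2. **Mixture PS** — calibrate/validate on the 36-composition factorial
   using only the PS windows (which contain SB signal);
3. **Mixture SB** — the same with roles swapped.

Test sets are fresh draws of the same design under a disjoint seed — the
emulated workflow validated with "another series" of solutions, not with a
train/test split of one series. Calibration rows are per-sample
replicate-averaged spectra, and metrics are computed on per-sample
predictions (one point per composition). Five seed pairs (calibration seeds
$s..s+4$, test seeds offset by 100) are run and the median of each metric
reported, taming Monte-Carlo variation; the whole bundle — 2,700 simulated
spectra and 15 cross-validated fits — runs in a few seconds, so no
scaled-down mode is needed. `interference_analysis()` reproduces the
deviation-from-group-mean view of the mixture predictions: within each
true-PS level, the six samples (SB from 0 to 100 mg/L) are compared to
their group's mean prediction; deviations sum to zero within each group by
construction, and their magnitude measures interferent leakage.

## Known limitations

* The synthetic band libraries are plausibility stand-ins, not measured
  line positions; conclusions about real PS/SB spectra require re-deriving
  windows from measured bands (`window_set()` accepts explicit intervals).
* PLS1 only: one analyte per model. Multi-response PLS2, SIMPLS variants,
  orthogonal signal correction and VIP scores are out of scope.
* No uncertainty quantification on predictions; the prediction tables make
  a bootstrap straightforward to add, but none is implemented.
* Concentrations are handled in mg/L throughout; convert μg/L inputs at
  the boundary.
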