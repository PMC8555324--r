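---
title: "Methods: dosimetric beam-matching analysis for PBS proton gantries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dosimetric beam-matching analysis for PBS proton gantries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pbsmatch)
```

This vignette documents the models behind `pbsmatch`, the defaults and
their units, the design choices that were genuinely open, and what the
synthetic data generator does and does not emulate.

## The analysis problem

A multiroom proton centre delivers pencil-beam-scanning (PBS) fields from
several gantries fed by one accelerator. Two rooms are *beam-matched* when
their dosimetric characteristics — integrated depth-dose (IDD) curves and
lateral spot profiles — agree within clinical tolerance, so plans can move
between rooms without recalculation. Each room additionally carries a
fitted beam model in the planning system; the modelling step itself
introduces errors. The package quantifies three layers of agreement:
measured vs model-computed within a room, room vs room for measurements and
for models, and the downstream effect on patient-specific QA when two
rooms share a single model.

## Pristine Bragg peaks and the range–energy law

Mono-energetic depth-dose curves are generated analytically
(`mono_bragg()`): the ideal stopping profile

$$\hat D(z) \propto (R - z)^{1/p - 1}, \qquad z < R,$$

is convolved with a Gaussian of width $\sigma_s(R) = k R^m$ representing
range straggling. The ideal profile is extended below the water surface
before convolution; truncating it at $z = 0$ would produce a spurious
entrance dip that real IDDs do not show. The integrable singularity at
$z = R$ is handled by cell-averaging the profile on an internal 0.05 mm
grid before an FFT convolution.

Parameters, with defaults and units (`beamline_config()`):

| parameter | default | unit | meaning |
|---|---|---|---|
| `alpha` | 0.0022 | cm·MeV⁻ᵖ | range–energy coefficient, $R = \alpha E^p$ |
| `p` | 1.77 | — | range–energy exponent |
| `straggling_k` | 0.012 | cm¹⁻ᵐ | straggling scale, $\sigma_s = k R^m$ |
| `straggling_m` | 0.935 | — | straggling exponent |
| `depth_step_mm` | 0.1 | mm | analysis depth grid |

The power-law constants are validated against the two machine calibration
points (69.8 MeV → 4.0 g/cm², 226.09 MeV → 32.0 g/cm²); they reproduce
both within 1.2%. Only the *shape family* of the curves matters to the
pipeline — the spectrum fit, R80 extraction and γ comparison are agnostic
to the exact stopping-power parameterization. The distal falloff of the
convolved peak reaches 0.1% of the peak value by about $4\sigma_s$ beyond
$R$ (the power-law/Gaussian convolution has a heavier-than-Gaussian
shoulder, so the often-quoted $3\sigma$ figure does not apply to it).

## Effective energy spectra

`fit_spectrum()` solves a non-negative least-squares problem against a
basis of unit-maximum pristine peaks at the nominal energy ± 10 MeV in
0.5 MeV steps (41 members). Design choices:

* **NNLS without regularization.** The basis granularity and any
  regularization used by commercial modelling tools are not public; plain
  NNLS (Lawson–Hanson, via `pracma::lsqnonneg`) is the declared choice.
  Non-negativity itself acts as a strong regularizer; recovered spectra
  are sparse or compact unimodal in practice.
* **Span/step trade-off.** ±10 MeV covers > 4 energy-spread sigmas at
  every nominal energy (σ_E defaults to 0.7% of E, i.e. ≤ 1.6 MeV);
  0.5 MeV steps keep the basis well-conditioned. Both are configurable;
  the NNLS residual is non-increasing as the step refines.
* **Scale separation.** Weights are normalized to sum to one and the
  overall amplitude is kept as a separate `scale` attribute, so spectra
  are comparable across energies once curves are normalized to unit
  maximum.

R80 is defined on the *distal* edge (the standard proton convention),
located by linear interpolation on the 0.1 mm grid; sub-grid bias is below
0.05 mm. The R80 energy inverts the range–energy law at the reconstructed
curve's R80.

## The γ engine

For each reference point the γ index is the minimum over evaluated points
of $\sqrt{\Delta r^2/\delta_{DTA}^2 + \Delta D^2/\delta_{DD}^2}$.
Numerical choices:

* **Global normalization** to the reference maximum; dose differences are
  percentages of that maximum. Local-normalization γ is out of scope.
* **Roles.** The measured distribution is the reference; the computed one
  is evaluated (and is the distribution that gets interpolated). In
  cross-gantry comparisons the first (lower-numbered) gantry is the
  reference and the baseline of every relative difference.
* **Search window** of radius 3·DTA; reported γ values are therefore
  capped by the window limit. The evaluated distribution is sampled at
  DTA/10 during the search, but never coarser than its native grid — this
  guarantees that loosening the criteria cannot lower a passing rate
  (monotonicity would otherwise be broken by discretization).
* **Distances are measured from the exact reference coordinates**, not
  from the nearest fine-grid node, so reference grids that are not
  sub-multiples of the search lattice are handled without bias.
* **Boundary inclusive**: γ ≤ 1 + 10⁻⁹ counts as passing; the epsilon
  guards analytically exact boundary cases (a pure DTA-limit shift, a
  uniform dose-tolerance offset) against floating-point noise.
* Points below the low-dose threshold (10% of the reference maximum for
  QA planes) are excluded from the summary only, not from computation.

## Spot optics

Spot images are reduced per plane: median background of the outer 5%
border subtracted (clamped at zero), square ROIs of half-width 8·σ_nominal
cut around the five pattern positions and recentered on their intensity
centroids, pixelwise-averaged into the equivalent spot, and sliced through
the centroid row/column into X and Y profiles. An ROI is rejected when
another spot's nominal position falls inside it, or when a centroid sits
more than 5 mm from its nominal position. With the default 80 mm pattern
spacing, ROI rectangles of the lowest-energy spots may touch at corners;
the contamination there is beyond 5σ of the neighbouring spot and is
ignored.

Profiles are fitted with a single Gaussian plus a constant baseline (the
baseline absorbs residual detector background; the beam model itself is a
cylindrical single Gaussian). The fit is Levenberg–Marquardt initialized
from profile moments, with an nl2sol fallback: on exactly noiseless
profiles the zero-residual solution can defeat the LM wrapper's
finite-difference Jacobian check.

The free-drift Fermi–Eyges fit regresses σ²(z) on (1, 2z, z²) with z in
metres, so that A is mm², B mm·mrad and C mrad² (mrad·m = mm). B < 0
denotes a beam converging towards larger z; this sign convention is
declared, not inferred. With noiseless σ values at ≥ 3 planes the
recovery is exact (a polynomial identity). A fitted C may come out
slightly negative under noise — the estimate is accepted as long as
σ²(z) > 0 across the ±300 mm measurement span, because clamping at zero
would bias repeated-measurement averages. The gantry mounting angle is
ignored: the fit assumes pure free drift in air, as the five-plane
measurement geometry does.

## The synthetic two-gantry generator

The generator emulates the *statistical structure* of water-phantom
commissioning data, not any real machine:

* **IDD curves**: Gaussian-weighted superpositions of pristine peaks
  (σ_E = 0.7% of E by default, 0.25 MeV sampling), range-shifted by the
  gantry's offset, with multiplicative lognormal noise (0.2% default) and
  unit-maximum normalization, on a 0.1 mm grid to 350 mm.
* **Spot planes**: 5-spot patterns (centre + (±80, ±80) mm) rendered as
  per-axis Gaussians whose σ(z) follows the free-drift law, on a
  300 mm × 300 mm, 0.5 mm grid at z = −300, −150, 0, +150, +300 mm, with
  per-spot position jitter, lognormal dose noise and an additive detector
  floor at 0.1% of the image maximum. Default optics: isocenter σ falls
  log-linearly from 6 mm (70 MeV) to 3 mm (226.09 MeV), angular spread
  from 3 to 1.2 mrad, correlation −0.25, with the Y axis 5% narrower than
  X. These magnitudes are plausible for a dedicated-nozzle PBS line and
  are clearly synthetic stand-ins: no machine's true σ(E) or σ_E(E)
  tables are public.
* **Two gantries**: "GTR2" is the nominal line with measurement noise;
  "GTR4" adds +0.3 mm range offset (the water-phantom positioning
  repeatability scale), 5% wider energy spread, and +2.3% spot σ — the
  upper end of what matched rooms exhibit, keeping cross-gantry isocenter
  σ differences comfortably inside the ±10% matching envelope.
* **QA pairs**: single-layer square spot fields per cohort (prostate
  40 mm half-size / 6.5 mm σ, lung 30/5.5, NPC 55/5.0, each with ±15%
  per-plan size variation, spot spacing equal to σ, mild edge
  enhancement), computed on a 1 mm grid and "delivered" onto a 33 × 33,
  7.6 mm QA array. The delivery applies the arm's σ-scale mismatch, a
  **rigid** setup offset drawn from the 0.3 mm positioning s.d., a
  range-driven global amplitude change of 2% per mm of range offset, and
  0.5% measurement noise. The position error is rigid rather than
  per-spot because measurement-position uncertainty is dominated by
  phantom setup; independent 0.3 mm per-spot scatter would instead
  impose ±5% interior dose ripple, which is not how a scanned delivery
  with layer-wise systematic errors behaves.
* **Model-sharing arms**: each gantry has a true state and a fitted-model
  state (σ scale 1.005/1.000 for GTR2 true/model, 1.023/1.018 for GTR4;
  range offsets 0.1/0.0 and 0.3/0.2 mm). An arm's effective perturbation
  combines the chosen model with the delivering gantry, so every arm sees
  at most ~2.3% σ and 0.3 mm range mismatch.

Everything is deterministic under a fixed seed (per-energy sub-seeds are
derived arithmetically from the main seed).

**What passing tests do and do not show.** The generator reproduces curve
shapes, drift kinematics, detector geometry and noise levels, so it
validates the *pipeline*: spectrum deconvolution, γ computation, optics
fitting, and the orchestration. It does not contain nuclear-halo/low-dose
envelopes, double-Gaussian spot tails, CT-based heterogeneity, plan
optimization or 3-D dose — so green tests say nothing about those effects,
and the QA study's passing rates are optimistic relative to clinical
tables (near 100% at 3 mm/3%, because planar analytic fields lack the
error sources that push real plans toward 95%). Paired-arm t/r statistics
on real QA tables cannot be reproduced from simulation; the package
instead verifies the statistics' null calibration and their agreement
with direct formula evaluation.

## Problem sizes used in the test suite

The shipped tests run the full 33-energy IDD reproduction and a
12-plans-per-cohort QA study (144 γ evaluations), which completes in about
a minute on a single core; spot-image tests use a compact 160 mm / 1 mm
detector with a 45 mm pattern so that five-plane optics fits stay fast
while exercising the identical code path as the full-size 300 mm / 0.5 mm
configuration.

## Known limitations

* The analytic Bragg-peak family has no nuclear buildup component; its
  entrance-to-peak ratios are higher than measured IDDs at high energy.
* Spectrum fits are only identifiable up to the basis granularity
  (0.5 MeV); narrower structures alias onto neighbouring members.
* The γ engine caps values at the 3·DTA window; distributions that
  disagree more than that report the cap, not the true γ.
* The Fermi–Eyges fit assumes free drift in air; in-material scattering
  power is out of scope.
* Cohort field templates are synthetic stand-ins; absolute QA passing
  rates should be read as envelope checks, not clinical predictions.
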