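---
title: "Models and methods behind sarcomri"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind sarcomri}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

sarcomri implements a muscle quantity/quality MRI analysis for
sarcopenia research together with the synthetic data needed to verify
it. This vignette explains the signal models, the segmentation and
morphology rules, the statistical battery, the synthetic-data design,
and the numerical choices — including the places where the design was
genuinely open and what we chose.

## Signal models

**Multi-echo chemical shift (PDFF and T2*).** Each voxel holds water and
fat proton pools with amplitudes $W, F \ge 0$. With a single-peak fat
resonance offset by $\Delta f$ from water, the magnitude signal at echo
time $TE$ is

$$S(TE) = \left|\,W + F e^{i 2\pi \Delta f\, TE}\right|
          \, e^{-TE/T_2^*}
        = \sqrt{W^2 + F^2 + 2WF\cos(2\pi \Delta f\, TE)}\; e^{-TE/T_2^*}.$$

We use $\Delta f = 434$ Hz (3.4 ppm at a 3 T proton frequency of about
128 MHz), making the opposed-phase echo time $1/(2\cdot 434\,\mathrm{Hz})
\approx 1.15$ ms. The proton density fat fraction is
$\mathrm{PDFF} = F/(W+F)$. A single spectral peak is the minimal model
consistent with a six-echo protocol; multi-peak fat spectra and field-map
(off-resonance) estimation are out of scope, as is complex-valued
fitting — only magnitudes are modelled.

An important consequence of magnitude-only single-peak fitting: the
model is *exactly invariant* under swapping $W$ and $F$, so a voxel with
PDFF $p$ and one with $1-p$ produce identical signals. The fitter
resolves this water–fat ambiguity with a muscle prior: among
residual-tied branches it reports the PDFF $< 0.5$ solution. This is the
right behaviour in muscle (the analysis mask), and the documented
behaviour everywhere else: fat-dominant tissue is reported at the
mirrored fraction. No estimator could do otherwise from these data.

**Diffusion (ADC and D).** The diffusion-weighted signal follows the
bi-exponential intravoxel-incoherent-motion (IVIM) form

$$S(b) = S_0\left[f e^{-b D^*} + (1-f) e^{-b D}\right],$$

with tissue diffusion coefficient $D$, perfusion fraction $f$ and
pseudo-diffusion $D^*$ ($D^* \ge D$). Two estimators are provided, both
closed-form ordinary-least-squares slopes of $\log S$ against $b$:

- **ADC** uses *all* b-values (0, 50, 100, 400, 1200 s/mm²) — the
  conventional definition, perfusion-sensitive, hence ADC $\ge$ D in
  perfused tissue;
- **D** uses only $b \ge 200$ s/mm² (the two high-b points of this
  protocol), suppressing the perfusion compartment. A full three-
  parameter IVIM fit is deliberately not attempted: five points with two
  above the perfusion knee make $(f, D^*)$ practically unidentifiable
  under noise, while the high-b log-slope estimates $D$ with a residual
  perfusion bias below 0.5% at $f = 0.1$.

**Rician noise.** Magnitude MRI noise is modelled as
$\sqrt{(S+g_1)^2 + g_2^2}$ with $g_1, g_2 \sim N(0, \sigma^2)$; at
$S = 0$ this is the Rayleigh distribution with mean
$\sigma\sqrt{\pi/2}$, which the tests verify.

## PDFF/T2* fitting: parameterisation and numerics

The fitter works on $(p, \log T_2^*)$ with $p \in [0,1]$ and
$T_2^* \in (1, 200]$ ms, with the overall amplitude profiled out in
closed form (variable projection): for a unit-amplitude model shape
$m(TE; p, T_2^*)$, the optimal amplitude is
$\hat A = \max(0, \langle S, m\rangle / \|m\|^2)$, reducing the problem
to two dimensions. Optimisation is bounded L-BFGS-B from multiple starts
on a coarse $(p, T_2^*)$ grid.

Two numerical facts shaped the implementation, both found by the
exhaustive grid-search oracle in the test suite:

- $p = 0.5$ is a symmetry ridge of the magnitude model (the gradient in
  $p$ vanishes identically there), so starts are chosen greedily with
  *distinct* $p$ values and any $p = 0.5$ start is nudged off the ridge;
  otherwise all top starts can sit on the ridge and the optimiser never
  leaves it.
- The $(p, T_2^*)$ landscape has shallow curved valleys along which
  residuals are numerically degenerate. Oracle agreement is therefore
  asserted as residual dominance (the NLS optimum is never worse than an
  exhaustive $201 \times 200$ profiled grid search) plus recovery of the
  noiseless generating parameters within one grid cell, rather than as
  argmin-vs-argmin proximity, which is ill-posed along a degenerate
  valley.

Voxels with all-zero signal are flagged, never fitted; flagged voxels
are excluded from (not imputed into) per-subject means. Boundary hits of
the $T_2^*$ box are reported via `at_bound`, never silently clipped.
Identical signals — ubiquitous in noiseless phantoms — are fitted once
and broadcast.

## Segmentation by intensity clustering and connectivity

The T1-weighted volume is segmented in three steps:

1. **Body mask.** Otsu's threshold on the intensity histogram, keep the
   two largest 26-connected components (the legs), fill in-plane holes
   so dark cortical bone and bright marrow belong to the body.
2. **Clustering, k = 3.** One-dimensional k-means on the masked
   intensities into dark / mid / bright populations. The four anatomical
   classes collapse to three intensity populations on T1w (marrow and
   fat share brightness); anatomy is recovered by connectivity.
   *Initialisation:* the intuitive percentile initialisation (10/50/90)
   is degenerate on fat-dominant thighs — two of the three percentiles
   fall in the bright mode, and Lloyd iterations from duplicated centres
   split the bright mode instead of separating dark from mid. We instead
   solve the binned (512-bin) 1-D k-means problem *exactly* by dynamic
   programming and polish with Lloyd iterations on the raw intensities.
   This is deterministic, seed-independent, and at least as good as any
   random restart scheme.
3. **Anatomical assignment.** Bright voxels enclosed in-plane by the
   dark shell → marrow; the dark shell (and all dark inside the body) →
   cortical bone; bright 26-connected components touching the background
   or the in-plane volume faces → subcutaneous fat; remaining bright
   components, enclosed by muscle, → intramuscular fat; mid → muscle.
   The axial faces are deliberately *not* treated as an outer boundary:
   the legs run through the whole stack, so fat touching the first or
   last slice is not thereby subcutaneous.

Small intramuscular components below a configurable volume (default
0.5 ml) are reassigned to muscle, standing in for the exclusion of
vessels and the neurovascular bundle; on coarse phantoms without
vessels this step should be disabled (`min_structure_ml = 0`).

**Macroscopic fatty infiltration** closes the muscle ∪ intramuscular-fat
mask morphologically (ball element, default radius 5 mm — enough to
bridge the speckle scale at this resolution, exposed as a knob) and
reports fat voxels inside the envelope divided by envelope voxels minus
bone voxels inside it. Closing is idempotent and never shrinks its
input; both properties are tested.

## The thigh phantom

Two legs, each a stack of concentric cylinders: background →
subcutaneous fat ring → muscle annulus → cortical bone shell → marrow
core, on a default 128 × 256 × 40 grid at 1.5 × 1.5 × 5 mm (200 mm
femoral coverage). Shell radii are set by order statistics of the
in-plane voxel-centre distances, so designed voxel counts are hit
exactly up to rounding — the four volumetric targets (muscle volume,
muscle/fat, muscle/bone, infiltration) are achieved to ≪1% rather than
the 2% voxelisation budget. Defaults are the reference cohort means:
muscle 1.25 L, muscle/fat 0.69, muscle/bone 13.0, infiltration 0.34,
PDFF 0.13, T2* 31.6 ms, D 1.01·10⁻³ mm²/s, with the muscle perfusion
fraction calibrated (≈0.06 at $D^* = 10\cdot10^{-3}$) so the
conventional ADC of the clean signal is exactly 1.05·10⁻³ mm²/s.

Intramuscular fat is placed as seeded random in-plane discs of radius
1–2 voxels until the designed infiltration is met exactly (the last
disc is trimmed). A one-voxel guard margin keeps speckle from touching
the subcutaneous ring so that the connectivity rules stay well posed —
real intermuscular fat does approach the fascia, which is a known
simplification. T1w class intensities are ordinal only (bone 50, muscle
500, fat/marrow 1000, background 0); absolute units carry no meaning.

What the phantom deliberately omits: coil sensitivity and bias fields,
motion, eddy currents, partial-volume mixing at boundaries (labels are
crisp), multi-peak fat, anatomical shape variation. Passing recovery
tests on it therefore demonstrates correctness of the *computational
chain*, not robustness to real-world artefacts.

## The cohort simulator

Subjects are drawn from a multivariate normal on the raw variable scale
with literature-informed marginal means/SDs for 38 variables
(cineanthropometric, functional, respiratory, imaging), truncated at
physiological lower bounds by row-wise redraw. The target correlation
matrix is assembled from the published imaging-vs-clinical cells;
unpublished pairs default to zero and the result is repaired to the
nearest positive-semi-definite correlation matrix (Higham-style
projection via `Matrix::nearPD`).

Two consequences deserve emphasis:

- **The repair attenuates published cells substantially** (the BMI–ADC
  cell moves from −0.71 to about −0.45). This is not a bug: a
  rectangular block of strong correlations with all complementary pairs
  pinned to zero is far from any valid correlation matrix. Studies that
  need a specific cell reproduced should configure the sampler with just
  the variables involved (as the acceptance script does), where no
  repair is needed.
- **The IPAQ group effect** is applied as an additive shift of the
  diffusion coefficient D (+0.09·10⁻³ mm²/s in the moderate group,
  group fractions 8/26 vs 18/26) that preserves the overall D marginal.
  The published group means (0.81/0.90) are arithmetically inconsistent
  with the published overall mean (1.01); we keep the marginal and the
  between-group difference, which is what the group comparison tests.
  The shift adds a small variance component to D and thereby attenuates
  D's correlations by a few percent.

With a fixed seed the sampler is bit-reproducible.

## Statistics

Normality gating uses Shapiro–Wilk at α = 0.05, *per variable* (a pair
is Pearson only if both variables pass — the stricter of the two
readings of the ambiguous convention; per-pair gating is selectable).
Constant samples are non-normal by definition. Group comparisons use
Student's t (equal variances) when both groups pass the gate and
Mann–Whitney U otherwise, exact for combined n ≤ 20 without ties and
normal-approximated with tie correction beyond. All tests are two-sided.
No multiple-comparison correction is applied by default, matching the
uncorrected starred-report convention of small-cohort imaging studies
(`p_adjust` switches it on). The report keeps all cells and flags those
with |r| > 0.4 as `reported`; stars are 0.05/0.01/0.001.

The test suite verifies the U test against exhaustive rank-permutation
enumeration for all group sizes up to 6, Spearman against the
rank-difference formula, and the per-cell type-I star rate under the
global null (0.05 ± 0.02, pooled over 1000 simulated cohorts).

## Problem sizes and runtimes

Unit and property tests run on 8-slice (and 4-slice) stacks of the same
per-slice reference design — the per-slice geometry is identical to the
full phantom and the designed muscle volume scales with slice count.
The end-to-end volumetric recovery and the acceptance script use the
full 40-slice grid (≈1.3 M voxels; segmentation plus closing in a few
seconds, the complete pipeline including map fits under ten). Noise
robustness is characterised at 10³ voxels; correlation-recovery
expectations over 200 cohorts of n = 26; the sampler's convergence to
its repaired target at n = 40,000 (the max-norm runs over 703 variable
pairs, so smaller n would confound sampling noise with bias).

In rendered cohort mode each subject is materialised as a phantom and
pushed through the imaging pipeline. Short stacks render a proportional
sub-volume and the measured volume is scaled back by the axial coverage;
sampled designs that are not geometrically representable (a
subcutaneous ring thinner than the grid can carry, a cross-section
exceeding the field of view) are clamped or shrunk shape-preservingly.
Fast mode skips rendering and feeds the sampled biomarkers directly to
the statistics — the mode to use when exercising the statistical path
at scale.

## Known limitations

- Single-peak magnitude PDFF is blind to the water/fat-dominance
  distinction (see above) and carries no field-map handling.
- The D estimator inherits a small positive perfusion bias (<0.5% at
  f ≈ 0.1) by design.
- The phantom's crisp labels mean segmentation Dice scores near 1 are
  expected; they bound algorithmic correctness, not clinical accuracy.
- Whether published per-subject imaging values summarise both thighs or
  the dominant leg is ambiguous; both modes exist (`leg` argument), with
  both-legs the default.
- The cohort simulator reproduces first and second moments and a
  repaired correlation structure — not skewness, floor/ceiling effects
  (e.g. Barthel), or discreteness of score variables.
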