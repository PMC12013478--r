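---
title: "Quantifying white-matter perivascular space volume fraction"
author: "pvsfrac"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying white-matter perivascular space volume fraction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvsfrac)
```

## The measurement problem

Perivascular spaces (PVS) are CSF-filled sheaths around penetrating
cerebral vessels. On T2-weighted MRI they appear as thin, bright,
roughly cylindrical structures threading the white matter. Enlarged PVS
are a marker of cerebral small vessel disease — in cerebral amyloid
angiopathy (CAA) they are thought to reflect obstructed perivascular
clearance — but the standard visual rating counts PVS on a single slice
and tops out at "> 40", a ceiling that symptomatic patients reach
early. A volumetric alternative segments every PVS-like tube in the
normal-appearing white matter (NAWM) and reports

$$\mathrm{PVS_{vf}} = \frac{\text{segmented PVS volume (mm}^3)}{\text{NAWM ROI volume (mm}^3)},$$

a dimensionless fraction that normalizes for how much white matter was
searched — essential in diseased brains where hemorrhages and
hyperintensities progressively eat into the NAWM.

`pvsfrac` implements this measurement as a semi-automated pipeline:
every numeric step is automatic, while the two genuinely judgment-laden
steps of the protocol — NAWM correction around lesions, and the
segmentation threshold — are explicit per-subject inputs (a lesion mask
and a scalar) rather than hidden defaults.

## Pipeline stages and their parameters

### ROI construction

The NAWM ROI is pure mask arithmetic on co-registered inputs:

```
ROI = brain − dilate(CSF, 2.5 mm) − templates − lesions
```

* `csf_dilation_mm` (default **2.5 mm**): a safety margin that keeps
  the ROI away from the ventricular and sulcal CSF, whose bright
  boundary would otherwise light up the tube filter. Dilation is
  defined in physical millimetres, not voxels: a voxel joins the
  dilated set iff its center lies within the radius of some CSF voxel
  center, distances measured with the anisotropic spacing. This is
  implemented by thresholding an exact Euclidean distance transform
  (Felzenszwalb's separable algorithm with per-axis sampling equal to
  the spacing), and the boundary is inclusive so radius 0 is the
  identity. On 3.6 mm slices a 2.5 mm dilation therefore never crosses
  a slice — the physically correct behavior.
* `exclusion_masks`: cerebellum, brainstem, basal ganglia and lateral
  ventricle templates, registered externally. Registration itself is
  out of scope: the package consumes co-registered masks (or resamples
  them with `resample_mask_nearest()` given affines), because
  mutual-information registration and tissue segmentation are solved
  problems in dedicated tools.
* `lesion_mask`: the library representation of manual NAWM editing.
  Interactive editing cannot live in a library; a mask of ICH/WMH
  voxels subtracted from the ROI reproduces its effect and keeps the
  operation scriptable and auditable (per-step removed-voxel counts are
  logged).

### Intensity normalization

The protocol normalizes the T2 signal "from the histogram" without
further specification, so the package adopts the simplest scheme with
the right invariances: percentile rescaling,
`clip((v − P1)/(P99 − P1), 0, 1)`. It is exactly invariant to positive
affine intensity rescaling (scanner gain), monotone, and robust to
hyperintense outliers such as hemorrhage rims through the 1 %/99 %
window (both percentiles configurable, optionally computed inside a
reference mask). This makes a single vesselness threshold comparable
across subjects; it is a documented stand-in for the original
in-house software's unspecified scheme.

### Multi-scale Frangi vesselness

At scale $\sigma$ the Gaussian scale-space Hessian is computed and its
per-voxel eigenvalues ordered $|\lambda_1|\le|\lambda_2|\le|\lambda_3|$.
With $R_A = |\lambda_2|/|\lambda_3|$ (line vs plate),
$R_B = |\lambda_1|/\sqrt{|\lambda_2\lambda_3|}$ (blob-ness) and
$S = \sqrt{\lambda_1^2+\lambda_2^2+\lambda_3^2}$ (structure-ness), the
bright-tube response is zero wherever $\lambda_2 > 0$ or
$\lambda_3 > 0$ and otherwise

$$V = \left(1 - e^{-R_A^2/2\alpha^2}\right)\, e^{-R_B^2/2\beta^2}
      \left(1 - e^{-S^2/2c^2}\right).$$

The final map is the per-voxel maximum over scales, zeroed outside the
ROI.

Parameter choices, all exposed:

* **Scales**: 10 values linearly spaced from $\sigma = 1$ to $3.5$
  in-plane voxels — at 0.5 mm in-plane resolution that spans tube radii
  from barely-visible to clearly enlarged PVS. The protocol fixes the
  endpoints and count but not the spacing; linear is assumed.
* **$\alpha = \beta = 0.5$**: the standard defaults of the filter; the
  original software's values are unreported.
* **$c$ adaptive**: half the per-scale maximum of $S$. The maximum is
  taken *inside the ROI*: CSF boundaries just outside it carry the
  largest Hessians in the image, and letting them set $c$ would deflate
  every in-ROI response. Adaptive $c$ also makes the map exactly
  invariant to intensity scaling (Hessian and $c$ scale together),
  which the test suite checks to 1e-8.
* **$\gamma = 2$** scale normalization (derivatives multiplied by
  $\sigma_{mm}^\gamma$), the condition for the max over scales to be
  meaningful. With a Gaussian tube profile of std $s$ this puts the
  argmax scale at $\sigma = s$; the suite verifies the argmax lands
  within one scale step of a 1.5-voxel profile.
* **Polarity** is hard-wired bright-on-dark (PVS are CSF-bright on T2);
  a dark mode exists only for testing.
* **Anisotropy**: $\sigma$ is interpreted in in-plane voxel units and
  converted to one physical scale
  $\sigma_{mm} = \sigma \cdot \mathrm{mean}(s_x, s_y)$, realized
  per-axis as $\sigma_{mm}/s_{axis}$ so the smoothing kernel is
  isotropic in millimetres. PVS are mm-scale physical objects; on
  3.0–3.6 mm slices the through-plane kernel is therefore deliberately
  sub-voxel (a warning notes the under-resolution once per run), which
  mirrors the acquisition's intrinsic through-plane insensitivity
  rather than pretending to resolve it.

Numerical choices: Gaussian-derivative kernels are sampled at radius
$\lceil 4\sigma \rceil$ and renormalized to be exact on polynomials up
to degree two (zero DC response enforced exactly inside the
convolution, first/second moments matched), so the Hessian of a
quadratic is analytic and constants map to an identically zero
response; at sub-voxel $\sigma$ the second-derivative kernel degrades
gracefully to the central difference `[1, −2, 1]`. Borders use
half-sample symmetric reflection, which affects voxels within about
$3\sigma$ of the volume edge. Per-voxel eigenvalues come from the
analytic trigonometric solution for symmetric 3×3 matrices (verified
against a dense solver to 1e-10); $\lambda_3 = 0$ or a failed sign gate
yields $V = 0$ exactly.

### Segmentation and threshold choice

A voxel is PVS iff it is in the ROI and its vesselness **strictly
exceeds** the threshold — strictness makes threshold 1 the empty
segmentation, a clean degenerate endpoint (the protocol does not state
the comparison). No component-size or shape post-filter is applied by
default because the protocol describes none; `min_component_voxels`
exists but defaults to 0. The threshold itself is a required
per-subject input, mirroring the per-participant manual adjustment of
the original protocol; `sweep_thresholds()` tabulates volume fraction
and 26-connected component count over a threshold grid as decision
support, and on phantoms the sweep combined with Dice against ground
truth replaces visual tuning in the tests.

## The phantom generator

`generate_phantom()` builds the study conditions in silico: an
ellipsoidal white-matter "brain" wrapped in a one-voxel bright CSF rim,
straight bright cylinders of known radius (default 0.3–1.5 mm), length
and orientation placed clear of the CSF dilation zone, optional bright
WMH-like and dark ICH-like spheres that never touch the tubes, and
Rician magnitude noise $\sqrt{(v+n_1)^2+n_2^2}$ — the correct
magnitude-MRI noise model, which reduces to Gaussian at high SNR. The
default grid uses the anisotropic 0.50 × 0.56 × 3.60 mm voxels of a
typical multi-slice T2 acquisition; intensities follow the T2
brightness ordering (CSF ≳ tubes > WMH > WM > ICH, defaults 200, 180,
160, 100, 40 with channel noise σ = 5, i.e. white-matter SNR 20).
Generation is deterministic given the mandatory seed, tubes are placed
before lesions so the same seed yields identical tubes with and without
lesions, and the analytic truth $\sum \pi r^2 L$ accompanies the
voxelized truth mask.

Tubes are straight because curvature adds no test power for a Hessian
line filter at these scales. What the phantom does **not** emulate —
cortical folding, bias fields, motion, partial-volume crescents around
real sulci, tissue texture — bounds what passing tests prove: recovery
on the phantom demonstrates that the chain of mask arithmetic,
normalization, filtering and thresholding measures what it claims on
tubes in noise, not that segmentation quality on clinical data matches
an expert. On a noiseless 1 mm isotropic phantom with tubes of
radius ≥ 1 mm the sweep-selected threshold reaches Dice ≈ 0.9 and a
volume-fraction error under 10 %; the test suite asserts the looser
contracts Dice ≥ 0.6, relative error ≤ 25 %, lesion-induced change
≤ 10 %, and Dice ≥ 0.4 for in-plane tubes on the thick-slice grid.

## The statistical battery

Group-level analysis of PVSvf uses heteroscedasticity-robust tools
throughout, because group spreads differ by an order of magnitude
between symptomatic carriers and young controls:

* `welch_anova()` — Welch's $F$ with Welch–Satterthwaite $df_2$,
  cross-checked in the tests against `stats::oneway.test` and equal to
  the squared Welch $t$ at $k = 2$. Effect size uses the classical
  one-way $\omega^2 = df_1(F-1)/(df_1(F-1)+N)$; no Welch-specific
  variant is claimed.
* `games_howell()` — pairwise comparisons on the studentized-range
  distribution (`ptukey`/`qtukey`, accurate far beyond the 1e-4 needed
  here), with Welch–Satterthwaite per-pair df. Cohen's d uses the
  pooled-SD formula; published pairwise d values computed with an
  unknown variant are not reproduced, only the formula's own hand
  cases.
* `icc_intrarater()` — ICC(A,1): two-way mixed effects, absolute
  agreement, single measurement, the standard model for two ratings by
  one rater.
* `spearman_rho()` — mid-rank Pearson correlation with the
  $t$-approximation p-value.
* `welch_power_mc()` — Monte-Carlo power (default 10,000 replicates,
  mandatory seed): the reference tool's internals are unknown, so power
  is estimated by direct simulation with MC standard error
  $\le \sqrt{0.25/\mathrm{reps}}$, vectorized over replicates with the
  same Welch formula as `welch_anova()`.
* `median_iqr_from_counts()` — quartiles by linear interpolation
  between order statistics (position $1 + p(n-1)$, R type 7), the
  convention that reproduces every published median/IQR in the cohort
  tables shipped as `dcaa_csvd_score_counts()`.

Simulated type-I error of the Welch test under strongly heteroscedastic
nulls (e.g. SDs 1 vs 4 with n 5 vs 20) stays in [0.03, 0.07] at nominal
0.05 — the property that motivates Welch over classical ANOVA — and is
asserted at 10,000 seeded replicates.

## Problem sizes, determinism, limitations

The test suite runs its end-to-end recovery at 96³ (about 20 s) and its
unit phantoms at 32³–64³; Monte-Carlo assertions use 10,000 replicates.
These sizes are chosen so the full suite completes in a few minutes
while keeping every tolerance comfortably resolvable. Nothing in the
pipeline consumes randomness except phantom generation and power
simulation, both of which require explicit seeds and restore the
caller's RNG state; re-running any configuration reproduces PVSvf
bit-identically.

Known limitations: through-plane sensitivity on 3.0–3.6 mm slices is
physically limited (in-plane tubes dominate recovery, as they do in the
acquisition); the NAWM stand-in shifts responsibility for lesion
delineation to the supplied masks; the normalization and the filter
constants $\alpha, \beta, c$ are documented surrogates for unreported
in-house settings; and the per-subject threshold remains a judgment
call — the package quantifies its consequences (sweep tables, the
threshold column of every result) rather than eliminating it.
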