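---
title: "Deformation-based morphometry of radiation-induced brain injury: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deformation-based morphometry of radiation-induced brain injury: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Whole-brain irradiation (WBI) of the rodent brain produces delayed,
spatially focal tissue changes: early shrinkage of white-matter tracts such
as the corpus callosum and later expansion of cortical grey matter,
accompanied by microstructural changes — restricted water diffusion (lower
mean diffusivity, MD) in the early phase and reduced cerebral blood volume
(CBV) in the late phase. Deformation-based morphometry (DBM) detects the
macrostructural component without any tissue segmentation: every subject
is registered nonlinearly to a common template and the analysis is run on
the *deformation fields themselves*, summarised voxel-wise by the Jacobian
determinant of the template-to-subject map.

`morphorad` implements that full analysis chain — brain masking, bias
correction, per-timepoint mean-control template, affine + diffeomorphic
nonlinear registration, log-Jacobian maps, voxel-wise permutation
statistics with family-wise error (FWE) control, atlas-based naming of
significant clusters, quantitative CBV and diffusion-tensor maps, and the
group/time statistics (two-way ANOVA with Fisher LSD, Pearson correlation
matrices with Fisher-z p-values) — together with a synthetic phantom cohort
generator that provides analytic ground truth for every stage.

## The morphometric model

The nonlinear registration produces, per subject, a displacement field
$u(x)$ on the template grid (world millimetres) defining
$\Phi(x) = x + u(x)$, the map from template to subject coordinates. Local
volume change is

$$J(x) = \det\!\left(I + \nabla u(x)\right),$$

computed with spacing-aware central differences (one-sided at boundary
faces). Statistics are run on $\log J$: zero under the identity, positive
where the subject is locally larger than the template (expansion), negative
for contraction, and additive under composition of maps. The natural
logarithm is used. Gradients are taken in world mm, so anisotropic voxels
(the default phantom uses 0.25 × 0.25 × 0.5 mm) are handled exactly;
central differences are exact on affine fields, which the closed-form tests
exploit.

## Registration

*Affine stage.* Rigid/similarity/affine registration maximises the mutual
information of a 32-bin smoothed joint histogram (Nelder–Mead with
restarts, multi-resolution 4×/2×/1×). Two details matter on
piecewise-constant-plus-noise images: the histogram is evaluated over
fixed-image foreground only (the masked background is pose-insensitive and
would swamp it), and both images are Gaussian pre-smoothed at each level so
tissue boundaries become ramps and the metric is smooth in the pose
parameters. The returned transform is guaranteed not to decrease the
full-resolution MI relative to its initialisation.

*Nonlinear stage.* A greedy compositive demons scheme with
local-correlation forces: both images are locally standardised (mean/SD
over a box window, radius 2 voxels), and a Thirion-style update
$\delta = e\,g / (\lVert g\rVert^2 + e^2/\mathrm{cap}^2)$ is computed from
the standardised residual $e$ and symmetric gradient $g$, so steps are
mismatch-proportional with a hard per-voxel cap (0.8 voxels by default).
Each image is standardised by *its own* local SD: this divides out smooth
amplitude differences (bias fields, interpolation blur), which would
otherwise masquerade as geometric mismatch and destabilise the field.
Updates are smoothed (σ_update = 1 voxel), composed, and the accumulated
field smoothed again (σ_total = 0.5 voxel); orientation preservation
(min det ∇Φ > 0) is enforced by step halving. The two pyramid images at
every level are built through an identical smoothing path, so
self-registration residuals are exactly zero and the null field is
recovered exactly.

Two operating points are worth distinguishing. For *measurement* of a
single pair (how large is this deformation?), stronger field
regularisation is preferable: with σ_total = 1 and σ_update = 2 voxels the
regional mean log-Jacobian of a planted 10% focal contraction is recovered
within ±0.02 across texture realisations, and without it the field slowly
accumulates a texture-chasing drift that overestimates the deformation as
full-resolution iterations grow. For *detection* in a cohort (is there a
group difference?), the default σ_total = 0.5 retains more per-subject
sensitivity and the group statistics absorb the extra field noise; the
shipped study configuration uses the default.

The field direction convention: the stored field maps template coordinates
to subject coordinates (pull-back resampling), so det ∇Φ > 1 means the
subject's region is larger than the template's. The DBM statistics use the
Jacobian of the *nonlinear* part only; the affine pose is held outside the
field.

## Voxel-wise inference

Group comparison uses the pooled-variance two-sample t per voxel (positive
t where the irradiated group exceeds controls). FWE control across voxels
is by group-label permutation with the maxT procedure: every relabeling of
the pooled subjects yields a statistic map whose maximum absolute value is
recorded; a voxel is significant when the fraction of relabelings whose
maximum reaches its observed statistic is at most α (default 0.01,
exhaustive enumeration when there are at most `n_perm` relabelings, an
explicit α-floor warning when fewer than 100 exist). This is
distribution-free and exact, which is the appropriate replacement for
parametric random-field corrections at rodent sample sizes.

Inside the permutation loop the default statistic is a *pseudo-t*: each
relabeling's voxel standard errors are floored at their median. With n = 6
per group, the raw-t maxT null is dominated by voxels whose pooled variance
is accidentally tiny (observed critical values |t| ≈ 20), which destroys
power; the floor removes that pathology while leaving FWE control exact,
because the identical statistic is used for the observed and permuted
labelings. The plain Student statistic remains available (`stat = "t"`),
and `voxelwise_ttest()` always returns the textbook pooled t. Log-Jacobian
maps are smoothed isotropically in world space *before* masking
(σ = 0.6 mm by default): the displacement field extends smoothly past the
brain boundary, and masking first would drag cortical edge values toward
zero and bias edge-adjacent clusters inward. At the default n = 6 vs 6
the C(12,6) = 924 distinct relabelings are enumerated exhaustively
(`n_perm = 1000`), so the null distribution carries no sampling
variance.

Significant voxels are split by sign, connected components extracted (26-
connectivity by default, 6/18 available), and each cluster is resolved
against a label atlas (rigid registration of the atlas reference to the
template, nearest-neighbour label resampling) into per-structure overlap
fractions and a majority structure.

## Quantitative maps

*Diffusion.* The tensor is fitted voxel-wise by ordinary log-linear least
squares on $\ln S = \ln S_0 - b\,g^\top D g$ over the six unique tensor
elements plus intercept — deterministic and exact on noise-free data with
the default 30-direction, b = 0/1000 s/mm² protocol. Eigenvalues are sorted
descending; negative eigenvalues are flagged, never silently clipped.
Scalars: MD = (λ₁+λ₂+λ₃)/3, AD = λ₁, RD = (λ₂+λ₃)/2, exported in μm²/s
(1 mm²/s = 10⁶ μm²/s, so 0.7 × 10⁻³ mm²/s appears as 700 μm²/s, the
conventional reporting scale).

*Blood volume.* With a steady-state intravascular susceptibility agent,
$\Delta R_2^* = \ln(S_\mathrm{pre}/S_\mathrm{post})/TE$ and

$$\mathrm{CBV}(\%) = 100\cdot\frac{3}{4\pi}\cdot
  \frac{\Delta R_2^*}{\gamma\,\Delta\chi\,B_0}.$$

The product $\gamma\,\Delta\chi\,B_0$ is exposed as a single configurable
constant (default: γ = 2.675 × 10⁸ rad s⁻¹ T⁻¹, Δχ = 10⁻⁷, B₀ = 7 T):
the effective susceptibility increase depends on the agent and dose and is
rarely published, so absolute CBV values are only as good as that
calibration — the package asserts formula correctness and exact round-trip
identity against its own simulator, not absolute agreement with any
particular scanner calibration. TE defaults to 13 ms. Negative CBV voxels
(noise) are flagged, not clipped.

*ROI statistics.* Mean JD/CBV/MD/AD/RD are extracted per subject inside
the significant DBM clusters (the table records ROI provenance — using
clusters from the same JD analysis is circular for JD itself, so a priori
atlas ROIs can be substituted). The two-way ANOVA (group × time) uses Type
II sums of squares via model comparison — appropriate for the unbalanced
cells of attrition-prone longitudinal animal studies — followed by Fisher
LSD group contrasts at each timepoint on the pooled residual mean square.
Correlation matrices use pairwise-complete Pearson r with two-sided
p-values from the Fisher z statistic $\mathrm{atanh}(r)\sqrt{n-3}$ (a
t-based alternative is available); per-pair n is always reported, and
pairs with n < 4 get r without p.

## The synthetic cohort: what it emulates and what it does not

`make_phantom()` builds an analytic rodent-like anatomy: an ellipsoidal
brain (asymmetric semi-axes, default 5.5 × 6.5 × 9 mm) with a cortical
shell, deep-grey interior, a white-matter band standing in for the corpus
callosum, and asymmetric paired ventricles; every voxel's class is known
exactly and class-mean intensities are exact before degradation. The
left/right asymmetry is deliberate: a rotationally symmetric phantom makes
pose unobservable to any intensity metric.

`make_cohort()` turns this into a two-group longitudinal study on disk.
Each subject is synthesised by resampling the (textured) phantom through
the numerical inverse of its ground-truth forward field — pull-back through
a field with centre Jacobian r produces a structure scaled by 1/r, so
inversion is required for "volume_ratio 0.8" to mean a genuinely contracted
structure whose *recovered* template-to-subject Jacobian is 0.8. Subjects
receive Rician magnitude noise (√((s+n₁)²+n₂²), SNR ≈ 50 by default, the
scale of a multi-average RARE acquisition), a smooth multiplicative bias
field, and per-subject smooth anatomical jitter (0.04 mm). A deterministic
multiplicative intra-tissue texture (two correlation lengths) plays the
role of common anatomy: real T2w images carry texture that makes
deformation observable away from tissue boundaries, and without it the
centre Jacobian of a planted blob is fundamentally unrecoverable (only
~30% of the planted log-ratio is visible from edges alone). Because the
texture *is* the anatomy, its seed is a fixed constant of the phantom
definition, not a function of the cohort seed — every cohort shares one
template anatomy, as an inbred-strain study would. Diffusion series are
simulated from piecewise-constant tensors (isotropic grey matter ≈
0.7–0.8 × 10⁻³ mm²/s, anisotropic white matter (1.5, 0.3, 0.3) × 10⁻³,
near-free CSF) and the T2* pairs from piecewise-constant CBV (cortex 6%,
deep grey 4%, white matter 3%, CSF 1%).

Planted irradiation effects follow the early-contraction / late-expansion
pattern: corpus-callosum centre Jacobian 0.78 at 1 month and cortical
expansion 1.5 at 6 months (Gaussian radius 1.8 mm), MD reduced to 0.77 of
control where affected, CBV to 0.74–0.75. The deformation magnitudes were
sized at design time so the *recovered* group contrast clears the
exhaustive maxT threshold with a wide margin at n = 6 per group — the
adequately-powered-design convention the package's own power tests also
use (effects of roughly three times the between-subject log-Jacobian
noise). Edge-adjacent effects are harder to recover than deep ones (the
cortical blob sits near the brain boundary, where part of its support has
no intensity evidence), which is why the planted cortical expansion is
larger than the white-matter contraction; the seeded structures are made
locally thick (as the corpus-callosum genu and cortical gyri are) so the
detected cluster's majority structure is the seeded one rather than the
surrounding deep grey matter.

What the phantom does *not* emulate: realistic rat neuroanatomy, partial
volume effects, k-space/pulse-sequence artefacts, susceptibility
distortion, eddy currents, motion, or arterial input physiology. Passing
tests on this cohort demonstrates that the pipeline's algorithms are
correct and powered under controlled conditions; it does not certify
performance on scanner data with those additional failure modes.

## Numerical choices and degenerate inputs

- Log-Jacobian clamps determinants below 10⁻⁶ before the log and counts
  the clamped voxels; non-positive determinants are reported, and the
  demons guarantees positivity inside its own fields by step halving.
- Brain masking is deterministic: Otsu threshold (256 bins), largest
  26-connected component, ball-radius-2 closing, hole filling; a constant
  image is an explicit error. A user-supplied mask can be used anywhere
  downstream.
- Bias correction fits an order-2 (10-coefficient) polynomial to masked
  log-intensities by least squares and preserves the masked median
  exactly; non-positive masked voxels are clipped to the smallest positive
  masked value with a warning. This handles smooth, low-order
  inhomogeneity; it is not a substitute for histogram-sharpening
  correction on strongly shaded clinical data.
- Displacement inversion uses fixed-point iteration (25 iterations),
  accurate to ~10⁻⁴ mm for the smooth fields used here.
- Permutation seeds are explicit everywhere and recorded in the JSON run
  manifest together with stage parameters and output checksums.
- Cluster ordering is deterministic: size descending, ties broken by
  lexicographic centroid. Clusters below `min_cluster_voxels` (default 5)
  are dropped from reports.

## Problem sizes used by the shipped checks

The test-suite and the acceptance script exercise closed-form checks at
32³, registration parameter recovery on the full 64 × 64 × 48 phantom, the
null FWE calibration on 50 simulated 6-vs-6 cohorts of 32³ smooth noise
maps with 500 permutations, and the end-to-end study on a 48 × 48 × 32
demonstration phantom (n = 6 per group, timepoints 1M and 6M, 500
permutations) across several cohort seeds. These sizes are the package's
demonstration configuration; the algorithms have no dependence on them,
and `phantom_spec()`/`dbm_config()` scale everything up.

## Known limitations

- The demons stage recovers deep focal deformations nearly completely but
  underestimates deformations near the brain boundary; treat absolute
  log-Jacobian magnitudes near the mask edge as conservative.
- Absolute CBV in % depends entirely on the γ·Δχ·B₀ calibration constant.
- The two-way ANOVA is fixed-effects; longitudinal within-subject
  correlation is not modelled (no mixed-effects machinery), matching the
  conventional analysis this pipeline reproduces.
- No multiple-testing correction is applied across the cells of the
  correlation matrices, deliberately mirroring common practice for these
  exploratory panels; interpret isolated significant cells accordingly.
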