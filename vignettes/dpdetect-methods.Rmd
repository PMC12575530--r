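---
title: "Detecting small pancreatic cancer from segmentation masks: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting small pancreatic cancer from segmentation masks: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dpdetect)
```

## The detection problem

Small pancreatic ductal adenocarcinomas (PDAC, diameter ≤ 2 cm) are
frequently invisible as masses on contrast CT, yet they announce
themselves indirectly: a tumor obstructing the main pancreatic duct (MPD)
dilates the duct *upstream of the obstruction* — that is, tail-ward,
since the duct drains toward the head — and the obstructed parenchyma
atrophies. `dpdetect` implements a two-channel detector built on exactly
this physiology:

1. **Tumor-mass channel.** A voxelwise tumor-likelihood volume ("heat
   map", produced upstream by a segmentation CNN and consumed here as
   input) is summarised by its **maximum value**.
2. **Indirect-indicator channel.** The **D/P ratio** — the
   cross-sectional area of the MPD divided by the cross-sectional area of
   the pancreatic parenchyma, measured on planes perpendicular to the
   pancreas centerline — is computed at every centerline station and
   summarised by its **90th percentile**.

A case is called positive when *either* channel exceeds its calibrated
threshold (logical disjunction, strict `>`). The mass channel is
calibrated for 80% sensitivity on a threshold-setting cohort, and the D/P
channel for 100% specificity there, so that adding the indirect channel
raises sensitivity while giving away as little specificity as possible.

## The D/P ratio pipeline

**Centerline.** The centerline is estimated from the *union* of the
parenchyma and duct masks (the duct bridges parenchymal gaps at the
neck): largest 26-connected component → 3-D topological thinning to a
curve skeleton → skeleton graph with edges weighted by physical
inter-voxel distance → **geodesic diameter** (the longest shortest path
over all skeleton voxel pairs; ties break to the lexicographically
smallest endpoint voxel index, making the result deterministic) →
moving-average smoothing (5 stations) → arclength resampling at 1 mm →
central-difference tangents. Thinning deletes *simple points* (points
whose removal provably preserves 3-D topology, checked by counting
foreground 26-components and background 6-components in the local
neighbourhood) in six directional sub-iterations, preserving curve
endpoints.

Thinning systematically erodes flat organ ends before a curve endpoint
can form there, so the geodesic path stops short of the organ
extremities. The estimator therefore prolongs both path ends along their
local direction until the walk leaves the mask, capping the walk at the
endpoint's *clearance* (its distance to the nearest background voxel —
the local inscribed radius). At a flat-cut end the clearance equals the
eroded extent, recovering it; at a rounded or tapered tip the skeleton
already reaches the extremity and the clearance is a fraction of a
millimetre, so essentially nothing is added. On a 100 mm solid cylinder
the estimated length is 98.5 mm; on the default curved phantom the error
is about −3% of the analytic curve length.

**Orientation.** Which end is the pancreatic head cannot be decided from
a mask alone, so orientation is configuration: an explicit head-end
coordinate, or an anatomical direction vector (the head is the endpoint
with the larger projection). The synthetic cohorts generate their curves
head-at-low-*x*, and the pipeline default (`head_vector(c(-1, 0, 0))`)
encodes that convention.

**Cross-sections.** At each station the masks are sampled by
nearest-neighbour lookup on a regular 2-D grid (pitch = native voxel
spacing, half-width 40 mm — generous for any pancreas) in the plane
orthogonal to the local tangent; the in-plane basis is built
deterministically from the tangent and its least-aligned coordinate
axis. Voxel counting times cell area gives the duct and parenchyma
areas; on a voxelized disc of radius 10 mm at 1 mm spacing the area
error is under 3%.

**The ratio and its summary.** The denominator is the parenchyma mask
alone: segmentation labels are mutually exclusive, so the duct lumen is
already excluded. (The alternative convention, duct/(parenchyma+duct),
differs by under 5% at physiological ratios.) Stations whose parenchyma
area falls below 20 mm² are flagged invalid and excluded from every
summary: the ratio diverges as its denominator vanishes at the organ
tips. The 90th-percentile summary uses the linear-interpolation quantile
(`stats::quantile` type 7) — quantile conventions differ across
ecosystems, so the definition is fixed and tested.

**Jump localization.** When only the indirect channel fires, the tumor
is reported at the place where the D/P profile "increases sharply" from
head to tail. We formalize this as a step detector: after median
pre-smoothing (window 5), each station is scored by the *forward
contrast* — the mean ratio over the next 10 stations minus the mean over
the previous 10 — and the maximizing station is reported if the contrast
reaches 0.005 (about a quarter of the smallest dilation effects the
generator produces). Ties go to the most head-ward station. A
single-station forward difference was evaluated first and rejected: on
20-cancer cohorts at the package's default conditions it recovered the
true tumor arclength fraction (within 0.1) in only 60–75% of cases,
because one-station differences are at the mercy of voxel-scale noise on
a duct whose cross-section spans only a handful of voxels. The
10-station flanks (≈1 cm at 1 mm stations) average that noise out while
leaving a genuine obstruction step — which persists for centimetres —
untouched; recovery on the same cohorts is 100%.

## Threshold calibration and classification

On the threshold-setting split, the mass threshold is the largest cutoff
keeping the fraction of cancers with `heatmap_max > t` at or above 80%,
realized as the midpoint between adjacent distinct observed scores
(stable to float jitter); the D/P threshold is the maximum control D/P
score, which under strict `>` gives exactly 100% specificity with the
smallest — hence most sensitive — admissible threshold. "Above the
threshold" is read as strict inequality; boundary equality is negative
(configurable in spirit, but the strict reading is what the package
tests). Published thresholds from the original clinical calibration
(0.051 for the heat map, 0.019 for the D/P ratio) are tied to their
private calibration data and are not reproducible from synthetic
cohorts; the *rule* is what the package reproduces, and its achieved
rates are recorded in the threshold provenance.

Localization follows the reporting rule: the mass channel's peak segment
when the mass channel fired, otherwise the D/P jump segment. Segments
map arclength fractions through breakpoints head [0, 0.40), body
[0.40, 0.70), tail [0.70, 1]. The uncinate process cannot be
distinguished by arclength, so "head (uncinate process)" exists only as
a truth label and matches geometric "head" calls at head granularity.
Localization concordance divides, by default, by the number of
*detected* cancers — an undetected cancer has no predicted location;
counting such cases as discordant is available via
`denominator = "all"`.

## Evaluation statistics

Sensitivity, specificity, PPV and NPV come with 95% **Wald** intervals
(p̂ ± z·√(p̂(1−p̂)/n), clipped to [0, 1]); Wald is the reporting default
because it reproduces the published sensitivity/specificity intervals
digit-for-digit, and Wilson and Clopper–Pearson are available behind a
flag. The **exact McNemar** test doubles the Binomial(b+c, ½) tail of
the smaller discordant count and caps at 1. **Fisher's exact test** for
R×2 tables is computed by full enumeration of tables with fixed margins
(multivariate hypergeometric; probabilities compared with a 1e-9
tolerance) — exact and bit-reproducible for the ≤4×2, n≈100 tables in
scope, and verified against `stats::fisher.test` in the test suite. ROC
curves sweep all distinct cutoffs under strict `>` with trapezoid AUC.
**Decision-curve analysis** uses the binary-test net benefit
NB(pt) = TP/N − (FP/N)·pt/(1−pt) against treat-all and treat-none
references. Note that with the published confusion counts this formula
makes the combined and D/P curves cross near pt ≈ 0.27, so a claim that
the combined model dominates everywhere below pt = 0.5 is not
algebraically reproducible from binary verdicts alone; the package
implements the standard formula and leaves that tension documented
rather than patched.

Display rounding is one decimal for percentages and three for p-values;
all internal values are unrounded.

## The phantom generator

Real cohort data for this problem are private CT segmentations, so the
package ships a generator whose cases have the statistical and geometric
structure the detector assumes, with analytic ground truth:

* a cubic-spline axis through head→tail control points (default curve
  ≈105 mm — compact for test-suite economy, with the same calibre
  relationships as a 15 cm gland);
* parenchyma radius tapering 10→6.5 mm head to tail, duct radius
  1.2 mm, both further tapered at the organ extremities (parenchyma to
  28% over the outer 7% of arclength, duct to 15% over 15%): real glands
  taper at the head beak and tail tip, and blunt spherical end caps
  would bias centerline termination. The duct tapers earlier than the
  parenchyma so the tail-zone ratio stays bounded even under dilation;
* rasterization by stamping spheres along the densely sampled axis; the
  duct is subtracted from the parenchyma so masks are disjoint, as real
  mutually-exclusive segmentation labels are;
* cancer cases: a tumor at arclength fraction s₀ multiplies the duct
  radius by the dilation factor and the parenchyma radius by the atrophy
  factor for s > s₀ (tail-ward — upstream of the obstruction); the tumor
  is modelled in the truth record and heatmap only, not carved out of
  the parenchyma (a documented simplification);
* heatmaps: a Gaussian blob (σ = tumor radius/2) of configurable
  amplitude at the tumor centre, plus distractor blobs and Gaussian
  voxel noise in every case, max-composed and clipped to [0, 1];
* segmentation error: independent flips of boundary voxels at rate
  `surface_noise_sd / voxel`.

Cohort draws (defaults in `cohort_parameters()`): tumor diameter
7–20 mm uniformly — the clinical small-PDAC range; tumor position
s₀ ∈ (0.15, 0.85); dilation 1.6–2.4; atrophy 0.80–0.95; duct calibre
0.9–1.4 mm; per-case parenchyma scale 0.9–1.15 and ±2.5 mm control-point
jitter; tumor blob amplitude 0.25–0.95 against distractors at 0.05–0.35,
so the mass channel misses some cancers and the calibrated thresholds
sit in a non-trivial place. Everything is reproducible from a single
seed, down to byte-identical NIfTI files.

**What the phantoms do not emulate** — and therefore what passing tests
do *not* establish about clinical data: CT intensities and contrast
phases (inputs are masks and likelihoods, not images); CNN heatmap
behaviour (blobs are idealized); fatty infiltration and other
non-obstructive parenchymal change; duct branches and anatomical
variants; uncinate anatomy (arclength cannot express it); correlated
segmentation errors. Phantom results validate the *machinery* —
geometry, calibration rule, disjunction logic, statistics — not clinical
performance.

## Numerical choices and degenerate inputs

* Quantiles: linear interpolation (type 7), fixed.
* Geodesic ties and equal heatmap maxima: resolved toward the smallest
  voxel index; all pipeline stages are deterministic given inputs.
* Orientation rule ambiguity (both endpoints project equally) is an
  error, not a guess.
* Empty masks, empty calibration classes, all-zero contingency tables,
  zero-denominator metrics: all are errors or flagged `NA`s, never
  silent zeros.
* Per-case pipeline failures mark the case unevaluable and the cohort
  run continues, reporting the failure list.
* Problem sizes in the test suite (cohorts of 12–40 cases, grids of
  ~0.3 megavoxels, 0.5 mm resolution only for the convergence checks)
  were chosen as the smallest sizes at which the validated properties
  are stable.

## Known limitations

The centerline assumes one dominant elongated component; multi-branch
duct trees are out of scope. The percentile and validity-floor choices
are calibrated for organs in the tested size range; organs a fraction of
the default calibre would need `min_parenchyma_area_mm2` revisited.
Published PPV/NPV confidence intervals could not be reproduced by Wald,
Wilson or Clopper–Pearson intervals with their natural denominators
(sensitivity/specificity intervals reproduce exactly); the package
reports Wald for all four metrics and leaves the discrepancy noted.
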