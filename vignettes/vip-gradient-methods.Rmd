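---
title: "Seed-based VIP connectivity gradients: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seed-based VIP connectivity gradients: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vipgradient)
```

## The analysis

The macaque ventral intraparietal area (VIP) sits in the fundus of the
intraparietal sulcus and is commonly treated as one area, but its
connectivity changes gradually along the antero-posterior axis. This
package implements the seed-based resting-state analysis used to map
that gradient: three 20-voxel seed ROIs (anterior, middle, posterior
VIP) are carved from consecutive coronal slices of the VIP label, and
each seed's mean time series is correlated with every ipsilateral
in-mask voxel, run by run.

For a run with kept frames $t = 1,\dots,n$, the connectivity of voxel
$v$ to seed $s$ is the Pearson correlation $r_{sv}$, variance-stabilized
by the Fisher transform $z_{sv} = \operatorname{artanh}(r_{sv})$. Within
each subject, run-level $z$ maps are aggregated as their mean, and a
two-sided one-sample t-test across runs against zero yields per-voxel
p-values; the subject map keeps its mean-$z$ values where $p < 0.001$
and is zero elsewhere. Group maps are unweighted means of these masked
subject maps ("zero-fill" convention; see *Open choices* below).

Group maps are moved to an abstract surface (each vertex inherits the
value of its unique source voxel), thresholded at $z > 0.05$ (strict
inequality; sweep 0.03–0.07 for robustness), and combined into an
eight-way exclusive categorization per vertex — NONE, A, M, P, AM, MP,
AP, AMP — depending on which seed maps cover it. Category maps are
displayed with the additive RGB code (A blue, M green, P red; overlaps
cyan/yellow/magenta; AMP white) and summarized as composition
percentages per hemisphere or per lobar region. Map similarity is
quantified as Spearman rank correlation between unthresholded
whole-hemisphere maps; per-area statistics compare the three seeds'
connected-vertex ratios across animals with Kruskal–Wallis tests and
Benjamini–Hochberg correction at 0.05, followed by a seed-preference
classification (anterior vs posterior).

## The synthetic phantom

The original animal data are not deposited, so the package ships a
generator that plants a known connectivity structure and lets the whole
chain be validated against ground truth. The phantom emulates the scale
of the study it mirrors: 10 subjects, 8 runs of 300 frames at TR 2 s
(per-subject run counts, frame counts and TR can also be drawn from the
packaged acquisition table with `emulate_acquisition()`), 1.25 mm
voxels, two hemispheres of 24×24×18 voxels (~20k in-mask voxels), and a
two-level parcellation of 16 areas in 8 lobar regions per hemisphere.

Each run draws three latent seed signals $s_a, s_m, s_p$ — unit-variance
Gaussian processes band-limited to 0.01–0.1 Hz (white noise through a
zero-phase DFT band mask, so their spectral power lies entirely inside
the analysis band and survives preprocessing) — plus a global
fluctuation, white-matter and ventricle nuisance signals with fixed
voxel-wise couplings, shared motion spikes, and white noise:

$$y_v(t) = w_a s_a(t) + w_m s_m(t) + w_p s_p(t)
  + g_0\,g(t) + w_{wm} n_{wm}(t) c_v + w_{csf} n_{csf}(t) d_v
  + \text{spike}(t) + \varepsilon_v(t).$$

The loading triple $(w_a, w_m, w_p)$ is constant within an area and set
by the area design; the implied true category of a voxel is the
zero-pattern of its loadings. Seed-ROI voxels always load 1.0 on their
own latent only. The default design covers all eight categories, places
three anterior-only and two posterior-only areas (targets for the
preference statistics), leaves three areas unconnected, and gives the
anterior-middle pair more shared territory (2 AM + 2 AMP areas) than
the anterior-posterior pair (1 AP + 2 AMP), which reproduces the
gradient signature $\rho(a,m) > \rho(a,p)$.

Default amplitudes — noise sd 1, global 0.15, wm/csf 0.3, single-seed
loadings 0.7, two-seed 0.5, triple 0.6, spike probability 0.02 per
frame — were chosen once to give realistic run-level correlations
(r ≈ 0.4–0.6 at loaded voxels, as in awake-monkey contrast-agent data)
while keeping the global-signal-induced null correlation (~0.02) well
below the detection threshold.

What the phantom does *not* emulate: hemodynamic response shapes,
spatial autocorrelation of the noise, head-motion realignment errors,
physiological rhythms, or mesh geometry (vertices are abstract table
rows with a region/area hierarchy; projection is a seeded 1-to-1..3
voxel-to-vertex fan-out). Passing recovery tests therefore demonstrates
the correctness of the analysis chain, not performance on real data.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `band_hz` | 0.01–0.1 | Hz | band-pass edges; the alternative 0.0025–0.05 Hz protocol band can be supplied |
| `order` | 4 | — | Butterworth order, applied forward-backward (zero phase) |
| `fd_threshold_mm` | 0.5 | mm | framewise-displacement scrub cutoff |
| `fwhm_mm` | 1.5 | mm | Gaussian smoothing kernel width |
| `alpha` | 0.001 | — | subject-level t-test threshold, uncorrected |
| `z_thr` | 0.05 | z | surface threshold (strict >), sweep 0.03–0.07 |
| `bh_alpha` | 0.05 | — | post-correction significance for area tests |

## Numerical choices

* **Filter realization.** Zero-phase forward-backward Butterworth of
  order 4. Because the forward-backward pass is linear in its input,
  the package applies the filter to the identity matrix once per series
  length and caches the resulting operator, filtering all ~10k voxels
  of a run in a single BLAS multiply with results bit-identical to the
  per-column reference. Columns are demeaned before and after filtering
  so constant series map to exactly zero.
* **Censoring.** Frames with FD above threshold are dropped, never
  interpolated; filtering runs on the concatenation of kept frames.
  Runs losing more than half their frames are excluded (logged). Series
  shorter than 64 kept frames are refused as filter-unstable, and
  correlation maps require at least 32 kept frames.
* **Fisher transform.** $|r|$ is clipped to $1-10^{-7}$ so the seed's
  own voxels stay finite; zero-variance voxels yield $z = 0$ with a
  logged count rather than NaN.
* **Degenerate t-tests.** Zero across-run variance gives $p = 0$ for a
  nonzero mean and $p = 1$ for a zero mean.
* **Smoothing.** Separable Gaussian with
  $\sigma = \mathrm{FWHM}/(2\sqrt{2\ln 2})$ voxelized by the voxel
  size, kernel renormalized over in-mask neighbors so constants are
  preserved and mask edges are unbiased. `fwhm_mm = 0` is an identity.
* **Ties and p-values.** Spearman uses average ranks with the
  large-sample approximation; Kruskal–Wallis uses the tie-corrected H
  with the chi-square (2 df) approximation, appropriate at n = 10 per
  group; identical-value groups get H = 0, p = 1.
* **Threshold boundary.** `z > z_thr` is strict: a vertex exactly at
  0.05 is not connected.

## Open choices, and why

Several steps are underdetermined by the protocol wording; the package
fixes each with a documented, configurable default:

* **Seed signal aggregation**: unweighted mean over the 20 seed voxels
  (`seed_agg = "first_pc"` available).
* **Subject-level map**: across-run mean z masked at $p < 0.001$
  (values kept, non-significant voxels zeroed), preserving the
  meaning of the downstream $z > 0.05$ threshold.
* **Group averaging**: non-significant subject voxels contribute 0
  rather than being dropped, so group values are comparable across
  voxels with different significance counts.
* **Sidedness**: the t-test is two-sided; correlation under
  contrast-agent (inverted-hemodynamics) imaging is sign-symmetric
  under joint inversion, so no sign-specific step is taken.
* **Smoothing stage**: applied to z-maps (`smooth_stage = "map"`),
  with time-series smoothing available. For these linear steps the two
  stages agree in expectation; map smoothing is cheaper and bleeds
  *less* across parcel borders than data smoothing, which also shrinks
  the noise variance at borders.
* **Ipsilateral restriction**: maps cover only the seed's hemisphere;
  contralateral voxels are missing, not zero.
* **Pooled-hemisphere tests** treat the two hemispheres of one animal
  as independent observations (doubling n); the Benjamini–Hochberg
  family is all areas within one scope.
* **Preference rule**: significant in both hemispheres or pooled →
  argmax of the pooled mean ratio between anterior and posterior seed,
  called `both` when within 10% relative difference; significant in
  exactly one hemisphere → judged on the average supra-threshold z;
  otherwise `none`. The middle seed is never preferred.

## Problem sizes and validation scope

The default phantom (10 × 8 × 300 frames, ~20k voxels, ~41k vertices)
runs the full pipeline in roughly 2–3 minutes on one CPU; unit tests
use a 12×14×8-per-hemisphere, 8-area miniature (~2.7k voxels) so the
whole suite stays fast, with five full-scale replicates reserved for
the end-to-end recovery checks. The null-calibration check (an all-zero
design) verifies that the subject-level $p<0.001$ mask flags at most
0.5% of voxels outside the seeds' smoothing neighborhood.

## Known limitations

* **Border bleed bounds recovery.** The planted design has voxel-sharp
  area borders, while the protocol smooths with a 1.5 mm FWHM kernel.
  Vertices in the one-voxel shell around a loaded area genuinely
  acquire supra-threshold, t-significant z from their neighbors, so any
  faithful implementation mislabels part of that shell relative to the
  sharp ground truth; with the default 16-area geometry this puts
  vertex-category accuracy around 0.86–0.89, almost all residual error
  sitting on borders. Real parcellations have larger areas (smaller
  border fraction) and smoother true transitions.
* Rank tests on deterministic structure: with 10 animals and near-zero
  within-group variance, even tiny systematic ratio differences become
  significant; the phantom's seed-hosting area shows this (its own seed
  voxels are planted single-seed), so it is not a clean AMP probe.
* The chi-square Kruskal–Wallis p is approximate at n = 10 per group;
  an exact permutation variant is not implemented.
* No realignment, coregistration, template normalization or
  slice-timing: the phantom is generated on a common grid, so these
  protocol steps have no counterpart here and are out of scope.
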