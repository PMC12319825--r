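# vipgradient

Seed-based resting-state functional-connectivity gradient analysis of
macaque area VIP, with a synthetic phantom for end-to-end validation.

The ventral intraparietal area (VIP) lies in the fundus of the macaque
intraparietal sulcus. Splitting it into anterior, middle, and posterior
seed ROIs (20 voxels each, carved from consecutive coronal slices) and
mapping each seed's whole-hemisphere resting-state connectivity reveals
a graded antero-posterior change in connectivity profile rather than
discrete submodules. This package implements that analysis as a tested,
reusable pipeline for anyone working with seed-based connectivity in
parcellated volumes:

* **Preprocessing** — motion scrubbing by framewise displacement,
  zero-phase Butterworth band-pass (0.01–0.1 Hz), nuisance regression
  against white-matter/ventricle traces, mask-normalized Gaussian
  smoothing (1.5 mm FWHM).
* **Connectivity** — per-run Pearson correlation of each seed's mean
  signal with every ipsilateral voxel, Fisher `z = artanh(r)`,
  per-subject across-run mean with a one-sample t-test (`p < 0.001`),
  group averaging.
* **Surface & categorization** — volume-to-vertex projection, strict
  `z > 0.05` thresholding (0.03–0.07 sweep), eight-way exclusive
  overlap categories `{NONE, A, M, P, AM, MP, AP, AMP}` with additive
  RGB encoding, composition percentages per hemisphere/region, and
  Spearman similarity between whole-hemisphere maps.
* **Areal statistics** — per-area connected-vertex ratios and mean
  supra-threshold z per subject, Kruskal–Wallis comparison of the three
  seeds per area (left/right/pooled) with Benjamini–Hochberg correction
  at 0.05, and anterior-vs-posterior seed-preference classification.
* **Phantom** — a multi-subject synthetic resting-state generator that
  plants per-area loadings on three latent seed signals, carries the
  implied true category per voxel, and writes a complete NIfTI/TSV
  dataset, so the whole chain is validated against ground truth (the
  original animal data are not publicly deposited).

## Worked example

```r
library(vipgradient)

spec <- phantom_spec()          # 10 subjects x 8 runs x 300 frames, ~20k voxels
res  <- run_pipeline(spec)      # ~2.5 min on one CPU
print(res)
#> VIP gradient pipeline result
#>         stage n_records seconds
#>      simulate     20736   0.031
#>    preprocess        80  92.504
#>  connectivity        60  50.174
#>       surface     41353   1.919
#>         stats       960   1.426
#> Category recovery accuracy: 0.890
#> Spearman rho (left): a-m -0.24, m-p 0.03, a-p -0.52
#> Spearman rho (right): a-m -0.24, m-p 0.04, a-p -0.53
```

The recovery accuracy is the fraction of surface vertices whose
estimated overlap category matches the planted one; residual error sits
almost entirely in one-voxel shells at planted area borders, where the
1.5 mm smoothing kernel genuinely spreads supra-threshold signal (see
the methods vignette). The Spearman rows quantify the gradient
signature: the anterior map resembles the middle map more than the
posterior map (`rho(a,m) > rho(a,p)` in both hemispheres; the values
are computed on sparse zero-filled group maps, hence their sign).

Per-area statistics and the planted-preference check:

```r
res$areal$preference[res$areal$preference$preferred != "none", ]
head(res$areal$tests)          # H, raw and BH-adjusted p per area and scope
res$composition_hemisphere     # eight-way percentages per hemisphere
```

Acquisition bookkeeping from the packaged per-session table:

```r
s <- summarize_acquisition(example_acquisitions())
s$per_subject[s$per_subject$subject_id == "TH", "total_minutes"]  # 271.5
s$global$min_run_count                                            # 8
```

A phantom dataset can be written to disk and validated with
`write_phantom(spec, dir)` / `validate_inputs(dir)`, and
`inst/cli/vipgradient.R` exposes `simulate`, `validate`, `run`, and
`summarize` subcommands for shell use.

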