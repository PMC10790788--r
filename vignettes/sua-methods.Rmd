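---
title: "Spatial uncertainty aggregation: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial uncertainty aggregation: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(suaseg)
```

## The problem and the model

A segmentation network for tumor metastases in lymph-node whole-slide
images outputs a per-pixel softmax probability ("segmentation heatmap").
With a deep ensemble of K networks, the fused prediction is the per-pixel
arithmetic mean of the member softmax scores, and the per-pixel epistemic
uncertainty is the predictive entropy of that fused binary distribution,

$$H(\bar p) = -\bigl(\bar p \log \bar p + (1-\bar p)\log(1-\bar p)\bigr),$$

in nats, with $0\log 0 \equiv 0$. False negatives — tumor whose fused
softmax never reaches the positive threshold $t_2$ — are the clinically
expensive error: a pathologist reviewing only highlighted areas will not
revisit them.

The SUA detector assumes that *regions* of missed tumor carry a
collectively elevated uncertainty even when individual pixel entropies are
too noisy to be diagnostic. It therefore:

1. forms **negative prediction regions** (NPRs): connected components of
   pixels with $t_1 < \bar p < t_2$, both inequalities strict;
2. scores each NPR by an aggregate (mean, or 90th percentile) of its
   pixels' entropies;
3. flags an NPR as a detected FN when its aggregate is strictly above a
   threshold $\tau$ calibrated on validation slides;
4. optionally converts flagged regions to positive predictions
   ("refinement"), which only ever adds positives.

The comparison baseline applies the same strict threshold logic to each
eligible pixel's own entropy, with no spatial grouping — the direct use of
the underlying uncertainty method. Ground truth for evaluation: an NPR is
a true FN when at least 90% of its pixels are annotated tumor (inclusive
at the boundary). That convention makes region conversion nearly safe by
definition — flagged true FNs contribute almost no false-positive pixels.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `t2` | 0.95 | softmax | positive-prediction cutoff; NPR upper bound (strict) |
| `t1` | 0.55 | softmax | NPR lower bound (strict); stops regions from absorbing the confident-negative background. 0.55–0.85 are the conventional sweep values; wider intervals (lower `t1`) give larger NPRs and, empirically, better separation |
| `connectivity` | 8 | — | pixel adjacency for components (8 = diagonals count, the scikit-image `connectivity=2` convention); 4 kept for sensitivity analysis |
| `aggregation` | mean | — | mean vs 90th percentile of region entropies; both separate well, the mean marginally better |
| `beta` | 0.5 | — | F$_\beta$ calibration objective; $\beta<1$ weights precision, reflecting that falsely converted pixels are costlier than missed regions |
| `fn_fraction` | 0.9 | — | inclusive tumor-fraction defining a true FN region |
| `min_region_px` | 1 | px | drop smaller regions; raise it with `"p90"`, where single-pixel regions make the percentile degenerate |
| `tau` | calibrated | nats | detection threshold; strict `>` at detection time |

## Calibration

$\tau$ is "empirically determined on validation data": the package scans
the midpoints between consecutive sorted unique aggregated-uncertainty
values (plus one candidate below the minimum, i.e. flag-everything) and
keeps the candidate maximizing F$_{0.5}$ of the induced classification,
breaking ties toward the larger $\tau$ (higher precision). A property test
checks the scan against an exhaustive enumeration of every
threshold-induced flag set. The baseline's pixel threshold is calibrated
by the same scan against pixel-level truth (eligible pixel = tumor), which
the source method leaves unspecified; symmetry keeps the comparison fair.

## What the synthetic generator emulates

`generate_scene()` builds the statistical situation the detector assumes,
not histology: elliptical blobs with a 2-pixel gap (so blobs never merge
under 8-connectivity) on a confident-negative background
($\bar p \approx 0.05$), in three roles:

* **detected tumor** — fused softmax above $t_2$ (guaranteed by
  construction), ground-truth tumor;
* **FN candidate** — ground-truth tumor, fused softmax inside
  $(t_1, t_2)$, region entropy targeted at
  `base_entropy + delta * shift`;
* **TN distractor** — tumor-free, fused softmax inside $(t_1, t_2)$,
  region entropy targeted at `base_entropy`.

Because the aggregated quantity is the entropy *of the fused mean*,
ensemble disagreement per se cannot move it: entropy targets are realized
by placing the fused softmax at $H^{-1}(e)$ on the upper branch
($p \ge 0.5$). Member maps get zero-centered per-blob offsets
(disagreement realism that leaves the fused mean on target) plus i.i.d.
pixel noise, and are clipped per role so the construction guarantees hold
exactly.

Chosen-once defaults, and why:

* `base_entropy = 0.42` nats ($\bar p \approx 0.83$): an in-range but
  fairly confident negative region, the typical benign distractor.
* `delta = 0.24` nats: FN candidates sit near 0.66 nats
  ($\bar p \approx 0.62$) — clearly uncertain, still below the
  $\log 2 \approx 0.693$ ceiling.
* `blob_entropy_sd = 0.05` nats between blobs: regions differ, so the
  FN/TN gap is clear but not degenerate, and threshold transfer under
  domain shift is meaningfully stressed.
* `pixel_jitter_sd = 0.06` softmax within blobs: single-pixel entropy
  becomes a noisy signal that regional aggregation denoises — the effect
  the method exists to exploit. (Near $\bar p = 0.83$ the entropy slope
  is steep, so distractor pixel entropies spread by ~0.1 nats and overlap
  the FN range; the baseline suffers, region means do not.)
* `k_members = 5`, `member_spread_sd = 0.03`, `noise_sd = 0.01`: a
  typical small deep ensemble with mild disagreement.
* `background_npr_rate = 4` (Poisson): a handful of benign in-range
  regions per slide.
* `shift` multiplies `delta` only: domain shift is modeled as the FN
  signal degrading toward the benign level, leaving distractors where
  they were.

What it does **not** emulate: H&E texture and stain variation, WSI
pyramids and magnification, annotation noise, spatially correlated
ensemble errors, tumors lying wholly outside any NPR, and FP-dominated
failure modes. A green synthetic test therefore establishes that the
machinery recovers planted separation and reproduces the qualitative
SUA-above-baseline orderings (in-domain and under shift) — not that any
particular clinical performance level would be reached on real slides;
the headline numbers on Camelyon/Sentinel-scale data require those data
and trained ensembles and are out of scope here.

## Numerical and convention choices

* **Log base**: natural log. The entropy base is unstated in the source
  convention; the choice only rescales $\tau$, which is calibrated on the
  same scale. All entropies in this package are nats, bounded by
  $\log 2$.
* **Strict inequalities everywhere they are written strictly**: NPR
  membership ($>t_1$, $<t_2$) and detection ($>\tau$); boundary-equal
  pixels/regions are excluded. FN truth is inclusive ($\ge 90\%$).
* **Positive prediction** is $\bar p \ge t_2$ (the complement of "below
  the cutoff").
* **Percentile**: linear interpolation between order statistics
  (R `quantile` type 7); the convention is unstated in the source and
  recorded here.
* **Label determinism**: component ids are assigned in raster-scan
  (row-major) first-occurrence order.
* **Refined pixels get probability 1.0**: any value $\ge t_2$ is
  equivalent for binary metrics; 1.0 makes updates visible in exported
  heatmaps and feeds the FROC scorer as a maximal-confidence detection
  (recorded as a convention, configurable in principle).
* **Dice of two empty masks = 1.0** (a slide with no tumor and no
  prediction is perfectly segmented).
* **FNCR is pooled** across slides (sum of numerators over sum of
  denominators), not averaged per slide.
* **FROC** follows the standard lesion-level protocol: lesions are
  connected components of the truth mask; a detection (one local-maximum
  coordinate + confidence per positive component) hits a lesion if it
  falls inside it; the score is mean sensitivity at
  {0.25, 0.5, 1, 2, 4, 8} average FPs per slide, linearly interpolated
  and clamped at the curve ends.
* **Slide-level score** for ROC-AUC: maximum (refined) pixel
  probability, with midrank tie handling.
* **Bootstrap** resamples whole slides with replacement (the unit of
  replication in all reported tables), default 1000 iterations, seed
  recorded in every report.
* **Degenerate inputs error loudly**: empty ensembles, shape mismatches,
  probabilities outside [0, 1], single-class calibration sets, FNCR with
  no updated pixels, FROC with no lesions, AUC with one class.

## Open design points, resolved

* The two wordings of FN truth ("≥90% missed tumor pixels" vs "≥90%
  overlap with the tumor annotation") are treated as the same rule:
  `tumor_fraction >= 0.9`.
* The baseline's F$_\beta$ is computed over pixels (no grouping), the
  plain reading of "pixels treated independently".
* Heatmaps are processed at the supplied resolution; no pyramid handling.
* Storage uses plain-text CSV rasters (17 significant digits, bit-exact
  round trips) with a JSON sidecar instead of TIFF/PNG, and JSON run
  configs instead of YAML: the guaranteed offline R stack has no TIFF
  reader, and text artifacts keep fixtures reviewable.

## Known limitations

* Connected-component labeling is pure R (vectorized union–find); fine up
  to a few megapixels per map, not tuned for gigapixel rasters.
* Only entropy-of-the-mean is computed in-package; other uncertainty
  estimators (MC dropout, test-time augmentation) can be supplied as a
  precomputed `UncertaintyMap` but are not generated here.
* Refinement never removes false positives, and tumors entirely outside
  all NPRs are undetectable by construction — both are outside the
  method's scope.
* With `aggregation = "p90"` and `min_region_px = 1`, single-pixel
  regions make the percentile equal the pixel value; raise
  `min_region_px` for percentile runs.
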