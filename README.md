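# suaseg — spatial uncertainty aggregation for segmentation heatmaps

Deep-learning tumor segmentation of whole-slide images (WSIs) in digital
pathology produces a per-pixel softmax **segmentation heatmap**, and a deep
ensemble additionally yields a per-pixel **uncertainty heatmap** — the
predictive entropy of the ensemble-mean prediction. A recurring failure
mode is the **false negative (FN)**: a tumor area whose softmax stays below
the positive threshold, so the pathologist is never pointed at it.

`suaseg` implements a spatial uncertainty aggregation (SUA) post-processing
pipeline for detecting such FN regions, for researchers working on
uncertainty quantification in computational pathology:

1. **Fusion / uncertainty** — fuse K ensemble members by per-pixel
   averaging, p̄ = (1/K) Σₖ pₖ, and compute the binary predictive entropy
   H = −(p̄ log p̄ + (1−p̄) log(1−p̄)) in nats.
2. **Negative prediction regions (NPRs)** — connected components
   (8-neighbor by default) of pixels with t₁ < p̄ < t₂, both strict; t₂ is
   the positive cutoff (0.95 by convention), t₁ ∈ {0.55, …, 0.85} bounds
   region growth into the confident background.
3. **SUA detection** — aggregate the entropies of each NPR (mean or 90th
   percentile) and flag the region as a detected FN when the aggregate
   exceeds a threshold τ calibrated on validation slides by maximizing
   F(β=0.5) = (1+β²)·precision·recall / (β²·precision + recall).
   A *pixel-independent baseline* thresholds each eligible pixel's own
   entropy instead.
4. **Refinement** — convert detected FN regions (or flagged pixels) to
   positive predictions; refinement only ever adds positives.
5. **Evaluation** — Fβ, Dice = 2TP/(2TP+FP+FN), the false negative
   conversion rate FNCR = Σᵢ N⁺ᵢ / Σᵢ N^totalᵢ (pooled fraction of updated
   pixels that are truly tumor), lesion-level FROC, slide-level ROC-AUC,
   and a slide-resampling bootstrap (mean/SD over 1000 resamples).
6. **Synthetic scenes** — a generator that plants detected-tumor blobs,
   FN candidates (≥90% tumor, elevated fused entropy) and tumor-free
   distractors, with a separation parameter `delta` and a domain-shift
   knob `shift` that shrinks it, so the entire pipeline is testable
   without any WSI data.

A ground-truth FN region is an NPR with ≥ 90% tumor pixels (inclusive).

## Worked example

Calibrate on four synthetic validation slides, evaluate on six test
slides:

```r
library(suaseg)
cfg  <- threshold_config(t1 = 0.55, t2 = 0.95, aggregation = "mean")
val  <- lapply(1:4,   function(s) generate_scene(scene_spec(seed = s)))
test <- lapply(11:16, function(s) generate_scene(scene_spec(seed = s)))
exp  <- run_fn_experiment(val, test, cfg, n_boot = 1000, seed = 42)
print(exp)
#> <sua_experiment>
#>   tau (region) = 0.5330, tau (pixel) = 0.5957
#>   SUA      F_beta = 0.9574  FNCR = 0.9232  Dice = 0.9827
#>   baseline F_beta = 0.9320  FNCR = 0.9443  Dice = 0.9577
#>   Dice (original) = 0.6587
print(exp$bootstrap$sua_f_beta)
#> <evaluation_report> point 0.9574, bootstrap 0.9593 (0.0369), n_boot=1000, seed=42
```

Reading this: the calibrated region threshold τ = 0.533 nats separates
FN-candidate NPRs (entropy ≈ 0.66) from distractors (≈ 0.42); region-level
aggregation beats the per-pixel baseline (Fβ 0.957 vs 0.932); converting
detected regions lifts the mean Dice from 0.659 to 0.983 while 92% of the
converted pixels were genuinely tumor (FNCR). Per-region records are plain
`data.table`s:

```r
a <- analyze_slide(test[[1]], cfg)
head(detect_fn(a$records, exp$calibration$region$tau), 4)
#>    slide_id region_id n_pixels agg_uncertainty tumor_fraction is_fn_truth is_fn_predicted
#> 1:  test_11         1       53       0.3791683              0       FALSE           FALSE
#> 2:  test_11         2       92       0.4585556              0       FALSE           FALSE
#> 3:  test_11         3       63       0.6797540              1        TRUE            TRUE
#> 4:  test_11         4       71       0.6805701              1        TRUE            TRUE
```

## Command line

```sh
Rscript inst/scripts/suaseg synth --out fixtures --n-slides 6 --seed 1
Rscript inst/scripts/suaseg run   --config config.json --mode both
```

`run` composes the whole pipeline from a JSON config (`input_dir`,
`output_dir`, thresholds, `mode` ∈ {sua, baseline, both}, `n_boot`,
`seed`, …) and writes region CSVs, calibration JSON, refined heatmaps and
a metric report, each stamped with the config hash; `extract`,
`calibrate`, `detect`, `refine` and `evaluate` run the individual stages.
Without ground truth, `run` needs a fixed `tau` and marks truth-dependent
metrics unavailable.

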