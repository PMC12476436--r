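# panodent

Post-processing of raw tooth instance-segmentation output from panoramic
dental radiographs, rule-based **Kennedy classification** of partially
edentulous jaws, and the evaluation protocol to score both — plus a seeded
synthetic detection generator so everything runs and is tested without
clinical data or a trained network.

## What it does

Instance-segmentation detectors emit per image a list of tooth candidates
(FDI position label, confidence score *s* ∈ [0, 1], binary mask). The raw
list contains duplicates, misses, spurious teeth, and confused labels.
`panodent` implements the downstream dentition analysis:

1. **Post-processing** — a single greedy pass in order of decreasing score.
   A candidate is discarded by the first enabled filter that rejects it:
   * score filter: *s* < 0.5;
   * duplicate-label filter: its FDI position is already occupied by a
     selected instance (each position exists at most once);
   * geometric filter: the novel-pixel fraction
     |M \ U| / |M| < 0.5, where M is the candidate mask and U the union of
     previously selected masks.
2. **Kennedy classification** per jaw from the surviving labels, rules in
   priority order (wisdom teeth ignored throughout): both second molars
   absent → **I**; exactly one absent → **II**; both present, both central
   incisors absent and the absences among indices 1–7 contiguous in arc
   order → **IV**; any other index-1–7 absence → **III**; else **FULL**.
3. **Evaluation** — greedy one-to-one matching of predictions to reference
   masks at IoU ≥ 1/3 (Dice ≥ 1/2); 33×33 tooth confusion matrix (32 FDI
   positions + FP row + FN column); 5×5 Kennedy confusion matrix;
   sensitivity TP/(TP+FN), precision TP/(TP+FP), F1, label accuracy,
   position-level specificity; an ablation harness over the filter stages.

I/O is COCO-style instance JSON (RLE or polygon masks); FDI codes are
category names. A thin CLI (`inst/cli/panodent`) exposes
`simulate / postprocess / classify / evaluate / ablate / run`.

## Worked example

```r
library(panodent)

# 100 synthetic images under the default detector-noise model
corpus <- simulate_corpus(100, noise = noise_config(seed = 3))
out <- run_pipeline(corpus$detections, corpus$references)
out$report
#> Evaluation of 100 images (200 jaws)
#>   detections: TP 2039, FP 10, FN 131 (mislabeled 65)
#>   sensitivity 94.0%  precision 99.5%  F1 96.7%  specificity 99.0%
#>   label accuracy 96.8%
#>   Kennedy accuracy 85.5% (upper 85.0%, lower 86.0%)
```

Reading the numbers: of the 2,170 reference teeth, 131 were missed
(sensitivity 94.0%) — the configured miss rate plus mislabeled molars that
the duplicate-label filter suppressed; 10 spurious detections survived
(precision 99.5%); 65 matched teeth carry a confused label
(label accuracy 96.8%), and those confusions propagate into the 14.5% of
jaws whose Kennedy class is wrong. With zero noise
(`noise_config_zero()`), the pipeline recovers every jaw class exactly:

```r
clean <- simulate_corpus(40, noise = noise_config_zero(83))
run_pipeline(clean$detections, clean$references)$report$kennedy$accuracy
#> [1] 1
```

The vignette (`vignettes/dentition-pipeline.Rmd`) documents the filter
semantics, the rule cascade, the metric definitions, and the generator's
calibration in detail.

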