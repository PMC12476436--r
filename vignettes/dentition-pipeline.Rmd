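---
title: "From raw tooth detections to Kennedy classes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From raw tooth detections to Kennedy classes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panodent)
```

## The problem

Instance-segmentation detectors (Mask R-CNN and relatives) applied to
panoramic dental radiographs emit, per image, a list of tooth candidates:
a bounding box, an FDI position label, a confidence score in 0..1, and a
binary segmentation mask. The raw list is noisy in characteristic ways:
the same region proposal can be emitted several times with an identical
mask but different class labels; different proposals can converge on
strongly overlapping masks of one tooth; teeth are occasionally missed
or hallucinated; and morphologically similar teeth — above all first,
second and third molars — get confused labels.

`panodent` implements everything downstream of such a detector:
cleaning the raw list into a duplicate-free dentition estimate,
classifying each jaw's pattern of tooth loss according to Kennedy, and
evaluating both stages against reference annotations. A seeded synthetic
generator reproduces the error modes above so the whole pipeline is
testable without any clinical images or a trained network.

## Post-processing: three filters, one greedy pass

Candidates are visited once, in order of decreasing score. Each is
discarded by the first enabled filter that rejects it, otherwise
selected:

1. **Score filter.** Discard if `score < 0.5`. The threshold means the
   winning position's score exceeds all alternatives combined; the
   performance surface around it is flat, so the exact value is not
   critical.
2. **Duplicate-label filter.** Discard if the candidate's FDI position is
   already occupied by a previously *selected* (hence higher-scoring)
   instance. Each position exists at most once in a dentition, which is
   what makes this class-aware suppression valid. It relies on predicted
   labels, so mislabels can trigger erroneous suppression.
3. **Geometric filter.** Compute the fraction of the candidate's mask
   pixels not covered by the union of previously *selected* masks; discard
   if this novel-pixel fraction is below 0.5. Correct neighboring teeth
   overlap by a few percent, duplicate proposals by nearly all of their
   pixels, so the cut separates the two regimes with a wide margin.

Three conventions are fixed for determinism, since any choice is
defensible at the exact boundary: a score exactly at the threshold
survives, a novel fraction exactly at the threshold survives, and score
ties are broken by ascending FDI code then input order. Discarded
instances occupy nothing — neither a label slot nor pixels — which is the
only reading consistent with suppression "by previously selected
instances", and it produces the documented filter interaction: removing a
geometric duplicate can let a later instance with the same label survive
when the duplicate-label filter is ablated, and vice versa. When the
geometric filter is off, ablating the duplicate-label filter changes
multiplicities but never the *set* of surviving labels — so it cannot
change any downstream jaw classification. That invariance is tested
corpus-wide.

The production pass is checked against a deliberately naive brute-force
restatement of these rules (full-frame matrices, no occupancy caching) on
1,000 random small fixtures, and is idempotent and monotone in the score
threshold by property test.

## Kennedy classification as a rule cascade

Each jaw's presence map (16 booleans; implants, pontics and root residues
count as absent) passes through rules in fixed priority:

1. both second molars absent → **I** (bilateral free-end);
2. exactly one second molar absent → **II** (unilateral free-end);
3. both second molars present, both central incisors absent, and the
   absent positions among indices 1–7 form one contiguous run in
   anatomical arc order → **IV** (anterior gap across the midline);
4. otherwise any position of index 1–7 absent → **III** (bounded gap);
5. otherwise → **FULL**.

Wisdom teeth (index 8) are invisible to every rule. The package treats
all 32 positions as detectable and applies the wisdom exclusion only
inside the rules, since third molars do occur in real dentitions and
should be detected even though they never influence the class.

Two operationalizations deserve comment. *"Remaining rows closed"* in
rule 3 is read as: the absent inner positions form exactly one maximal
contiguous run, and that run contains both central incisors — this
matches the textbook picture of class IV as a single anterior gap while
permitting gaps wider than the two centrals. And the priority order is
strict: a jaw missing 47 as well as both lower centrals is II, not IV.
A jaw with no abutment teeth at all among indices 1–7 is classified I and
flagged as fully edentulous in the consistency report — such jaws fall
outside Kennedy's partially-edentulous scope, and the flag lets callers
exclude them.

The rule engine is exhaustively enumerated over all 65,536 presence
patterns per jaw in the test suite: totality, mirror symmetry (arc
reversal), wisdom-toggle invariance, and consistency of every class with
its defining condition are asserted pattern by pattern.

## Evaluation protocol

Predictions are matched one-to-one to reference teeth greedily by
decreasing mask IoU, keeping pairs with IoU ≥ 1/3 (Dice ≥ 1/2). Greedy
rather than optimal bipartite assignment is used because observed
candidate IoUs are strongly bimodal — overlaps sit far below 10% or far
above 60% — which makes the two equivalent in practice while greedy is
simple enough to oracle-test; the report carries the IoU histogram of all
candidate pairs so the bimodality can be verified on any corpus. Ties are
broken by reference label then prediction index. Implants never count as
reference teeth: a prediction covering only an implant region is a false
positive.

From the matching follow the 33×33 tooth confusion matrix (32 positions
plus a false-positive row and a false-negative column, with a
row-normalized variant), and the scalar rates, defined once in
`rates_from_counts()`: sensitivity TP/(TP+FN), precision TP/(TP+FP),
F1 = 2TP/(2TP+FP+FN), label accuracy = correctly labeled matches / TP.
Matched-but-mislabeled predictions are TP for detection and errors only
for label accuracy. Detection has no natural true negatives; the
position-level definition adopted here counts absent FDI positions
(32 per image minus reference teeth) not consumed by a false positive:
specificity = TN/(TN+FP) with TN = absent − FP. Zero denominators yield
`NA`, never 0. Jaw classification is summarized in a 5×5 confusion matrix
over {I, II, III, IV, FULL} with overall and per-jaw accuracy, and
`ablation_run()` re-evaluates one corpus under any set of filter
configurations.

Exact bookkeeping is enforced: TP+FN equals the reference tooth count,
TP+FP the prediction count, correct+mislabeled equals TP.

## The synthetic generator

`generate_reference()` samples dentitions and renders masks;
`corrupt_to_detections()` applies the detector noise model. Defaults
describe a partially edentulous adult study population:

* **Presence priors** by tooth index, identical across quadrants:
  0.78, 0.75, 0.914, 0.72, 0.70, 0.68, 0.66, 0.205 for indices 1–8. The
  three anchors — canine prevalence 91.4%, wisdom prevalence 20.5%, and
  an overall missing rate of 32.4% — pin the landscape; the remaining six
  values interpolate smoothly between them. Absent positions carry an
  implant with probability 0.10.
* **Scene geometry.** Each jaw's 16 positions sit at equal pitch along a
  shallow parabolic arc on a 640×320 grid; teeth are axis-aligned
  ellipses with class-dependent widths (molars widest) and ±4% size
  jitter. The widths are chosen once from the arc pitch so adjacent masks
  overlap by roughly 1–9% of the smaller mask — non-zero, as tooth masks
  genuinely overlap in panoramic projections, but far below the 50%
  novel-fraction cut, so correct detections always survive the geometric
  filter. Realism beyond this overlap topology is a non-goal: no
  radiographic texture, no roots, no superimposed anatomy.
* **Noise rates**: misses with `p_miss = 0.03`; spurious detections at
  0.4 per image placed in edentulous gaps or over implants; duplicate
  proposals at rate 0.15, split evenly between the same-mask mode
  (identical mask, different class) and the shifted-mask mode (strongly
  overlapping mask, same class); label confusion per index of
  0.03/0.03/0.01/0.04/0.04/0.08/0.08/0.08 — lightest for the
  morphologically unique canine, heaviest among the mutually similar
  molars — always targeting an adjacent index of the same group within
  the quadrant. Scores are Beta(9, 2) for correct and Beta(3, 4) for
  erroneous instances, overlapping so the 0.5 threshold is genuinely
  exercised. These rates correspond to the error landscape reported for
  Mask R-CNN-class detectors on panoramic radiographs: missing a tooth is
  somewhat more likely than inventing one, and label confusion is the
  dominant error.
* Expert Kennedy classes of generated references are produced by the rule
  engine itself, so `validate_reference_consistency()` agrees 100% by
  construction — mirroring the consistency verification clinical studies
  perform between manually assigned classes and rule output.

Identical seeds yield byte-identical corpora; per-image corruption seeds
derive deterministically from the corpus seed and image id.

**What passing tests do and do not show.** The generator reproduces the
overlap topology and the error *modes* of real detector output, not its
appearance or its spatial failure correlations (e.g. collapse in a
blurry premolar region affecting several neighbors at once). Green
rate-recovery tests demonstrate that the pipeline measures what the
generator injects; they say nothing about detector quality on clinical
images.

## Problem sizes and calibration checks

The test suite verifies the scalar metric formulas against the printed
integer counts of a 209-image clinical evaluation (4,516 reference teeth,
130 FN, 83 FP, 4,156 of 4,388 matches correctly labeled, 347 of 418 jaws
correct), recovering each published rate to one decimal. Property suites
use: all 65,536 presence patterns for the rule engine; 1,000 random
fixtures of up to 8 detections for the oracle-equivalence check; a
200-image corpus for the corpus-wide label-set invariance; a 40-image
noiseless corpus for exact class recovery; and a 500-image noisy corpus
for rate recovery within 95% sampling intervals. For the rate-recovery
check, duplicate injection is disabled and rates are measured on the raw
detections: the duplicate-label filter converts label collisions into
extra misses and one-to-one matching converts duplicates into false
positives, so measuring after filtering would conflate the configured
rates — the isolation makes the binomial comparison exact.

## Known limitations

* The class-IV "closed rows" reading rejects jaws with an anterior gap
  plus any second, separated gap (those become III); clinical usage
  varies here and no modification spaces (Kennedy–Applegate) are
  implemented.
* Specificity is a derived, position-level quantity; comparisons against
  evaluations using a different TN convention are not meaningful.
* Masks are treated purely as pixel sets: no boundary-quality metric is
  computed, and segmentation accuracy beyond the IoU matching threshold
  is out of scope.
* The generator does not emulate fully edentulous jaws, deciduous
  dentition, orthodontic hardware, or cross-image (patient-level)
  correlation.
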