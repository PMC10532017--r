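---
title: "Slice selection, patient-wise partitioning and detection metrics: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Slice selection, patient-wise partitioning and detection metrics: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lesionprep)
```

## The annotation model and its noise source

The cohorts this package targets annotate one lesion per patient as a *3D
bounding box*: a single 2D rectangle (row/column bounds) plus an inclusive
slice range. The rectangle is tight around the lesion's largest
cross-section, and the identical rectangle is asserted on every slice of the
range. Near the range extremities the lesion cross-section has shrunk, so
the box there is mostly background — a systematic source of label noise for
any detector trained on per-slice boxes. The package's central operation
removes those edge slices.

Assumptions inherited from the annotation scheme: exactly one annotated
lesion per patient; all slices of a patient share one square size (320, 448
or 512 px); annotations are only valid on fat-suppressed series; slices are
ordered by instance number within a series.

## The funneling selection

For a tumor spanning $n$ slices the kept count is
$\mathrm{keep}(n) = \lceil n \cdot a \ln b \rceil$ with defaults $a = 0.75$,
$b = 1.9625$, giving an asymptotic keep fraction $a\ln b \approx 0.5057$.
The removal total $R = n - \mathrm{keep}(n)$ is split
$\lfloor R/2 \rfloor$ from the start of the range and $\lceil R/2 \rceil$
from the end. Consequences the test suite verifies exhaustively for
$n \in [1, 10^4]$: conservation ($\mathrm{keep} + R = n$), monotonicity of
both counts in $n$, an end-minus-start removal difference of 0 or 1, and
convergence of $\mathrm{keep}(n)/n$ to $a\ln b$ within $10^{-3}$ at
$n = 10^4$.

$a$ and $b$ are dimensionless tuning constants, not fitted quantities; both
are exposed as parameters (`funnel_params()`) with the defaults above. The
constructor rejects $a \ln b > 1$ (a keep fraction above 1 is meaningless)
and $b \le 1$. $n = 1$ is accepted and keeps the single slice, although
annotated tumors in the source data always span at least 2.

Selection is *count-based only*: no pixel-area criterion decides which
slices go. On the package's phantoms, where cross-section areas are known,
the tests confirm the rank agreement this implies — every removed slice has
a cross-section no larger than every kept slice — but on real data the
symmetric trim is a geometric approximation, not a guarantee.

The selection applies to training patients only. Test patients keep every
slice of their annotated series, so a detector is evaluated on the whole
stack; the pipeline (not the selection function) enforces this split of
responsibilities.

## Coordinate conventions and the export path

Internally all boxes are 0-based, half-open (`max` is one past the last
lesion pixel), which makes widths subtraction and rescaling linear. The two
external dialects are converted exactly once each, at the I/O boundary:

- annotation tables are read as 1-based inclusive (the clinical convention);
- Pascal VOC XML is written 1-based inclusive with x = column, y = row:
  `xmin = col_min + 1`, `xmax = col_max` (a half-open max equals an
  inclusive 1-based max).

Resolution normalization (default target 448 px) resizes pixels bilinearly
and rescales box coordinates by `target/original`, rounding halves away
from zero and clamping to the frame. If rounding collapses a side (possible
only under extreme downscaling), the box is widened to 1 px with a warning
rather than silently dropped. Round-tripping a box through a 320→448→320
rescale moves each coordinate at most 1 px, which the tests assert on random
boxes.

Training export includes only the *kept tumor slices* of training patients —
the detector learns from boxed examples, and non-tumor slices of training
patients carry no usable label. Test export includes every slice of the
annotated series, with object-free annotation files on non-tumor slices.

## Patient-wise partitioning

All splitting is by patient, never by image, since same-patient slices are
strongly correlated and would leak. The k-fold plan shuffles patients,
deals the first $k\lfloor n/k \rfloor$ into $k$ equal folds and marks the
$n \bmod k$ leftovers as remainder patients that join *every* training set
and are never tested: for 922 patients and $k = 10$, ten test folds of 92
and training sets of $922 - 92 = 830$ with 2 ever-training patients. (The
alternative reading of the described protocol, 829-patient training sets,
is inconsistent with the fold arithmetic, so the package follows the
arithmetic.) Shuffles are uniform permutations under a recorded seed; the
plan file stores the seed in a header comment so any plan can be
regenerated.

## Detection metrics

Per annotated slice, the matched detection is the one with maximal IoU
against the ground-truth box; ties go to the higher score, then input
order. Slices with no overlapping detection contribute IoU 0 and count as
false-negative slices. A patient is a true positive iff some annotated
slice has IoU strictly above the threshold (default 0 — any overlap); this
mirrors the `IoU > 0` stratification of the metric tables and is exposed as
`tp_threshold` for stricter regimes.

Cohort metrics come in two variants: `all` averages over every patient with
false-negative patients contributing zeros; `pos` (`IoU > 0`) restricts to
true-positive patients, and within a patient to positively overlapping
slices for the per-slice averages. By construction `pos >= all` for every
IoU metric. Two points were genuinely open and are resolved as follows:
"average score" averages *matched-slice* scores (a score is only meaningful
relative to the box it accompanies), and false-negative *slice* counts are
tallied over annotated slices only — detections on unannotated slices are
unverifiable, so they are excluded from all averages and reported only as
an informational false-positive slice tally.

Cross-fold aggregation reports the arithmetic mean and the *sample*
standard deviation ($n-1$ denominator); on the reference fold accuracies
the $n$-denominator variant gives 2.30 rather than the published 2.43, and
the test suite pins the $n-1$ behaviour.

Accuracy is a percentage; all other IoU/score metrics are kept as fractions
in $[0,1]$ and formatted as percentages only for display.

## Training-schedule arithmetic

`epochs() = steps × batch / train_images` (reported rounded to nearest);
cosine decay `lr(s) = lr₀ (1 + cos(πs/S))/2` with no warmup, matching a
schedule that starts at 0.05 and reaches 0 at the final step; and the
uniform init half-width `sqrt(3/n)` for fan-in `n`, the scaling that gives
weight variance `1/n` (the published formula for this limit is typeset
ambiguously; `sqrt(3/n)` is the standard rule the surrounding description
of a symmetric uniform initializer implies). Augmentation follows the
published transform set: 50% horizontal flip, 50% vertical flip, 50%
90° rotation, brightness delta up to 0.05, contrast multiplier in
[0.5, 0.95] applied to the deviation from the image mean. Geometric
transforms move boxes with the image; the tests verify box/raster agreement,
area preservation and flip involution.

## The phantom generator

`phantom_spec()` defaults encode the target cohort's structure:

| parameter | default | rationale |
|---|---|---|
| image sizes | 320/448/512 px, weights 33/261/628 | observed case counts per size |
| tumor slice count | empirical table, support 2–131 | the cohort's published distribution |
| series per patient | 5–6, one annotated (always fat-suppressed) | acquisition protocol |
| in-plane semi-axes | uniform 8–40 px (capped at size/4) | desk-scale lesions spanning small to large |
| margins | 2–6 non-tumor slices per side | keeps stacks compact |
| intensities | background 0.2, lesion 0.9, noise sd 0.05 | geometry-driven testing, not MRI physics |

Lesions are superellipsoids: the in-plane cross-section is a superellipse
with exponent 4, whose area fills ≈ 93% of its tight bounding box (a plain
ellipse fills only π/4 ≈ 79%, too loose to represent a radiologist's tight
central box); along the stack the in-plane semi-axes scale by
$\sqrt{1-(d/a_s)^2}$ with $a_s = (n-1)/2 + 0.5$, so the cross-section is
maximal centrally, shrinks monotonically toward the range ends, and the
end slices fill well under half the box — reproducing the loose-box
geometry the funneling rule exists to remove. The annotation box is the
exact tight box of the central cross-section on the integer pixel grid,
computed analytically.

What the phantom does *not* emulate: breast anatomy, contrast kinetics,
scanner intensity profiles, multi-lesion cases, or annotation error. Tests
passing on phantoms therefore validate the *bookkeeping and arithmetic* of
the pipeline — selection counts, coordinate transforms, leakage-free
partitioning, metric algebra — not detector performance on clinical data,
and the headline detector metrics of any real model are out of reach
without training one.

The synthetic detector (`detector_model()`) emits, per tumor slice, the
ground-truth box with Gaussian corner jitter and a clipped-Gaussian score,
with a per-slice detection probability and a per-patient complete-miss
probability `miss_rate`. The latter makes patient-wise accuracy directly
calibratable: with miss probability $q$, recovered accuracy is
$100(1-q)$ within binomial error, which the tests check by pooling 20
seeded replicates of a 40-patient cohort.

## Cohort I/O backend

Cohorts are read from a flat annotation CSV, a series-metadata CSV
(scan-options text, slice counts, image size) and per-series PNG stacks
named by instance number — the dialect the phantom generator writes.
Fat-suppression is detected by a word-bounded, case-insensitive `FS` token
match on the scan-options text, overridable by regex, and series ordering
sorts instance numbers with filename tie-breaks. Series whose pixel data
are not materialized (any non-annotated series of a phantom) participate in
metadata-dependent stages — filtering, counting, planning — and error out
only if pixel export is actually requested.

## Determinism and problem sizes

Every stochastic step (shuffles, phantom sampling, detector draws,
augmentation) is a pure function of an explicit integer seed, and the RNG
state of the caller is restored afterwards. Fixed seed, fixed output: the
tests assert byte-identical annotation CSVs and identical manifests across
repeated runs.

The suite exercises full-scale arithmetic where it is cheap (funnel
properties to $n = 10^4$; 922-patient fold plans) and small cohorts where
pixels are involved (5–13 patients with slice counts capped at ~12 for
image-writing tests, 40 patients metadata-only for the miss-rate
calibration, 1000 patients for the slice-count distribution check). These
sizes are the package's own test design: large enough for every property to
bind, small enough that the whole suite runs in well under a minute.

## Known limitations

- One annotation per patient; multi-lesion cohorts need a schema extension.
- Slice selection is purely count-based and symmetric; a lesion whose
  largest cross-section sits off-center in its slice range will lose
  slightly more good slices on one side.
- The DICOM origin of real cohorts is abstracted behind the PNG/CSV
  dialect; converting a DICOM series into it (pixel extraction, scan
  options, instance numbers) is left to upstream tooling.
- Precision/recall and AP curves are deliberately absent: without
  exhaustive annotation, false positives on unannotated slices cannot be
  validated, so only patient-wise detection metrics are reported.
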