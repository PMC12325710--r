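---
title: "Continuous blur-scanning of TMA slides: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Continuous blur-scanning of TMA slides: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(her2scan)
```

## The problem

Conventional whole-slide scanners stop the stage for every exposure
("stop-and-stare"). A cheaper and faster alternative keeps the stage moving
continuously while a camera records video, accepting motion blur in exchange
for throughput. This package simulates and analyses that acquisition mode end
to end for HER2-stained tissue microarrays (TMAs): it generates synthetic
slides with score-graded membrane staining, simulates the zigzag blur scan,
stitches the frame stream back into a whole-slide mosaic, crops and labels
the tissue cores, classifies each core's HER2 score (0, 1+, 2+, 3+) with a
Fourier-domain network, and aggregates repeat-scan predictions under
confidence-based schemes.

## Motion-blur model

With the stage moving at speed $s_x$ and a camera exposure $T$, the recorded
frame is the crisp image convolved along the scan direction with a 1-D
rectangular kernel whose support is the blur distance

$$w = s_x T,$$

normalized to unit sum. At the default operating point
($s_x = 5000\ \mu m/s$, $T = 7.8$ ms) the blur width is $39\ \mu m$.
Key numerical choices:

* **Discretization.** `width_px = round(w / pixel_size_um)`, floored at 1;
  sub-pixel remainders are ignored because the physical model specifies only
  the kernel support.
* **One-sided kernel.** The exposure integrates content swept *ahead* of the
  pixel in the scan direction, so the kernel is causal: `+x` rows average
  columns $x..x+w-1$, `-x` rows the mirror. Opposite rows therefore produce
  mirror-image smears — the tell-tale alternating blur of a zigzag scan.
* **Boundaries.** Replicate-edge padding. Frames are windows of a larger
  slide, so `simulate_scan()` blurs the padded slide first and cuts windows
  afterwards; frame edges then carry true neighboring content. Mean
  intensity is conserved exactly when the slide carries uniform background
  bands at least one kernel width wide at its lateral edges (always true for
  slides with margins); for arbitrary images the replicate edge biases the
  mean slightly, which is why the conservation property is stated for the
  scanning regime.
* **Exposure model.** The frame is modeled as an instantaneous window of the
  pre-blurred slide rather than a sub-frame time integral — mathematically
  identical for constant stage speed.

Throughput follows from the sweep geometry: each second the stage uncovers
$(s_x + \text{fov}_w) \times \text{fov}_h$ of area, i.e.
$(5000 + 640) \times 480\ \mu m^2/s = 2.7072\ mm^2/s$ at the defaults.

## Zigzag schedule

`plan_zigzag()` brackets each scan line with `pause_s` of static frames
(0.5 s = 15 frames at 30 fps on each side, so 30 static frames sit between
consecutive lines), advances $s_x/\mathrm{fps}$ per moving frame, and
alternates direction row to row. The stage dwells one frame-advance before
the line origin (a lead-in), so the first moving frame already covers
$x = 0$ and the union of moving-frame footprints covers the slide. The
vertical jump between lines is absorbed into the static runs rather than
modeled as a third state; it shows up as a single decorrelated frame pair
that the square-wave fit corrects. Row step defaults to 80% of the frame
height, i.e. 20% vertical overlap between rows. Optional stage ringing is
modeled as sinusoidal jitter $\delta_x(t), \delta_y(t)$ with seed-derived
phases; amplitudes default to zero, making the simulation deterministic.

## Stitching

The stitcher infers *timing*, not displacement, from the video:

1. `frame_correlations()` computes the Pearson correlation of consecutive
   grayscale frames on central 50% crops (the support is a free choice; the
   center crop reduces edge effects).
2. `classify_motion()` thresholds the series at the midpoint of its two
   1-D k-means modes, then replaces the raw labels with the best-fitting
   square wave: an exhaustive grid over integer periods in $[4, n/2]$,
   pause lengths $[1, p-1]$ and phases $[0, p)$, scored by Hamming
   disagreement, ties resolved to the smallest period then smallest phase.
   The fit repairs featureless-region errors (uniform background correlates
   highly even while moving) and the inter-row jump artifact.
3. `detect_scan_lines()` turns moving runs into segments with alternating
   directions. The first direction cannot be inferred from a featureless
   start, so it is supplied by the caller (or taken from the config).
4. `assemble_mosaic()` places frames at uniform offsets
   $s_x/(\mathrm{fps} \cdot \mathrm{px})$ — displacement comes from the
   known stage speed, not from image registration; sub-pixel residuals are
   ignored. Overlaps default to last-wins overwriting (averaging is
   available); with uniform illumination and identical content in overlaps
   the rule is immaterial.

Because the simulator and the stitcher round stage positions to pixels with
the same convention, a noise-free round trip reconstructs the row-wise
blurred slide almost exactly; the acceptance suite bounds the RMSE at 2% of
dynamic range and checks that core centroids land within one blur width.

## Core extraction

White balance samples the brightest low-variance 64×64 block (a region
devoid of tissue) and subtracts its offset from white, clipping to range —
subtraction, not division, following the additive-cast model. Tissue
localization converts to grayscale, Otsu-thresholds, Gaussian-smooths the
binary mask, re-thresholds, clears border-touching components, and takes the
bounding box of what remains; the box is split into the layout's
$n_{rows} \times n_{cols}$ equal cells, and each cell with at least 2%
tissue occupancy is cropped and labeled from the manifest. Cells below the
occupancy floor are treated as gaps. An Otsu foreground whose mean gray
exceeds 0.92 is declared tissue-free (a blank slide's noise otherwise
produces a spurious split).

The quantitative staining readout, `stain_statistic()`, is the mean over
the tissue mask of $\max(0, 1 - B/R)$ after internally re-normalizing the
background to white. DAB brown attenuates the blue channel more than red,
so the statistic increases with membrane stain level and completeness, while
blue hematoxylin nuclei clamp to zero contribution. The internal
normalization makes the statistic invariant to white-balance offsets by
construction.

## Synthetic slides: what they emulate and what they do not

`render_core()` draws a circular tissue disk with a faint, stain-neutral
haze (so score-0 cores remain detectable), hematoxylin-blue nuclei, and
DAB-brown membrane rings. Staining is multiplicative attenuation by a
chromogen color raised to the stain level — monotone, invertible, and
score-graded through two parameters that mirror how the HER2 score is
defined: membrane stain *intensity* (0.06 / 0.28 / 0.55 / 0.85 for scores
0–3) and membrane *completeness* (0.10 / 0.35 / 0.70 / 0.95). Cell density
(2000 cells/mm²), nuclear staining, and geometry are score-independent.
Default pixel size is 1 µm/px so a 640×480 px frame covers the stated
640×480 µm field of view; the instrument's sensor arithmetic would imply a
smaller field, an inconsistency we resolve in favor of the stated FOV.

These slides are *stylized*: no nuclear texture, no stromal architecture, no
staining artifacts, no carcinoma-in-situ exclusion, no focus variation. A
green classifier test on them establishes that the pipeline is wired
correctly and that the network can exploit the stated class signal — it says
nothing about performance on real IHC tissue, and the study-scale accuracies
(79.3% / 89.7%) from real TMAs are out of scope by design.

## Multi-scale stacks

Each core yields a 5-slot stack: one area-downsampled $S \times S$ view of
the whole core plus four uniform-random $S \times S$ crops at native
resolution ($S = 512$ by default, smaller in tests), concatenated into a
$3(1+4) = 15$-channel raster. Cores smaller than $S$ are reflect-padded.
Crop offsets derive from `(seed, core_id, repeat_index)`, so datasets are
reproducible core by core.

## The spectral classifier

Each block applies a 2-D FFT, multiplies every frequency of every channel by
a learnable complex weight (a stationary linear filter, initialized near
identity), inverse-transforms, takes the real part, applies GELU, and mixes
channels with a 1×1 convolution; a final 1×1 convolution to $K$ classes
followed by global average pooling produces the logits, and softmax the
probabilities. With the nonlinearity disabled a block is shift-equivariant
under circular shifts, which the test suite verifies, and the GAP head makes
the final prediction shift-invariant. The block count (3) and widths
(32/64/64) are desk-scale defaults — the underlying architecture family
leaves them open — and the input is area-pooled to a 16×16 feature grid
before the first block purely for CPU tractability. Inputs are converted to
absorbance ($1 - I$) so the background maps to zero; without this centering
the optimizer spends most of its budget learning the bias.

Training uses cross-entropy, AdamW with decoupled weight decay $10^{-4}$,
initial learning rate $10^{-3}$, and cosine annealing with warm restarts
(initial period 10 epochs, period multiplier 2). Everything — split,
shuffling, initialization — is seeded; retraining reproduces identical
weights and history. The backward pass is hand-derived (the spectral-filter
gradient is $g_z \odot \overline{X_f}$ with $g_z = \mathcal{F}(dY)/N$) and
validated against central finite differences to $10^{-4}$ relative error.

The confidence index (CI) attached to each prediction is the **maximum
softmax probability**. The source material uses CI throughout without a
formal definition; max-probability is the simplest reading consistent with
CI-weighted averaging and thresholding on $[0,1]$, and we flag it as a
modeling choice. CI is uncalibrated; nothing here should be read as a
clinical confidence.

## Repeat aggregation and evaluation

Three schemes reduce the three scans per core:

* **3N** — every scan counts as its own prediction;
* **max-CI** — keep the repeat with the highest CI (ties to the lowest
  repeat index);
* **CI-weighted** — $\mathrm{round}\left(\sum_i s_i c_i / \sum_i c_i\right)$,
  half away from zero, clamped to the score range. The literal description
  ("multiply, sum, round") can leave the score range (three 3+ scans at CI
  0.9 sum to 8.1), so the normalized weighted mean is primary and the
  literal sum sits behind `normalize = FALSE`.

Consistency is the fraction of repeats matching the modal prediction; an
all-distinct triple scores 1/3 with the lowest score reported as the mode.
`threshold_curve()` sweeps a CI threshold (101 grid points on $[0,1]$),
marking cores below it indeterminate and scoring accuracy on the rest;
`threshold_at_indeterminate()` finds the smallest threshold reaching a
target indeterminate rate (e.g. 15%). Under the max-CI scheme the aggregate
CI is the selected repeat's CI; under the weighted scheme, the CI-weighted
mean of CIs; under 3N each scan is thresholded individually. The 2-class
task merges scores {0, 1+} vs {2+, 3+}; sensitivity treats the 2+/3+ group
as positive. ROC/AUC uses mid-rank ties (equivalently, simultaneous steps in
the threshold sweep), making AUC invariant under monotone transforms.

## Degenerate inputs and tie-breaks (summary)

* All-static or constant-correlation video → `no-scan-lines` error.
* Slide with no tissue-free block → `no-background`; blank slide →
  `empty-tissue`; manifest/grid mismatch → `label-mismatch`.
* Prediction argmax ties → lowest score index; max-CI ties → lowest repeat;
  square-wave fit ties → smallest period, then phase.
* All-zero CIs → `undefined-aggregate`; single-class labels →
  `degenerate-data` (training) / `undefined-AUC` (ROC).

## Known limitations

* The synthetic appearance model is parametric; class separability is by
  construction, so classifier tests are functional checks, not benchmarks.
* Stitching assumes the configured stage speed is exact; drift between the
  nominal and true advance would require registration-based refinement,
  which is deliberately out of scope.
* The classifier runs at reduced resolution internally (`pool_to`); at
  $S = 512$ with a 16×16 grid the fine-scale membrane texture contributes
  only through pooled averages.
* Scan-video compression, illumination flat-fielding, and focus errors are
  not modeled.
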