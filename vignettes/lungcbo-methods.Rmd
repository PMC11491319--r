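---
title: "Methods: phantoms, CBO-Otsu segmentation, LBP features and the DenseNet-style classifier"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phantoms, CBO-Otsu segmentation, LBP features and the DenseNet-style classifier}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lungcbo)
```

`lungcbo` is a desk-scale lung-CT nodule analysis pipeline for 2-D 8-bit
slices: synthetic phantoms with ground truth, histogram preprocessing,
Otsu thresholding driven by Colliding Bodies Optimization (CBO), local
binary pattern (LBP) texture features, a small densely connected CNN
classifier, standard evaluation metrics, and an IoT telemetry adapter.
This vignette records the models, the tunable parameters, and the design
choices made where the design was genuinely open.

## The synthetic phantom model

Clinical CT archives cannot be redistributed with a package, so every
stage is exercised on phantoms built by `generate_phantom()`. A phantom is
an `S x S` 8-bit image (default `S = 128`) containing:

- a soft-tissue background at intensity 180 and two elliptical lung fields
  at intensity 60 (semi-axes `0.32 S` by `0.16 S`, centred at 30% and 70%
  of the width) — intensities on the familiar bright-tissue / dark-lung
  scale of a display-windowed CT slice;
- one circular nodule of radius `r0` (default 10 px) centred in the left
  lung field, mean intensity 140, with boundary
  `r(θ) = r0 (1 + a·s(θ))` where `s` sums two seeded sinusoidal lobes
  (5–9 and 11–15 cycles). The spiculation amplitude `a` and the
  intra-nodule texture contrast are the class signal: benign defaults are
  `a = 0` (smooth disk) and texture 8; malignant defaults are `a = 0.3`
  and texture 45. Texture is an i.i.d. uniform field scaled by the
  contrast, so malignant nodules have visibly rougher interiors and
  higher intensity variance — the margin/texture cues the classifier is
  meant to learn;
- a low-frequency multiplicative bias field
  `1 + (b / 255)·(2 sin(π r / S) sin(π c / S) − 1)` (default `b = 30`),
  emulating shading artifacts and giving histogram equalization something
  to correct;
- additive Gaussian noise (default SD 5), then rounding and clamping to
  `[0, 255]`.

The ground-truth mask is the exact set of pixels whose centre falls inside
`r(θ)`; with `a = 0` this is a rasterized disk, which the tests check
against a brute-force in/out oracle. All randomness flows from the spec's
seed, so a spec is a complete, reproducible description of an image.

What the phantoms deliberately do **not** model: 3-D structure,
vasculature and airways, juxta-pleural nodule placement, scanner-specific
noise spectra, or calibrated Hounsfield statistics. Consequently a perfect
score on the phantom benchmark demonstrates that the pipeline's machinery
works and that the classifier exploits texture/margin signal; it is not
evidence of clinical performance on real CT.

Dataset plumbing: `generate_dataset()` derives per-image seeds as
`master seed + image counter`, so any subset of a dataset regenerates
bit-identically regardless of order. `split_dataset()` apportions records
to train/validation/test by **largest-remainder apportionment**: each
split receives the floor of `fraction × N`, remaining records go to the
largest fractional parts, ties broken in train → val → test order. For
N = 1135 at 70/10/20 this gives 795 / 113 / 227. (Published split counts
for a 1,135-image collection sometimes quote 795/114/227, which sums to
1,136; 114 is arithmetically impossible and the splitter makes no attempt
to reproduce it.) `kfold_assign()` deals records into folds differing in
size by at most one, covering the four-folds-train / one-fold-test
arrangement at `k = 5`.

## Preprocessing

`equalize()` implements plain histogram equalization,
`v → round((L−1)·CDF(v))`, with two deliberate choices:

- **Rounding** is half-away-from-zero, chosen because it is deterministic
  across platforms (IEEE round-half-even applied by `round()` would give
  platform-stable but less intuitive worked examples).
- **No CDF-minimum renormalization.** Some textbook variants subtract
  `CDF_min` so the darkest occupied level maps to 0; the plain mapping is
  used here, so a constant image maps to `L − 1`.

The mapping is monotone, conserves histogram mass, is idempotent up to one
quantization level, and cannot worsen the Kolmogorov–Smirnov distance of
the intensity CDF to uniform on bias-field phantoms — all properties the
test suite asserts. `median_filter()` (odd window, edge replication) is
provided as an optional artifact-suppression step; equalization and the
median filter can be chained in either order through the pipeline's
`preprocessing` setting, with equalization-only the default, since the
order of the two operations is a free choice.

## Colliding Bodies Optimization

`cbo_optimize()` minimizes a black-box objective over a box. Bodies are
candidate solutions; per iteration:

1. evaluate all `n` bodies; update the best-so-far (reported externally —
   the population itself is memoryless);
2. convert fitness to masses `m_k = (1/fit_k) / Σ_i (1/fit_i)` — better
   bodies are heavier;
3. sort ascending by fitness; the lower half is stationary with zero
   pre-collision velocity, each upper-half body `i` moves onto its partner
   with `v_i = x_{i−n/2} − x_i`;
4. post-collision velocities follow 1-D collision mechanics with
   coefficient of restitution ε: moving
   `v′_i = (m_i − ε m_{i−n/2}) v_i / (m_i + m_{i−n/2})`, stationary
   `v′_i = (m_{i+n/2} + ε m_{i+n/2}) v_{i+n/2} / (m_i + m_{i+n/2})`;
5. new positions `x_stat + rand ∘ v′` (stationary) and
   `x_partner + rand ∘ v′` (moving), with `rand` a fresh uniform
   `[−1, 1]` vector per body, clipped to the box.

Open parameters were fixed as follows and are all overridable in
`cbo_config()`:

- **ε schedule**: `ε(t) = 1 − t / max_iters`, elastic early (exploration)
  and plastic late (exploitation);
- **`rand` distribution**: uniform on `[−1, 1]` per dimension — symmetric
  so collisions can overshoot in either direction;
- **bound handling**: clipping, which keeps boundary optima reachable (a
  tested property);
- **positive fitness**: the mass rule requires `fit > 0`. When the caller
  declares a finite lower bound `b`, fitness is `raw − b + 1`; otherwise,
  if non-positive values appear, an exponentially rescaled rank
  `exp(rank/n)` is substituted. The reported optimum is always on the raw
  scale.

Defaults of `n = 30` bodies and 200 iterations solve the 2-D shifted
sphere (`f = 1 + ‖x‖²` on `[−5, 5]²`) to within `10⁻⁴` of the optimum in
the median over seeds; the acceptance tests pin that behaviour.

## CBO-driven multilevel Otsu segmentation

`between_class_variance()` implements the multilevel Otsu criterion
`σ_B² = Σ_j w_j (μ_j − μ_T)²` over the `k + 1` classes induced by
`t_1 < … < t_k` (empty classes contribute zero). For `k = 1`,
`otsu_bilevel_exhaustive()` scans all 255 candidates with the smallest-`t`
tie-break, matching common reference implementations.
`cbo_multilevel_threshold()` searches continuous positions in
`[0, L−2]^k` and **repairs** each candidate before evaluation — round,
clamp, sort, nudge duplicates to the nearest free level — rather than
penalizing infeasibility, keeping the search space smooth. The CBO
fitness is `1/(1 + σ_B²)`: positive, as the mass rule requires, and
monotone in the Otsu objective. With the default budget (20 bodies, 100
iterations) the bilevel result matches the exhaustive optimum on
effectively every random test image (the acceptance bound asks for 95 of
100); `k` is configurable, with `k = 1` the default since nothing in the
task fixes a larger value.

`extract_nodules()` labels connected components of the chosen foreground
class under **8-connectivity**, reports 0-based `(row, col)` centroids,
half-open bounding boxes and `equivalent_diameter = sqrt(4·area/π)`, and
filters by minimum area. The pipeline additionally discards regions whose
bounding box touches the image border: the body wall shares the bright
class with the nodule and always reaches the border, while a nodule
candidate never does. Which label is foreground defaults to the top
(brightest) class.

## LBP texture features

`lbp_code()` computes `Σ_h G(p_h − p_c)·2^h` with `G(x) = 1` iff
`x ≥ 0` — note `G(0) = 1`, so a flat patch codes to 255 at `H = 8`.
Because LBP codes are convention-dependent, the conventions are fixed and
documented: neighbor `h = 0` due **east**, indices proceeding
**counterclockwise** (image rows grow downward, so the row offset is the
negated sine); circle points snapped to the nearest pixel; borders
**excluded** rather than padded, since padding would fabricate texture at
the image edge; no uniform-pattern reduction. `feature_vector()`
concatenates the 256-bin LBP histogram over a nodule's pixels with area,
equivalent diameter, centroid and mean intensity (261 entries). The
classifier consumes images, not these vectors; the vectors are emitted as
auxiliary output for downstream analysis, which resolves an ambiguity in
how the two stages could be wired while keeping both available.

## The DenseNet-style classifier

`build_densenet()` constructs: 3×3 convolution to `k₀` channels → 2×2
average-pool downsampling → `B` dense blocks (each layer batch-norm →
ReLU → 3×3 convolution producing `g` maps, concatenated with all earlier
maps; layer `ℓ` sees `k_in + (ℓ−1)g` channels) separated by transitions
(1×1 convolution to `⌈θ·C⌉` channels, 2×2 average pooling) → batch-norm →
ReLU → global average pooling → 2-way softmax. The forward and backward
passes (im2col GEMM convolutions, batch-norm statistics and gradients,
pooling adjoints) are hand-written in Rcpp/Armadillo and verified against
central finite differences in the test suite, to ~1e-10 relative error on
parameters with non-degenerate gradients.

Architecture and optimization defaults — none dictated by the task —
were chosen for CPU-scale training: `k₀ = 16`, 2 blocks × 2 layers,
`g = 8`, `θ = 0.5`, 64×64 input, Adam at learning rate 1e-3, batch 32.
Inputs follow a fixed contract: equalize, nearest-neighbor resize to the
network size, scale to `[−0.5, 0.5]`. Training logs per-epoch
train/validation loss and accuracy; the returned model restores the
parameters of the epoch with the lowest validation loss (classic
early-stopping-style model selection — with small validation sets the
final epoch's decision threshold can be poorly calibrated even when the
ranking is perfect, and selecting on validation loss removes that
failure mode). Ties at probability 0.5 predict **malignant**, the
cautious screening choice. Seeded runs are reproducible on a fixed
BLAS/compiler stack; bit-equality across numerics stacks is not promised.

## Evaluation

Malignant is the positive class. `metrics()` reports accuracy,
sensitivity (= recall), specificity and precision; a metric with a zero
denominator is `NA` ("undefined"), never silently 0, since a coerced zero
would corrupt method comparisons. `roc_curve()` computes TPR/FPR at every
distinct threshold (`score ≥ t` ⇒ malignant) plus the `(0,0)`/`(1,1)`
endpoints and integrates by the trapezoidal rule; the result equals the
Mann–Whitney statistic `P(s₊ > s₋) + ½P(tie)` to 1e-12 on randomized
tests including ties. `error_histogram()` bins signed errors
`target − P(malignant)` on `[−1, 1]` per split; an odd bin count keeps the
binning mirror-symmetric about zero.

## Pipeline and IoT telemetry

`run_pipeline()` chains generate/ingest → preprocess → CBO-Otsu segment →
localize → LBP → classify → evaluate → (optional) transmit, derives every
stage seed from the master seed, and writes a JSON run report containing
the config, thresholds, per-image predictions with their
`"Tumor is BENIGN"` / `"Tumor is MALIGNANT"` messages, nodule tables,
metrics and transmission status — enough to re-execute the run.

The IoT adapter mirrors the public ThingSpeak channel-update convention
(an `api_key` plus numeric `field1..field8`, form-encoded over HTTP)
behind an abstract transport, so tests never touch a network: the mock
transport records updates in-process, and a `curl`-based transport is
provided for real channels. Only scalar percentage metrics are ever
mapped to fields — never pixel data or anything patient-identifying,
which is the privacy-safe reading of transmitting "relevant metrics".
Updates are paced by a minimum-interval rule (free-tier channels accept
one update per 15 s) with delay or reject policies, and transport
failures degrade to a logged `failed` status rather than aborting an
analysis. Undefined metrics are omitted from updates rather than sent
as zeros.

## Problem sizes, tolerances and degenerate inputs

- Test-suite and acceptance problem sizes: 32×32 or 64×64 phantoms,
  datasets of 16–400 images, 100-image segmentation sweeps, 20-seed
  optimizer benchmarks, 12-epoch training runs — sizes at which the whole
  suite completes in a few minutes on one core while leaving the
  acceptance bands comfortable margins.
- `σ_B²` comparisons against oracles use a relative slack of `10⁻⁶`;
  AUC identities use `10⁻¹²`; equalization idempotence allows one
  quantization level.
- Degenerate inputs fail loudly and specifically: single-level histograms
  (no threshold exists), `k` ≥ distinct levels, empty LBP regions,
  single-class training splits, non-finite objective values (reported with
  the offending position), odd population sizes (the collision pairing
  needs equal halves), non-odd median windows.

## Known limitations

- 2-D only; no DICOM ingestion (8-bit PNG/TIFF-style matrices are the
  interface), no anatomical lung-field segmentation, no morphological
  post-processing chains.
- The phantom benchmark is intentionally separable; results on it upper-
  bound nothing about clinical data.
- CBO is implemented in its canonical form; enhanced/chaotic variants and
  constraint handling beyond box clipping are out of scope.
- The classifier is a small CNN trained from scratch; transfer learning
  and GPU-scale configurations are expressible through the config but
  untested at that scale.
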