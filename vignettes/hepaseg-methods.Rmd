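---
title: "Liver and tumor segmentation with a cascaded U-Net and a localized level set"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Liver and tumor segmentation with a cascaded U-Net and a localized level set}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(hepaseg)
```

## The problem and the model

Delineating the liver and the tumors inside it on contrast-enhanced
abdominal CT is a prerequisite for hepatic surgical planning, and doing it
by hand is slow and operator-dependent. `hepaseg` implements a two-stage
automatic approach. A convolutional network trained on many cases supplies
a *coarse* segmentation that is approximately in the right place; a
localized region-based active contour then uses the intensity statistics of
the *target* scan itself to move that coarse boundary onto the actual
liver or tumor edge. The two components are complementary: the network
contributes learned shape and appearance knowledge, the level set
contributes case-specific boundary accuracy that no amount of training data
provides.

The cascade runs liver first, tumors second. The liver network sees whole
abdominal slices; its refined output defines a liver region of interest
(ROI) in which a second network looks for tumors. Both stages assume
portal-venous-phase contrast, where liver parenchyma is enhanced and
lesions appear darker than the surrounding tissue.

## Preprocessing

**HU windowing.** Intensities are clipped to the −50 to 250 HU window and
mapped linearly onto [0, 1]:
`u = (clip(x, −50, 250) + 50) / 300`. This removes air (≈ −1000 HU) and
compact bone (≥ 400 HU) from the usable contrast range while spanning the
liver (≈ 120 HU) and tumor (≈ 45 HU) intensities. The map is monotone and
idempotent on already-windowed data re-expressed in HU.

**Median filtering (liver stage).** Each windowed slice is filtered with a
3×3 median (edges reflected) to homogenize parenchyma texture before the
liver network and liver level set see it. We window first and filter
second; the two nearly commute for in-window values, and this order keeps
the median's rank statistics on the bounded scale. The kernel size is a
configuration key.

**Edge-enhancing diffusion (tumor stage).** The liver ROI is smoothed by
tensor-driven anisotropic diffusion, `u_t = div(D ∇u)`, where `D` has
eigenvalue `g(|∇u_σ|²)` along the regularized gradient direction and 1 on
the orthogonal complement, with Weickert's diffusivity
`g(s) = 1 − exp(−Cm/(s/λ²)^m)`, `m = 4`, `Cm = 3.31488` (so `g(0) = 1` and
`g` decreases). Noise inside liver and tumor tissue diffuses freely while
flux across the tumor–parenchyma boundary is inhibited, which raises the
contrast the tumor network and level set depend on. Defaults:
`σ = 1 px` (gradient pre-smoothing), `ρ = 2 px` (componentwise smoothing of
the assembled tensor field — its integration scale), `λ = 0.05`
windowed-intensity units (gradients above ≈ λ stop diffusing), `τ = 0.1`,
10 steps. These are conventional choices for this filter family; the tests
pin the *behavior* (within-phase variance at most halved, cross-phase
contrast retained to ≥ 90 %, mean conserved, no new global extrema) rather
than the constants. The explicit step must satisfy
`τ ≤ 1/(2·(1/hx² + 1/hy² + 1/hz²))` with in-plane pixel units
(`hx = hy = 1`) and `hz` the slice spacing ratio; `eedFilter()` refuses an
unstable `τ` before iterating. The conservative face-flux discretization
(zero-flux boundaries) conserves the intensity sum to machine precision,
and gradients are spacing-aware for anisotropic voxels.

## The network

Both stages use the same compact 2D U-Net: a contracting path of
convolution blocks (two 3×3 convolutions + ReLU per level, channels doubled
and resolution halved per level via 2×2 max pooling), an expanding path of
2×2 stride-2 transposed convolutions with skip concatenations, each
followed by one 3×3 convolution, dropout (rate 0.5) before the output, and
a 1×1 convolution with a logistic sigmoid producing a per-pixel probability
in [0, 1]. With the default 256×256 input, depth 4 and 32 base filters the
audit counts exactly 19 convolutional layers:
`2·(depth+1) + 2·depth + 1 = 19`. Putting the second convolution of each
decoder block into the transposed convolution (i.e., one plain convolution
per decoder level) is what makes the count come out at 19 rather than the
23 of the fully symmetric variant. A single output channel with a sigmoid
is used rather than a two-channel softmax; for a binary task the two
parameterizations are equivalent and the sigmoid matches the probability
semantics of the output.

**Loss.** The soft-Dice loss
`1 − (2·Σ p·t + ε)/(Σ p + Σ t + ε)` is computed per sample and averaged
over the batch (`ε = 1`). On binary predictions it equals `1 − Dice` as
`ε → 0`, which the tests assert. Dice-type losses self-balance foreground
and background, which matters for small tumors.

**Slice selection.** Training uses only slices whose target mask is
nonempty — empty slices carry no gradient signal under a Dice loss and
would dilute the batches. For the tumor stage, volumes with no tumor
annotation at all are excluded entirely. Class balance is handled entirely
through this selection; no per-pixel loss weighting is applied.

**Initialization.** He-scaled Gaussian weights; the output bias starts at
−2 so the untrained network predicts background (p ≈ 0.12) rather than 0.5
everywhere — the standard prior initialization for dense detection. This
matters for short training runs: starting at p = 0.5 makes the first epochs
an all-foreground free-for-all whose outcome decides, seed by seed, whether
the run lands in a false-positive-heavy basin that the
learning-rate-on-plateau rule then freezes.

**Optimization.** Adam at learning rate 0.001, 20 epochs, batch size 32.
The learning rate is multiplied by 0.1 whenever the monitored loss
(validation loss when a split exists, else training loss) has not improved
for 5 consecutive epochs, so after k reductions `lr = 0.001 × 0.1^k`. One
seed governs weight initialization (He) and shuffling; training is
reproducible given the seed. The convolution, pooling and transposed
convolution kernels and their backward passes are implemented in C++
(im2col + BLAS matrix products) and are verified against finite-difference
gradients in the test suite.

## The localized level set

The refinement minimizes a Chan–Vese-type energy
`E(C) = μ·length(C) + ∫inside (I − c1)² + ∫outside (I − c2)²` in its
*localized* form: the contour is represented as the zero level of a signed
embedding φ (negative inside, exact Euclidean distance at initialization,
so the initial zero level reproduces the coarse mask boundary exactly), and
at every narrow-band point the fitting constants are the means `u_x`, `v_x`
of the image over the disk of radius `r` around that point, intersected
with the interior and exterior. Locality matters here because liver
parenchyma is not globally homogeneous: each boundary segment only has to
separate its own neighborhood.

Numerics, in order of consequence:

* **Step size.** The data force `(I − u_x)² − (I − v_x)²` is normalized by
  its maximum over the band each iteration, and the update is scaled so the
  largest per-iteration change of φ equals `dt = 0.45` px — a CFL-style
  step. Without this normalization the raw force (squared windowed
  intensities, order 10⁻²) moves the front by ~0.02 px per iteration and
  cannot traverse a 5 px initialization error within 200 iterations.
* **Curve shortening.** The regularization `μ·κ` (curvature by central
  differences, clamped to ±1, `μ = 0.2` relative to the normalized force)
  is applied across the whole narrow band rather than only inside the
  smoothed Dirac support. After reinitialization `|∇φ| ≈ 1` on the band, so
  this is the standard `μ·κ·|∇φ|` curve-shortening term; restricting it to
  the Dirac support makes sub-pixel shrinkage of small components so slow
  that periodic reinitialization undoes it, and spurious objects then never
  collapse. The data force keeps its Dirac factor (`ε = 1.5` px).
* **Reinitialization and stopping.** φ is reset to the signed distance of
  its current sign mask every 20 iterations. Evolution stops at `maxIters`
  (200 liver / 100 tumor), when the mean |Δφ| over the band falls below
  `tol = 10⁻³`, or when the binary mask has not changed for 10 consecutive
  iterations — the normalized step keeps a noise-scale |Δφ| even at
  convergence, so the mask-stability rule is the one that usually fires.
* **Localization radius.** `r = 9` px at a 256×256 working grid (about the
  scale of boundary ambiguity); the band half-width equals `r`. The phantom
  study, which refines at its native 128×128 grid, uses `r = 7`.
* **Empty sides.** If a ball sees no interior (or no exterior) pixels the
  point's force is 0 — only the curvature term acts there.

**Otsu gate.** The package couples a simple intensity gate into the level
set: an Otsu threshold (256-bin between-class-variance maximizer, ties to
the lowest cut; verified against exhaustive search) defines an interval,
and pixels outside it contribute to the *exterior* statistics regardless of
their φ sign. The liver stage keeps intensities above the threshold of the
whole slice (liver is bright after windowing). The tumor stage computes the
threshold from the intensities *inside the liver envelope* of the slice and
keeps values at or below it (tumors are darker than enhanced parenchyma).
The envelope restriction matters: the cropped ROI contains a zeroed
background whose blurred ramp would otherwise dominate the histogram and
push the threshold below the tumor intensity range, gating the tumors
themselves out. The gate concentrates the interior statistics on the tissue
class being segmented; it is off by default in `evolveContour()` and on in
the pipeline presets.

**Collapse of spurious objects.** A predicted component whose local
interior and exterior means are statistically indistinguishable receives no
net data force, and the curve-shortening term contracts it until it
vanishes. This is a feature, not an artifact: it removes small non-tumor
blobs from network predictions, and the tests plant a 3-px impostor with
matched mean next to a genuine dark lesion and require the impostor to
disappear while the lesion stays.

## The cascade

`segmentLiver()` windows and median-filters the volume, predicts per-slice
probability maps at the network input size, thresholds at 0.5 (`p ≥ t` is
foreground), keeps the largest 3D 6-connected component (a multi-blob
"liver" contradicts anatomy; this is the minimal cleanup before
refinement), refines each nonempty slice with the level set + liver gate,
and inverse-resizes to the native grid with nearest-neighbor interpolation.
`segmentTumors()` crops the axis-aligned liver bounding box dilated by 5 px
(margin so the level set has room at the boundary), zeroes voxels outside
the liver mask (zero is the window floor, making suppressed background and
window-floor tissue coincide), applies the diffusion filter, predicts,
refines with the tumor gate, maps back, and intersects with the liver mask
— tumors are by construction inside the liver envelope. The network runs at
its own input size, but refinement happens at the *native* grid: the coarse
mask is upsampled (nearest neighbor) first and the level set then works on
the full-resolution slice. Refining before upsampling looks cheaper but
caps the achievable Dice — a 0.5 px nearest-neighbor boundary error is
negligible for the liver yet costs of order 15 % Dice on a 6 px tumor — and
the gate statistics are better resolved at native resolution. Both the
network-only and the refined mask are returned at every stage so the
level-set contribution can be ablated. The pipeline is a pure function of
(volume, trained weights, configuration).

## The phantom generator

`generatePhantom()` builds 3D abdominal stand-ins with per-voxel ground
truth: an air background (−1000 HU), a soft-tissue body ellipse (≈ 40 HU),
a posterior spine cylinder and rib arcs (≈ 450 HU), a liver modeled as an
ellipsoid whose radius is modulated by a low-frequency angular perturbation
(amplitude 8 % — so the level set faces non-trivial curvature, not a
textbook ellipse), Gaussian tissue texture (liver 120 ± 15 HU, tumors
45 ± 10 HU), 0–4 spherical tumors with radii 4–14 px placed where the
distance to the liver boundary exceeds the radius plus 2 px (in-plane pixel
metric, slice axis weighted by the spacing ratio), and additive Gaussian
noise (σ = 10 HU). All intensities sit inside the −50..250 HU working
window with tumors darker than parenchyma, matching the portal-venous
contrast regime the method assumes; the liver-to-tumor contrast (75 HU)
exceeds three noise standard deviations by construction. Every drawn
parameter is recorded in a manifest and each case is reproducible from its
seed.

What the phantoms deliberately do **not** model: vessels and bile ducts
inside the liver, spatially correlated scanner noise, partial-volume
blurring at organ boundaries, respiratory deformation, inter-organ contact
with matched intensities (stomach, heart), and the extreme shape variety of
real livers. Passing the phantom study therefore demonstrates that the
implementation is correct and that the cascade's machinery works end to
end under the intensity regime it assumes — it does not certify clinical
accuracy on real CT, where published results at full scale require the
public LiTS/IRCAD corpora and far larger training budgets.

## The phantom study

`runPhantomStudy()` is the package's scaled-down counterpart of a full CT
experiment, sized for a single CPU: 50 phantoms of 128×128×48 voxels at
(1.5, 1.5, 2.5) mm spacing, split 40 training / 10 held-out; both networks
run at 64×64 input with 8 base filters, the liver network at depth 4 (the
default 19-convolution architecture at reduced input size and width) and
the tumor network at depth 3. The asymmetry is deliberate: the liver
network must recognize that a slice contains no liver at all — its
training set, by the slice-exclusion rule, contains only liver-bearing
slices, so this discrimination has to come from whole-slice shape context,
which needs the depth-4 bottleneck's full receptive field — whereas small
lesions are local structures that degrade through a fourth pooling level.
Every second qualifying slice per volume
enters training (adjacent phantom slices are highly redundant); the
training recipe is the standard one above (20 epochs, batch 32, Adam
0.001, plateau schedule). Evaluation is Dice per case, with the refined and
the network-only masks reported side by side; cases whose ground truth has
no tumor are flagged and excluded from the tumor means (their tumor Dice
under the empty-vs-empty convention is not informative about detection).
Two details of the data plumbing matter
here: slices whose resized target mask comes out empty are dropped (a tiny
native-grid section can vanish under nearest-neighbor downsampling, and an
empty target carries no usable Dice gradient), and the suite's
overfit *capacity* check (16 representative slices of one phantom driven to
training soft-Dice ≥ 0.95) runs with dropout off, batch size 4 and a fixed
learning rate — dropout exists to prevent exactly that memorization, and
with 16 samples an "epoch" is so few optimizer steps that the 5-epoch
plateau rule would fire on step noise; the cascade training itself keeps
the standard recipe. `scripts/acceptance.R` reruns this study and the
per-stage property checks from scratch and writes the resulting numbers as
JSON.

## Conventions and edge cases

* Axial plane = third array axis (the LiTS layout); (row, column) = (y, x)
  within a slice; 1-based indices in R.
* Bilinear interpolation for intensities, nearest-neighbor for masks;
  resize records are kept so every transform inverts.
* Label volumes: {1, 2} → liver, {2} → tumor; other nonzero labels are
  coerced to liver with a warning.
* Dice of two empty masks is defined as 1 (configurable); empty prediction
  against nonempty truth is 0.
* `binarizeMaps()` counts `p = threshold` as foreground.
* Empty coarse masks are a "nothing to refine" condition: the pipeline
  keeps the (empty) network output for that slice; an entirely empty liver
  prediction is a hard "no liver found" error carrying its stage tag.
* Masks are stored as 0/1 integers and written as unsigned 8-bit NIfTI.

## Known limitations

2D evolution only (per-slice, by design — slice-wise curve evolution is
better behaved than its 3D counterpart at this task, at the cost of
through-plane consistency); no data augmentation; no vessel/lesion
subtyping; tumor-stage accuracy is bounded by the liver stage, since
tumors are only sought inside the recovered liver envelope; the CPU
implementation is deliberately compact and is not intended for
GPU-scale training on real corpora.
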