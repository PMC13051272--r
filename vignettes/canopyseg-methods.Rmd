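---
title: "Methods: environment-simulation augmentation and the attention context-guided U-Net"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: environment-simulation augmentation and the attention context-guided U-Net}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Pixel-level delineation of individual tree canopies in high-resolution UAV
RGB imagery (ground sample distances of a few centimetres) is hampered by
two things at once: the appearance gap between clean training mosaics and
degraded field acquisitions (haze, specular over-exposure, platform jitter,
transient occluders), and the difficulty convolutional encoders have with
crown adhesion and background clutter. `canopyseg` packages the two
remedies this toolkit is built around:

1. an **environment-simulation augmentation framework** — four physically
   motivated degradation simulators (fog, local overexposure, directional
   motion blur, occlusion) applied with randomized parameters to the
   training side of a leakage-safe split; and
2. an **attention context-guided U-Net**: a VGG16-backbone U-Net whose
   encoder is rewired with split-based convolutions, one criss-cross
   attention block at the deepest features, and context-guided
   downsampling in place of max-pooling.

Everything operates on `H x W x C` arrays in the native R layout; images
are 8-bit RGB in `[0, 255]`, masks are `{0, 1}` planes with 1 = canopy.

# Degradation simulators

All four simulators are *pixel-level* operations: the mask is never
altered. Each application draws fresh parameters from configured ranges
and is a pure function of `(input, params, seed)`.

**Fog.** A local opacity field $M \in [0,1]$ is built from $N \in [1,3]$
circular spots with peak opacities $\alpha \in [0.4, 0.8]$, combined by
element-wise maximum and smoothed by one Gaussian kernel of size
$\mathrm{odd}(0.7 R)$ with $R = 0.3\min(H,W)$. The blend is
$I' = \mathrm{clip}((1-M)I + C_\mathrm{fog} M,\,0,\,255)$ with the fog
colour drawn from the bright grey range $[220, 245]$. The maximum (rather
than a sum) keeps overlapping spots inside the configured peak range, so
the output is always a convex combination of the input value and the fog
colour.

**Local overexposure.** One smoothed highlight spot (radius
$0.25\min(H,W)$, initial opacity $\alpha \in [0.5,0.9]$, kernel
$\mathrm{odd}(1.5R)$) is added: $I' = \mathrm{clip}(I + \beta M,\,0,\,255)$
with the brightness increment $\beta \in [150, 255]$. The operation is
pixel-wise non-decreasing.

**Directional motion blur.** A line of ones in an $L \times L$ kernel
($L \in [5,31]$, evens rounded up) is rotated by
$\theta \in [0^\circ, 180^\circ)$ with bilinear interpolation and
renormalized to unit sum; the blurred image
$B = \mathrm{conv}(I, \mathrm{psf})$ (reflect borders) is blended as
$I' = \mathrm{clip}((1-\gamma) I + \gamma B,\,0,\,255)$,
$\gamma \in [0.35, 0.8]$. Reflect borders make the blur mean-preserving
(constants map to themselves).

**Occlusion.** A cutout: one $S \times S$ patch ($S = 50$), uniformly
placed fully inside the frame, set to the fill value 0 in all three
channels. The label is deliberately untouched — the network must infer the
occluded canopy from its visible surroundings.

The expansion planner `expand_esref()` accepts per-operation
multiplicities, refuses anything already environment-augmented (leakage
guard), and yields `n * (1 + sum(mult))` samples. When several operations
chain within one copy they run in the fixed order fog, overexposure,
motion blur, occlusion. How many spots combine per fog application and the
per-image firing probability of each operation are configuration choices,
not fixed constants; the defaults above are the configured study
conditions.

# Classic augmentations

Flips and right-angle rotations apply the identical spatial map to image
and mask (lossless and mask-exact; the 90° map is $(r,c) \to (c, N-1-r)$).
Gaussian noise ($\sigma \in [5,15]$ grey levels), Gaussian blur (kernels 3
or 5) and contrast about the per-image mean (factor $[0.8, 1.5]$) leave
the mask byte-identical. Magnitudes are deliberately conservative —
plausible for clear-day UAV acquisitions — and all overridable. An
arbitrary-angle rotation (reflect padding, nearest-neighbour mask
resampling, re-binarization at 0.5) sits behind an explicit flag because
it is not mask-exact.

# Splitting before augmenting

The split is performed on original samples only and augmentation then
expands the train side. A stated "80:20 after augmentation" protocol can
only be leakage-free if the partition happens first, so that is the
implemented order; the realized post-expansion ratio is reported instead.
Train size is `round(ratio * n)` with round-half-away-from-zero (4,510 ids
at 0.8 give 3,608/902). Guards (`classed leakage errors`) fire when
augmented provenance reaches `split_dataset()`, the validation set of
`train()`, or `expand_esref()` twice.

# The network operators

**Split-based convolution** (`spconv_forward()`). Input channels are
partitioned at ratio $\alpha$ (default 1/2 — the ratio is not prescribed
by the design, so the original operator's default is kept and exposed in
`spconv_config()`) into a representative part, processed by a 3×3 grouped
convolution ($G = 2$) plus a parallel 1×1 convolution whose outputs are
summed ($U_3$), and a redundant part processed by a 1×1 convolution only
($U_1$). Fusion is parameter-free: channel statistics
$S_k = \mathrm{GAP}(U_k)$, pairwise softmax
$\beta_c = e^{S_{3c}} / (e^{S_{3c}} + e^{S_{1c}})$,
$\gamma_c = 1 - \beta_c$, output $Y = \beta U_3 + \gamma U_1$. Bias-free
throughout; parameter count
$(\alpha L / G) M k^2 + \alpha L M + (1-\alpha) L M$, e.g. 13,312 versus
the vanilla 36,864 for $L = M = 64$.

**Criss-cross attention** (`cca_forward()`). 1×1 projections give
$Q, K \in \mathbb{R}^{C' \times H \times W}$ (default $C' = C/8$; the only
constraint stated is $C' < C$) and $V$ at full depth. For each position
$u$, affinities $d_{i,u} = Q_u \cdot \Omega_{i,u}$ over the $H + W - 1$
criss-cross positions — the full column (containing $u$ once) plus the row
without $u$; counting $u$ twice would make the axis $H+W$ — are
softmax-normalized into an attention map of shape $(H+W-1) \times H
\times W$, used to aggregate $V$, and the input is added back residually.
One pass only: no recurrence is used. Shapes are strictly preserved.

**Context-guided downsampling** (`cgb_down_forward()`). Two parallel
stride-2 3×3 convolutions — a standard one (local features; the standard
rather than depth-wise form is used) and a dilation-2 one (surrounding
context) — each emit $C_\mathrm{out}/2$ channels; concatenation + batch
normalization + PReLU form the joint feature; a global-average-pool +
two-layer perceptron (hidden width $C_\mathrm{out}/16$, sigmoid output)
produces per-channel weights applied by channel-wise scaling. Output is
exactly $C_\mathrm{out} \times H/2 \times W/2$; no residual (shapes
differ).

Each operator is pinned to an independent brute-force oracle (plain
nested-loop convolutions, per-position attention lists) on ≥ 50 random
small tensors at 1e-5, and every gradient in the package's reverse-mode
engine was verified against central finite differences during
development.

# Model assembly

The baseline is a VGG16-backbone U-Net: 13 encoder convolutions
(64-64 / 128-128 / 256-256-256 / 512-512-512 / 512-512-512, biases, no
batch norm), skips taken before each of the four downsampling steps,
decoder stages of bilinear ×2 upsampling + skip concatenation + two 3×3
convolutions (512/256/128/64), and a 1×1 head to 2 classes. This layout
yields 24,891,202 parameters = 94.95 MB at 32-bit — matching the reference
footprint of ≈ 94.97 MB.

The toggles of `model_spec()` rewire exactly: `use_spconv` replaces every
encoder 3×3 convolution except the 3-channel stem (which cannot be
meaningfully split at α = 1/2); `use_cca` inserts one attention block
after the deepest 512-channel stage ("high-level semantic features"
admits one or several sites; one block at the deepest stage is the
cheapest reading and the attention-only variant's size then matches the
reference delta of +1.25 MB exactly); `use_cgb_down` replaces all four
max-pools, with output channels equal to the next stage's width. The
decoder is identical in all variants. `ablation_grid()` enumerates the
eight toggle combinations in the standard order.

**A known accounting discrepancy.** With this layout the split-convolution
variant weighs 59.1 MB and the full network 77.7 MB, whereas the reference
footprints are 73.33 MB and 100.71 MB. The attention delta matches
exactly and the baseline to 0.02 MB, and the orderings
(split-conv < baseline < context-guided; full > split-conv) all hold, but
no layout consistent with the stated module designs reproduces the
split-convolution and downsampling deltas; the corresponding
reference-size consistency check for the full network is therefore
expected to fail and is left failing rather than tuned. The package
reports its own, internally consistent books.

# Training harness

Mean per-pixel softmax cross-entropy, Adam (default moments, no weight
decay, no clipping), cosine learning-rate schedule from `lr0` to
`0.01 * lr0` (floored at `lr_min`), deterministic single-threaded
execution under the config seed, per-epoch history (train loss, validation
loss, validation mIoU) and best-mIoU weight retention. The reference
protocol (100 epochs, 512×512, batch 8, seed 11, `lr0 = 1e-7`,
`lr1 = 1e-9`) is kept as the default configuration for fidelity, with the
caveat that an initial rate of 1e-7 is implausibly small for training a
25M-parameter network from scratch — likely a reporting convention — so
desk-scale experiments override it (1e-3) rather than silently "fixing"
the default.

Batch normalization (present only inside the context-guided block) runs
with fixed inference-mode statistics (mean 0, variance 1) plus a learnable
affine, in training as well as in evaluation. This keeps every forward
deterministic, batch-size independent, and exactly differentiable with the
stored-statistics convention the operator oracles use; the affine pair
still gives the block its normalization degrees of freedom. The cost is
that activations are not re-standardized per batch, which matters little
at the smooth activation scales the seeded Kaiming initialization
produces.

Metrics come from pooled pixel confusions: per-class IoU, pixel accuracy,
precision and recall, with "m" prefixes denoting unweighted two-class
means (per-class means, not the global pixel ratio — the two agree only
for balanced classes). A class absent from both prediction and truth
contributes the identity value 1 and is flagged in the report.

# The synthetic scene generator

`generate_scene()` renders lobed crowns — unions of six jittered discs
with multiplicative value-noise texture and per-crown colour tints — over
a background of low-frequency colour patches plus speckle, then quantizes
to 8 bits (round half up). Defaults (256×256, 3–6 crowns of radius 20–40
px, clutter 0.3, autumn-foliage foreground over mixed soil/understory
background) were chosen once to reproduce the challenge axes that matter
for the pipeline — crown adhesion (overlapping crowns merge into one mask
component), clutter, illumination variation — at a foreground fraction
around 0.2–0.4. What it does *not* model: real spectra, radiometric
calibration, shadows cast between crowns, geo-referencing, or
species-level texture. Passing tests on these scenes therefore demonstrate
the correctness and trainability of the pipeline, not field accuracy on
real UAV mosaics.

# Problem sizes used by the test and acceptance runs

CPU-scale choices, stated here as the package's own study conditions: the
operator oracles run on tensors up to 6×6×16; the architecture audit
builds all eight variants at full reference width and runs one 64×64
forward each; the training smokes use 16 scenes of 64×64, width-1/8
channels (VGG widths scaled by 1/8, keeping every width divisible by 4 so
the split/grouped convolutions stay well-formed), batch 4, 200 Adam steps
at `lr0 = 1e-3`, seed 11 — under which both the baseline and the full
variant exceed 0.90 training mIoU — plus shorter 40-step runs at two
further seeds for the loss-decrease property. The acceptance script
repeats the same protocol on a 20-scene dataset with an 80:20 split and
reports held-out validation mIoU alongside training mIoU.

# Known limitations

- The gradient engine is exact but CPU-bound; full-width 512×512 training
  is out of reach here by design.
- Fog is an opacity blend, not a transmission model from atmospheric
  scattering; overexposure adds brightness without sensor saturation
  rolloff.
- Only binary (canopy / background) labels are supported.
- The model-size discrepancy for the split-convolution and downsampling
  variants against the reference footprints is documented above and left
  visible.
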