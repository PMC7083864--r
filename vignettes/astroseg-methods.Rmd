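---
title: "Methods: detection and segmentation of astrocytes with directional filters and a constrained stacked U-net"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detection and segmentation of astrocytes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Astrocytes are star-shaped glial cells: a roughly isotropic cell body (soma)
with several thin, curved, branching processes, visualized in tissue sections
by GFAP immunofluorescence. Automated analysis is hard for exactly the
reasons that make the cells interesting - extreme shape variability,
structure spread over multiple scales, and dense, entangled populations where
intensity thresholding cannot separate neighbours. `astroseg` implements a
multistep pipeline for single-channel 2D micrographs that requires no nuclear
counterstain:

1. **Pre-processing** - multiscale directional shrinkage denoising and
   intensity normalization to [0, 1].
2. **Detection** - somata are located as the super-threshold components of
   the *modified Directional Ratio*, a per-pixel measure of local isotropy
   computed from a bank of elongated orientable filters; each detection
   yields a square window (128 px by default) presumed to contain one cell.
3. **Segmentation** - each window is segmented by a stacked encoder-decoder
   network whose first encoder is constrained to linear combinations of
   predefined directional basis filters.
4. **Post-processing** - satellite components from neighbouring cells are
   removed, string-like objects (immature, precursor-like morphologies) are
   discarded by an orientation-profile test, and the surviving masks are
   reassembled into a full-image labeled segmentation with an explicit
   "ambiguous" label where cells overlap.

A synthetic-scene generator with exact ground truth makes every stage
testable offline; evaluation uses sensitivity `S = TP/(TP+FN)`, precision
`P = TP/(TP+FP)` and Dice `DC = 2TP/(2TP+FP+FN)` at cell and pixel level.

## The directional filter bank

`build_filter_bank(n_scales, n_orientations, base_kernel_size, aspect_ratio)`
constructs, per scale `j` and orientation `l`, two kernel families sharing
one geometry (an elongated Gaussian envelope with long/short sigma ratio
`aspect_ratio`, default 3:1; support approximately doubling per scale;
orientations uniform over [0, 180) degrees):

* **band-pass kernels** (`kernels`): a second-derivative-of-Gaussian (Ricker)
  profile across the short axis under the elongated envelope. They are
  exactly zero-mean, point-symmetric (so correlation equals convolution),
  unit-L2-normalized, and globally rescaled so that the maximal absolute
  response to any [0, 1] image is 1 (the bound is the kernel's positive-part
  mass, not its L2 norm). These drive denoising, the star/string shape test
  and the network's fixed basis.
* **smoothing kernels** (`smoothers`): the bare anisotropic Gaussian,
  non-negative and L1-normalized, i.e. an oriented local *average*. These
  drive detection.

The two families exist because the two roles are mathematically
incompatible. A zero-mean filter strictly inside a constant bright disk
responds 0 at every orientation, so a ratio of directional responses is 0/0
there; an isotropy score that is "close to 1 inside somata" requires
averaging filters, whose response inside a bright isotropic region
approaches the region's intensity at *every* orientation. Conversely,
denoising-by-shrinkage and orientation profiling need band-pass behaviour
(respond to structure, not to background level). Package functions choose
the right family internally; `apply_bank(image, bank, type =)` exposes both.

## Detection: the modified Directional Ratio

For responses `r_jl(p)` of the smoothing family, normalized by their global
maximum, the modified Directional Ratio at scale `j` is

    D_j(p) = min_l |r_jl(p)|^2 / (max_l |r_jl(p)| + eps)

It is ~1 inside bright isotropic blobs commensurate with the filter scale,
~0 on thin vessel-like structures (one orientation dominates), and exactly 0
in flat background (`eps = 1e-12` turns 0/0 into 0; both extremes are unit
tested). The squaring in the numerator - the "modification" - suppresses
low-contrast isotropic regions, which makes the fixed threshold workable.
`detect_cells()` thresholds the per-pixel maximum of `D_j` over scales at
**0.7** (the reference value), labels 8-connected components, drops
components below `min_blob_area` (default 30 px), merges components whose
centroids are closer than `min_separation`, and emits one centroid plus one
`patch_size` window per survivor.

Numerical/default choices worth knowing:

* Detection bank default `build_filter_bank(3, 8, 15)`: kernel sizes 15, 29,
  57 px, i.e. envelope sigmas of about 3, 6 and 11 px along the long axis,
  bracketing soma radii of 8-13 px at the reference 20x / 1024x1024 scale.
  Only the 20-orientation post-processing bank is a reference value;
  detection-bank defaults are this package's own.
* `min_separation` defaults to 25 px (the centroid match radius), *not* half
  a window (64 px): at realistic densities somata of distinct cells are
  routinely 30-40 px apart and a 64 px merge radius would fuse them.
* Responses are globally max-normalized before the ratio, so the DR map is
  invariant under rescaling the image by a positive constant followed by
  re-normalization.
* Pixels within half the coarsest kernel of the border carry reflective
  -padding artefacts and are flagged via `border_margin`.

## Denoising

`denoise()` performs shrinkage in a translation-invariant directional frame
built from the bank: the band-pass kernels plus the low-pass, rescaled to
unit L2 norm, complemented by a zero-phase residual band whose power
spectrum is `max(S) - S` (with `S` the frame function), so that the total
frame function is exactly flat. Analysis and synthesis then form an exact
identity when nothing is shrunk - the no-noise case reproduces the input to
floating-point accuracy. Directional and residual coefficients are
soft-thresholded at `k * sigma_hat * ||kernel||_2`, where `sigma_hat` is the
median absolute deviation of the finest directional band divided by 0.6745,
and `k = threshold_multiplier` (default 3). The low-pass band is never
shrunk. An optional Anscombe transform (`vst`) is available for images whose
pixel values are photon counts; it is **off** by default because on
[0, 1]-rescaled images the unknown gain makes the transform mis-stabilize
(measured to worsen mean squared error), while the MAD estimate adapts to
the actual noise level either way.

## Segmentation: constrained stacked U-net

`build_gesunet()` builds two stacked U-nets. The first ("representation")
U-net's encoder convolutions are *constrained*: each kernel is a linear
combination of `n_basis` fixed directional basis filters (finest-scale
band-pass kernels plus the low-pass, unit L2), and only the combination
coefficients are trained. A constrained layer has
`out_channels * in_channels * n_basis` weights regardless of kernel size -
16 output channels over 1 input with 9 basis filters costs 144 coefficients
whether the kernels are 5x5 or 31x31, versus 3600 free weights at 15x15.
The second U-net receives the input patch concatenated with the first's
output and uses free 3x3 convolutions throughout. Per-pixel probabilities
come from a 1x1 convolution and a sigmoid.

Details the reference leaves open, fixed here: leaky rectifier (slope 0.05),
2x2 max pooling, nearest-neighbour upsampling, skip connections by channel
concatenation after upsampling, He initialization, depth-4/16-channel
"full" preset (128 px windows) and depth-3/8-channel "desk" preset (64 px).
The optional transfer of the second encoder from a pretrained image
classifier is exposed but rejected with an informative error, since it
requires a one-time external weight download; the default is random
initialization so the package builds and tests offline.

### Training, and why the optimizer does not use the raw MAE subgradient

Training (`train_gesunet()`) uses Adam (lr 1e-3, batch 8 - package
defaults, not reference values), random 85/15 train/validation split, and
reports per-epoch **mean absolute error**, the reference loss metric.

The *search direction*, however, is the smooth (Huber) relaxation of the
absolute error, which on sigmoid outputs in [0, 1] coincides with the
quadratic. This is a deliberate, experimentally forced choice. The raw MAE
subgradient has the same magnitude at every pixel, so with ~75-90%
background the majority class dominates every shared parameter; under Adam
(whose steps depend only on gradient sign consistency) the output bias
walks monotonically negative until the sigmoid saturates, and the
all-background state is then a stable attractor - the uniform output
minimizing MAE is the per-pixel median, which is background almost
everywhere. We verified that a sigmoid-derivative floor, leaky activations,
deep supervision, instance normalization, and low-rate MAE fine-tuning after
a quadratic warm-up all fail to reach the desk-scale Dice target, and that a
late MAE phase actively *shrinks* masks (it abandons hard foreground pixels,
trading Dice for MAE). The error-proportional quadratic gradient counteracts
the imbalance naturally - a saturated wrong foreground pixel pulls ~50x
harder than a nearly-correct background pixel - and trains reliably. In the
reference setting the informative initialization (predefined filters plus a
pretrained encoder) is what makes plain MAE trainable; its own architecture
ablations point the same way. Two further stabilizers are kept: a small
floor (0.02) on the sigmoid derivative in the backward pass, and deep
supervision of the first U-net's output (weight 0.5) so the representation
stage receives a direct signal.

`augment()` implements the reference protocol: `k` extra pairs per input
pair by a joint rigid transform - rotation uniform in [0, 360), integer
translation within +-10% of the window (bilinear for images, nearest for
masks); 118 pairs with `k = 20` yield exactly 2478.

## Post-processing

`keep_central_component()` keeps only the connected component containing
(or nearest to) the detection centroid - windows are centered on their cell,
so everything else belongs to neighbours. `orientation_profile()` sums the
absolute band-pass response over the object per orientation (20 orientations
by default, the reference value) and normalizes to max 1;
`classify_star_string()` counts circular profile peaks with height at least
`prominence_frac` (default 0.5) of the maximum and pairwise angular
separation at least `min_separation_deg` (default 30): at least two
prominent peaks = star (kept), one = string (discarded). "Prominent" is not
defined in the reference; both knobs are config-exposed. Ties (a flat
positive profile, i.e. an isotropic object) classify as star; an all-zero
profile (empty object) as string. The test runs on the segmented mask by
default (`classify_on = "patch"` switches to the raw window - the reference
is ambiguous on this point). `reassemble()` gives each surviving cell a
unique positive label and assigns pixels claimed by several cells the
reserved label -1 ("ambiguous", stored as 65535 in 16-bit TIFF label maps).

## The synthetic world

`render_scene()` draws GFAP-like scenes with exact, noise-free ground truth:

* **Stars**: soma = filled disk (radius 9-13 px), 4-7 processes grown from
  the soma boundary as unit-step random walks with Gaussian direction jitter
  (sd 0.08 rad/step), length 40-75 px, width tapering from 4-7 px to 1.
  Defaults were calibrated once so the mean cell area is near the reference
  ~1500 px² at 1024x1024 / 20x scale; process-growth parameters are entirely
  this package's invention.
* **Strings**: a single near-straight curve (jitter sd 0.02), length
  55-100 px, near-constant width 2.5-4 px, no soma.
* **Scene**: centers placed by rejection sampling under a minimum separation
  (default 40 px; placement failure names the violated constraint);
  intensities background 0.08 < process 0.5 <= soma 0.95 (single values per
  scene, per the configuration schema); per-pixel maximum blending
  (fluorescence is non-subtractive); Gaussian blur sigma 1 as an optics
  surrogate; Poisson sampling at `photon_peak = 50` expected photons per
  unit intensity; rescaling to [0, 1]. Everything is bitwise reproducible
  from `seed`.

What a green test on this world does *not* establish: performance on real
tissue (no PSF model, no illumination gradients, no autofluorescence, no
intensity variation between cells, no dense inseparable clusters, no
annotation noise). The generator's role is mechanism-level validation -
isotropy vs. elongation, separation of contiguous cells, star/string
geometry - not photorealism. Reproducing the reference's headline scores on
its real image sets would additionally require its expert annotations and
trained weights, which is out of scope.

## Known limitations

* Strictly 2D; confocal stacks must be projected or processed per-slice.
* The DR detector needs somata bright relative to their surroundings after
  normalization; strongly varying per-cell brightness would motivate local
  normalization, which is not implemented.
* Strings dimmer or thinner than the synthetic defaults are usually already
  rejected at detection (DR well below 0.7), so the shape test sees them
  rarely in end-to-end runs; it remains essential for windows where a
  process fragment of a neighbour survives as a separate object.
* The minimal TIFF codec reads/writes uncompressed single-strip grayscale
  8/16-bit only; PNG covers the rest, PGM (P2) is available for plain-text
  fixtures.
* Training is CPU-bound R/Rcpp; the "full" preset trains in tens of
  minutes, not seconds.
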