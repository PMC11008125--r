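---
title: "Measuring transient sickling kinetics from time-lapse microscopy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring transient sickling kinetics from time-lapse microscopy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sicklekin)
```

## The measurement problem

Red blood cells from sickle-cell-disease patients (SS RBCs) deform when the
oxygen tension drops: polymerizing sickle hemoglobin turns a smooth,
near-circular disc into an elongated, spiculated, optically darker cell.
Whether such a cell blocks a capillary depends on the *timing* of this
transition — the per-cell sickling delay time relative to its transit time —
so an assay has to resolve sickling within a physiologically relevant window
of one to two minutes, not after an hour of deoxygenation. The readouts
`sicklekin` produces are (i) per-cell shape-factor and classification time
courses, (ii) the population sickled fraction per frame, and (iii) per-cell
sickling delay times, all under a timed oxygenation protocol of 30 s at high
oxygen, 120 s at low oxygen, and 30 s of reoxygenation (`oxygen_protocol()`).

The package implements the full computational chain — segmentation,
morphometrics, CNN classification, tracking and kinetics — together with a
seeded synthetic image generator. No imaging data ships with the package;
every test and every reported number is computed on synthetic scenes whose
ground truth is known exactly.

## The synthetic generator

`render_cell()` draws one cell as a radial contour

$$ r(\theta) = R\,\bigl(1 + e(s)\cos 2(\theta-\phi)
   + s\,A \textstyle\sum_{k=3}^{8} a_k \cos(k\theta + \phi_k)\bigr), $$

where $s \in [0,1]$ is the sickling degree. The elongation coefficient
$e(s)$ grows linearly from 0.02 to 0.22 and the spicule harmonics (orders
3–8, amplitudes and phases frozen per cell by its texture seed) reach a
total amplitude of $A = 0.25$ at $s = 1$, producing the concave lobes that
pull Convexity and the circular shape factor down. The interior is light and
smooth with a central pallor at $s = 0$ and darkens linearly with $s$ while
gaining band-limited multiplicative texture (smoothed white noise, about
1.5 px correlation length) — the "dark coarse texture" a human annotator
keys on. Both monotonicities (mean intensity down, variance up) are enforced
by construction and asserted in the tests.

Per-cell kinetics are a delayed exponential: during deoxygenation
$s(t) = 1 - e^{-k_s (t - t_{\mathrm{deoxy}} - \tau)_+}$, during
reoxygenation $s$ decays at the faster unsickling rate $k_u \ge k_s$.
Irreversibly sickled cells (ISCs) are pinned at $s = 1$. The population
defaults are the study conditions the suite measures under:

| parameter | default | why |
|---|---|---|
| ISC prevalence | 0.20 | the fraction of cells reading "sickled" in the initial oxygenated state |
| delay time $\tau$ | lognormal, meanlog $\ln 30$ s, sdlog 0.5 | makes both a fast sickler (< 36 s) and a slow sickler (> 56 s) plausible draws; the true in-vitro distribution is not reported, so this is a modeling choice |
| sickling rate $k_s$ | lognormal, meanlog $\ln 0.12$ s$^{-1}$, sdlog 0.25 | full morphological transition in tens of seconds |
| unsickling rate $k_u$ | $k_s \times U(3, 6)$ | unsickling is observed to be much faster than sickling |
| frame size / cell diameter | 720 × 480 px / 90 px | the recording format and magnification of the assay |
| frame interval | 1 s | the source does not state a frame rate; exposed as configuration |
| background / noise | 0.85 / 0.01 (normalized) | light background, mild sensor noise |

`generate_sequence()` places cells by rejection sampling with pairwise
center distance greater than 1.3 × the cell diameter. The non-overlap
contract only requires the distance to exceed one diameter; the 1.3 factor
was fixed at design time, jointly with $e_1 = 0.22$ and $A = 0.25$, so that
fully deformed neighbours do not touch — at larger amplitudes or tighter
packing, merged components broke the segmentation-recall property the suite
asserts. Frames are written as 16-bit grayscale PNG; because no installed R
package writes 16-bit PNG, the package carries a minimal encoder whose
output is verified against an independent decoder.

What the generator does *not* emulate: optical blur and illumination
gradients, cell-to-cell intensity variation beyond the texture model,
overlapping or flowing cells (the assay is hydrostatic; cells get only
sub-pixel jitter, 0.15 px), debris, and focus drift. A classifier trained
here learns the generator's texture/shape contrast, which is deliberately
unambiguous away from $s = 0.5$; passing the suite therefore demonstrates
that the pipeline is correct and self-consistent, not that the trained
weights transfer to real microscopy.

## Segmentation and the exclusion rules

The default segmenter is classical: background estimation by
downscale–blur–upscale, subtraction (cells are darker), Otsu threshold,
hole filling, removal of components below $0.15\,\pi (d/2)^2$, and connected
component labeling. A retrained external model (e.g. Cellpose) can be
plugged in through `segment_with_adapter()`; its output is validated and
relabeled, and everything downstream is segmenter-agnostic.

`filter_cells()` applies three discard rules with reason codes. *Border*:
a component touching a frame edge whose area is below 60% of the median
component area is "majorly located outside the frame" (the source gives no
number; the fraction is configurable). *Clump*: equivalent-circle diameter
above 1.3 × the expected diameter. The union of two merged 90 px cells has
an equivalent diameter of at most $\sqrt 2 \times 90 \approx 127$ px, so a
1.5 factor (135 px) can never fire on a merged pair; 1.3 (117 px) separates
merged pairs (~124 px) from the largest single fully sickled cell (~98 px).
*Debris*: equivalent diameter below 0.4 × expected. Raising the clump
threshold can only reduce clump discards (a property test).

`crop_patches()` cuts a square of side $\lceil 1.5 d \rceil = 135$ px
around each centroid, pads with the background median beyond the frame,
replaces pixels of *other* labeled cells with the background median (each
patch is a single-cell image), and min–max rescales to $[0,1]$; a constant
patch maps to zeros rather than dividing by zero. Coordinates throughout
are 0-based, x right, y down, with half-open bounding boxes.

## Morphometrics

Seven contour factors and two intensity moments per cell:
CSF $= 4\pi\,\mathrm{Area}_r/\mathrm{Perm}_r^2$, ESF $= R_b/R_a$,
SF1 $= R_b/\mathrm{maxFD}$, SF2 $= \mathrm{minFD}/\mathrm{maxFD}$,
Elongation $= \mathrm{maxFD}/\mathrm{minFD}$, Convexity
$= \mathrm{Area}_r/\mathrm{Area}_c$, Compactness
$= 4\pi\,\mathrm{Area}_r/\mathrm{Perm}_c^2$, plus sample skewness and
excess kurtosis (Gaussian $\to$ 0; the convention is not stated in the
source) of the intensities inside the mask (interior rather than whole
patch — also a choice).

Numerical choices that matter:

* **Contours are subpixel.** The mask is lightly smoothed (Gaussian,
  $\sigma = 0.8$ px) and traced at the 0.5 iso-level with a
  marching-squares-style algorithm. Pixel-edge counting would bias the
  perimeter up by ~27% for a disc and push CSF far below 1; the subpixel
  contour recovers disc area within 0.1% and perimeter within 1%. The
  documented pixelation tolerance for the $(0, 1]$ invariants is
  $\varepsilon = 0.03$.
* **Feret diameters** are computed on the convex hull: the maximum as the
  largest pairwise vertex distance, the minimum as the smallest width over
  hull-edge normals (exact for convex polygons). A dense 3600-angle
  projection sweep exists only as a test oracle.
* **Ellipse axes** come from the eigenvalues of the second central moment
  matrix, scaled so a solid ellipse recovers its own axes; $R_a, R_b$ are
  full axis lengths, which makes SF1 equal 1 for a circle (the source's
  wording does not resolve semi- versus full-axis; only SF1 depends on the
  choice).
* Degenerate inputs are explicit errors (empty or multi-component masks,
  collinear polygons, single-pixel masks) or flagged-missing values
  (zero-variance intensities).

`SF2 × Elongation = 1` holds exactly; `Compactness ≥ CSF` because the hull
perimeter never exceeds the contour perimeter; on ≥ 200 rendered cells per
class the CSF and Convexity interquartile ranges of the two classes do not
overlap and every factor is more dispersed in the sickled class.

## The classifier

The network is the assay's 17-layer sequence — C1 P2, C3 P4 D5, C6 P7 D8,
C9 P10 D11, C12 P13 D14, F15, FC16, D17 — with 3 × 3 same-padded
convolutions, 2 × 2 max pooling, ReLU, dropout probability 0.001, and a
2-way softmax with categorical cross-entropy. Per the stated layer order,
the final dropout sits after the fully connected output, before the
softmax; this is unusual but followed literally. FC16 is taken to *be* the
2-unit output layer (the text is ambiguous about a hidden layer; nothing
downstream depends on the choice). The number of kernels per layer is never
stated ("several kernels"); the default is (16, 32, 64, 128, 128),
configurable.

No deep-learning framework exists in this R stack, so the network is
implemented in the package: activations live in a flat
$(H \cdot W \cdot N) \times C$ matrix layout, convolutions are BLAS GEMMs
over compiled im2col/col2im gathers, pooling and bias+ReLU are small
compiled kernels, and the training loop (stratified 80/20 split, per-epoch
shuffling, augmentation of the training set only — ±10% width shift with
edge replication, horizontal and vertical flips — Adam at learning rate
0.001, best-validation-accuracy checkpointing) is R. All randomness flows
through R's RNG, so a seeded run reproduces its history exactly; the
backward pass is verified against finite differences in the tests.

Training patches are produced by `sample_patch_dataset()`, which observes
each synthetic cell **through the same chain the pipeline applies to a
frame**: render at the 90 px assay scale, add sensor noise, center-crop to
135 px, min–max rescale, resize to the model input (bilinear). Matching the
observation model matters: a classifier trained on clean, unrescaled
renders misreads noisy rescaled pipeline crops. Labels follow the
ground-truth rule — sickled iff $s > 0.5$ or ISC — a mid-scale surrogate
for the human visual annotation used on real data.

The desk-scale profile used by the tests and the acceptance script is
64 × 64 inputs, 2 000 patches per class, batch 32, and 3 epochs — the
classes are well separated, so validation accuracy plateaus around 0.99
within two epochs. The full-scale configuration (256 × 256, 500 epochs)
remains available through the same functions. The fusion variant
(`fuse_shape_factors()`) concatenates four standardized shape factors to
the flattened features before FC16 and trains identically.

## Tracking, kinetics, delays

Cells are static (hydrostatic assay), so `link_tracks()` uses greedy
nearest-centroid matching with a 15 px gate (about a sixth of a cell
diameter), ties broken by distance then lowest track id; no motion model.
`sickled_fraction_curve()` counts, per frame, tracked cells labeled sickled
after per-track majority-vote smoothing (centered window of 3 frames, to
suppress classifier flicker); frames with no cells report a missing
fraction, and per-frame denominators are over currently tracked cells.
`delay_time()` calls a cell sickled at the first post-onset frame where the
smoothed label persists for 3 consecutive frames; cells already sickled at
onset are ISCs (delay 0, flagged), and cells that never meet the
persistence rule are right-censored at their last observed frame rather
than assigned the window length, so delay summaries stay honest.
`compare_conditions()` aligns conditions recorded under one protocol:
fraction at the end of deoxygenation, median uncensored non-ISC delay, and
censoring rate. No hypothesis testing is attached — the readout is the
curves themselves.

## Problem sizes used by the test suite and acceptance script

The suite reproduces the headline numbers as scaled-down surrogates, all
seeded: the classifier criterion trains on 2 000 synthetic patches per
class at 64 × 64 for 3 epochs; the ISC-floor criterion runs the full
pipeline (segment → classify → track → kinetics) over five 60-cell fields
of 1800 × 1200 px sampled at 10 s intervals and reads the first-frame
sickled fraction of the pooled 300 cells; delay recovery uses 300 cells at
1 s frames with both a ground-truth-label oracle and the trained CNN (for
the CNN pass, frames of one cell sharing the same sickling degree to two
decimals share one rendered patch and one prediction — the texture is
frozen per cell, so this is exact up to a ≤ 0.1 s shift in crossing times).
The treated-versus-vehicle comparison applies the treatment as a paired
transform (delays × 2, rates × 0.5 on the same cells), which makes the
at-or-below ordering of the curves deterministic rather than a coin-flip
between two independent 300-cell draws.

## Known limitations

* The kinetic form is phenomenological; no HbS polymerization physics,
  oxygen diffusion, or membrane mechanics.
* The classifier's reported performance is on synthetic imagery; real
  deployments should retrain on annotated patches (the training contract
  accepts any labeled patch set).
* Overlapping cells are excluded, not split; there is no watershed.
* One oxygenation cycle per sequence; cyclic hypoxia protocols are out of
  scope.
* Fraction denominators follow currently tracked cells, so segmentation
  dropouts shrink the denominator rather than being imputed.

## A minimal session

```{r example, eval = FALSE}
library(sicklekin)

protocol <- oxygen_protocol()                  # 30 s O2 / 120 s N2 / 30 s O2
scene <- scene_spec(n_cells = 12, seed = 1)
seq <- generate_sequence(scene, protocol)

ds  <- sample_patch_dataset(400, seed = 2)
fit <- train_cnn(build_cnn(input_size = 64, seed = 3), ds$x, ds$y,
                 config = train_config(epochs = 4, seed = 4))

res <- analyze_sequence(seq$frames, fit, protocol)
head(res$curve)          # t, n_total, n_sickled, fraction
head(res$delays)         # track_id, delay_s, censored, isc
```
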