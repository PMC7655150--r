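---
title: "Camera-based vital-sign monitoring: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Camera-based vital-sign monitoring: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Pre-term infants in intensive care need continuous vital-sign monitoring,
but adhesive ECG electrodes and pulse-oximetry probes damage their fragile
skin. A video camera above the incubator can recover the same information
without contact: cardiac pulsation appears as a sub-percent intensity
modulation of the skin (photoplethysmographic imaging, PPGi, strongest in
the green channel), and breathing appears as slow geometric change of the
visible skin region. Neither signal is usable unless two questions are
answered continuously: *where* is the skin, and *when* is the scene
clean — the patient present and nobody reaching into the incubator.

`vitalcam` implements that whole chain: a multi-task convolutional network
for joint patient detection and skin segmentation; a sliding-window
two-stream classifier that finds clinical-intervention periods from skin
confidence and optical flow; a semi-automatic annotation engine (graph cut
with geodesic star convexity, GMM label propagation, multi-annotator
consensus); PPGi/respiratory extraction with rate estimation by peak
counting; and a deterministic scene simulator so that everything can be
trained and validated without clinical recordings.

## Patient detection and skin segmentation

One shared convolutional core feeds two heads. The core is a VGG-style
stack of 3x3 convolutions; batch normalization sits between every
convolution and its ReLU, and each stage ends in 2x2 max pooling, for an
overall subsampling factor of 32 (a 512 px input reaches a 16x16 grid, a
64 px input 2x2).

* **Detection head**: a 1x1 convolution with two outputs on the last
  pooling stage, global average pooling, then softmax — the probability
  pair \((p_{\text{absent}}, p_{\text{present}})\).
* **Segmentation head**: 1x1 score convolutions on pooling stages 3, 4
  and 5 are fused FCN-style — the coarsest prediction is upsampled x2 by
  a transpose convolution and added to the stage-4 scores, upsampled x2
  again and added to stage 3, then upsampled x8 to full resolution; a
  per-pixel softmax yields the *skin confidence map*. Transpose
  convolutions start as bilinear interpolation filters with no bias.

Execution is conditional: the segmentation head runs only when
\(p_{\text{present}}\) reaches the detection threshold (default 0.5; the
threshold is a free parameter of the deployment, so it lives in the
configuration).

**Losses.** Detection uses the multinomial logistic loss
\(-\log p_{\text{true}}\). Segmentation uses the same per-pixel loss, but
summed with class-balanced weights \(w_p = 1/(2\,f_{c(p)})\), where
\(f_{c}\) is the frequency of pixel \(p\)'s true class in the ground
truth. This normalization was chosen so that a uniform predictor scores
exactly \(\ln 2\) on any two-class truth and so that the loss is
invariant to class imbalance — skin typically covers a small fraction of
the frame. Images containing a single class fall back to the plain
per-pixel mean. Probabilities are clamped at \(10^{-12}\) so a confident
mistake is expensive but finite. The joint objective is the weighted sum
of the two losses, weighted equally by default.

**Two-stage training.** Stage 1 trains the core and segmentation head on
positive (patient-present) images only: SGD with momentum 0.90, batch 20,
learning rate starting at \(10^{-2}\) and dropping tenfold on a fixed
epoch schedule. Stage 2 trains all layers jointly on positive and
negative images with the rate starting at \(10^{-4}\); negatives use an
all-non-skin segmentation target. The default decay period is two epochs,
which presumes a core initialized from pretrained weights that only needs
fine-tuning. The tiny from-scratch backbone used at desk scale learns
nothing after the rate collapses, so the package's own training runs keep
the same staged procedure but stretch the decay period to 12 epochs and
start stage 2 at \(10^{-3}\); both knobs are plain `training_schedule`
arguments, and the defaults remain the fine-tuning values.

**Backbones.** `vgg16` reproduces the full 13-convolution topology with
the fully-connected layers converted to convolutions (their width is
configurable). `tiny` is the desk-scale variant: five single-conv stages
of 8-32 filters preserving the subsampling-by-32 arithmetic, so every
shape contract of the full network holds at a 64 px input. All
convolutions are Xavier-initialized with zero biases. Loading pretrained
VGG16 weights is supported in principle but treated as an external asset;
nothing in the package requires it.

## Intervention detection

A 5 s window slides over the recording in 1 s steps; each window samples
6 frames one second apart, giving 56 windows for a 60 s recording. Two
input stacks describe a window:

* **context**: the 6 skin-confidence maps, stacked as channels;
* **motion**: the 5 optical-flow fields of consecutive frame pairs, their
  horizontal and vertical components interleaved in temporal order
  (u1, v1, ..., u5, v5) — 10 channels.

Flow is stored through a deliberately lossy 8-bit codec: each component
is clipped to ±40 px (one-second displacements beyond that are rare) and
mapped linearly onto 0..255, with round-half-up so zero maps to code 128.
The classifier is trained on decoded values, i.e. on exactly what
deployment-time storage provides. Quantization error is at most 80/255/2
≈ 0.157 px per component in a lossless container.

Each stack feeds its own backbone whose first convolution is adapted to
the channel count by *cross-modality initialization*: the original
kernels are averaged over their input-channel dimension and the average
replicated across the new channels. The two feature maps are
concatenated, reduced by a 1x1 convolution with 512 outputs (ReLU),
globally average-pooled, and classified by a two-output softmax.

Training again has two stages with balanced class sampling every
iteration: stage 1 trains each stream separately under its own
pooling + fully-connected head (rate \(10^{-3}\), tenfold drop every
12 000 iterations, batch 24); stage 2 freezes everything before the
fusion and trains only the fused layers (default rate \(10^{-5}\), drop
every 6 000 iterations, batch 12). The defaults again assume pretrained
streams; the desk-scale runs raise the stage-2 rate to \(10^{-2}\)
because the fusion layers start from random initialization. Window
training labels follow a strict majority rule — a window is
*intervention* iff more than half of its labelled time is — and windows
overlapping patient absence are excluded.

At prediction time every second receives the mean `p_intervention` of all
windows covering it and becomes `intervention` at 0.5. How overlapping
window scores combine into the per-second decision is genuinely open; the
mean is the least-committal aggregation and keeps the timeline a pure
function of the window scores. Detection-branch absence takes precedence
over everything, making the three per-second states mutually exclusive
and exhaustive. Windows that overlap patient-absent frames are never
scored — exactly as they are excluded from training — because the
appearance or disappearance of the patient produces large apparent
motion the classifier has never been asked to interpret; their seconds
fall back to `absent` or `valid`.

## Semi-automatic skin annotation

The annotation engine is a classical interactive graph cut with a
geodesic star-convexity (GSC) shape prior:

* **Unary terms**: negative log-likelihoods of two Gaussian mixtures (by
  default 5 components per class, diagonal covariances, fitted with
  `mclust`; degenerate inputs fall back to a moment fit with a variance
  floor) learned from the seed strokes.
* **Pairwise terms**: the contrast-sensitive boundary cost
  \(\lambda\, e^{-\beta\lVert c_i - c_j\rVert^2}/\mathrm{dist}(i,j)\) on
  the 8-connected grid, with \(\beta\) set to the reciprocal of twice the
  mean squared neighbor color difference.
* **Shape prior**: on a geodesic metric weighted by gradient magnitude,
  every pixel's predecessor towards the nearest star center receives an
  infinite-capacity edge, so a finite cut can never make skin membership
  non-monotone along geodesics. The minimum cut is computed exactly
  (`igraph`); with \(\lambda = 0\) and the prior disabled the solution
  provably degenerates to per-pixel likelihood classification, which the
  tests exploit as an oracle.

Labels propagate to the next frame by fitting per-class color mixtures to
the previous label, scoring the new frame, and placing seeds inside
high-confidence regions (posterior ≥ 0.9) with Mitchell's best-candidate
sampling, which spreads seeds much wider than uniform placement. Three
annotators are combined by quorum: an image is positive if at least two
supplied labels, and a pixel is skin if at least two of the suppliers
marked it. Agreement is the ratio of ≥2-vote pixels to ≥1-vote pixels
(an empty union scores 1).

## Vital-sign extraction

The PPGi waveform is the spatial mean of the green channel over the skin
mask, frame by frame; respiratory signals are the area (default),
centroid and perimeter of the mask. Samples from empty-mask frames, and
all samples inside absent or intervention seconds, are flagged invalid —
values are kept, so masking is non-destructive.

Rates come from counting peaks: the series is detrended by subtracting a
moving-average baseline whose window is twice the slowest period of the
physiologic band, lightly smoothed (3-sample average), and local maxima
are kept if separated by at least \(60/\text{max rate}\) seconds and at
least a quarter of the detrended amplitude high. The rate is
\(\text{peaks} \times 60 / \text{duration}\). Default bands are neonatal:
90-240 min\(^{-1}\) cardiac, 20-120 min\(^{-1}\) respiratory; analysis
segments default to 30 s. Plateau maxima (common in pixel-quantized area
series) are counted once.

## The scene simulator

`generate_recording()` renders the minimal scene with the statistical
structure the pipeline needs: a skin-colored ellipse on a darker
background whose green channel is modulated by ~1% at the cardiac
frequency, whose area breathes at the respiratory frequency (axes scaled
by \(\sqrt{1 + a\sin 2\pi f t}\) so the *area* modulation is exactly
sinusoidal), a slow sinusoidal illumination drift, additive Gaussian
pixel noise (default sd 1 intensity unit, so segmentation is not a
thresholding exercise), patient-absence intervals that empty the scene,
and intervention events rendered as a large block in a distinct chroma
sweeping at 48 px/s — fast enough that one-second flow exceeds the 40 px
codec clip. Everything is a pure function of the configuration and seed.

What it does **not** model: real skin texture and tone diversity,
specular reflection, phototherapy lighting, camera noise statistics,
partial occlusion by bedding, or motion of the infant itself. Passing the
synthetic recovery tests therefore demonstrates that the implementation
is correct and trainable — that gradients, losses, schedules, codecs and
bookkeeping do what they claim — not that the tiny networks would reach
clinical accuracy on real recordings.

## Numerical and design choices

* Letterboxing pads with black *before* mean subtraction; landscape
  sources pad top/bottom, portrait left/right, odd remainders go to the
  bottom/right. The pixel grid is 0-based with half-open boxes.
* Lightness augmentation scales the HSL L channel multiplicatively and
  clips to the valid range; rotations keep the canvas and fill exposed
  corners with black; masks always use nearest-neighbour resampling.
* Lighting-model intervals with no corpus images fall back to their
  midpoints, keeping the four means strictly increasing.
* Flow codec rounding is round-half-up; the clip limit and mapping
  endpoints travel in a YAML sidecar so decoding is bit-exact.
* The dense flow solver is a coarse-to-fine variational scheme
  (Horn-Schunck smoothness with incremental warping, smoothness weight
  0.05 on unit-scaled intensities, 3 warps x 60 relaxations per level);
  the backend is pluggable and the codec/stack layers accept any dense
  field.
* Batch normalization uses batch statistics in training and running
  averages (momentum 0.1) at inference; epsilon 1e-5.
* Problem sizes used by the package's own validation runs: 64 px frames,
  200 training / 50 held-out frames and 30 epochs for segmentation
  (held-out IOU ≥ 0.85), 400 training / 80 held-out windows and 300
  iterations per stage for intervention detection (held-out accuracy
  ≥ 0.9), 30 s recordings for rate recovery (±2 min\(^{-1}\)). These
  sizes make the full suite runnable on a single CPU in minutes while
  leaving every contract of the full-scale configuration intact.

## Known limitations

* No video-container demuxing: recordings are image-sequence
  directories (PNG/JPEG). Containers would add an external dependency
  without changing any algorithmic behaviour.
* The `resnet50` stream backbone is a configuration point that expects
  externally supplied pretrained weights; the from-scratch `tiny`
  backbone is the supported desk-scale path.
* Rate estimation is strictly time-domain (peak counting), matching the
  monitor-style presentation; no spectral estimator is provided.
* SpO2 estimation and comparisons against contact reference signals are
  out of scope.
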