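---
title: "Restoring incomplete fan-beam sinograms with a residual U-net"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Restoring incomplete fan-beam sinograms with a residual U-net}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

X-ray computed tomography reconstructs a 2-D attenuation map
$\beta(x, y)$ from its line integrals
$P(w, \phi) = \int \beta\,\mathrm{d}l$, collected as a *sinogram*
indexed by rotation angle $\phi$ (views) and detector channel $w$.
Filtered back-projection (FBP) inverts complete data fast and accurately,
but real acquisitions are often incomplete: *sparse-view* scans keep only
every $k$-th view (streak artifacts), *limited-angle* scans cover only a
sector such as $[0, 120^\circ]$ (directional shading and distortion).

`fanrec` implements a learned reconstruction chain for such data that
works in the *projection domain* rather than the image domain:

1. zero-fill the incomplete sinogram to the full scan grid and
   reconstruct an initial image with fan-beam FBP;
2. forward-project that image back to a full-size, *corrupted* sinogram;
3. restore the corrupted sinogram toward the complete one with a
   residual U-net;
4. reconstruct the final CT image from the restored sinogram with FBP.

Because the network's estimate is a complete sinogram and not a final
image, a local estimation error is averaged over many rays by the final
FBP, which makes the chain tolerant to learning bias.

## Physical model and geometry

The scanner model is 2-D equi-spaced fan-beam: a point source on a
circle of radius $D$ (default 2700 px for a 512-px grid) and a virtual
flat detector through the rotation centre with unit channel pitch.
The full scan has 720 views over $[0^\circ, 360^\circ)$ (0.5° steps,
endpoint-exclusive) and 731 channels. Scaled profiles derive the channel
count as the smallest odd number covering the fan-projected circumscribed
circle, $2\lceil D R_c / \sqrt{D^2 - R_c^2}\rceil + 1$ with
$R_c = (n/2)\sqrt 2$; a 128-px grid gives 180 views x 185 channels and a
64-px grid 96 x 93.

Reconstruction follows the standard weighted FBP for this detector:
cosine pre-weight $D/\sqrt{D^2 + w^2}$, convolution with the band-limited
ramp (Ram-Lak) kernel — centre tap $1/4\tau^2$, odd offsets
$-1/n^2\pi^2\tau^2$, even offsets zero — applied as a direct spatial
convolution, then pixel-driven back-projection with the $1/U^2$ distance
weight and a final $\Delta\phi/2$ scale. Pixels outside the inscribed
circle are cut off. Direct convolution (rather than FFT filtering) was
chosen so the filter is exactly the closed-form kernel, with no dialect
differences in padding or normalisation; at 731 channels it costs well
under a second per sinogram because zero rows of embedded incomplete
sinograms are skipped.

**Angular weight for incomplete data.** Zero-filled sinograms are
reconstructed with $\Delta\phi = \text{angular range}/n_\text{measured}$:
each measured view stands in for its share of the scan. This is the
convention of standard fan-beam tools fed with subsampled data; it keeps
sparse-view and limited-angle reconstructions on the correct attenuation
scale (we verified that the native full-scan weight instead leaves a
$[0,120^\circ]$ reconstruction about 3x low, which would also clamp the
network's de-normalised output to a wrong scale downstream). The missing
sector of a limited scan simply contributes nothing.

## The synthetic world

Reference data are random ellipse phantoms: each 512x512 phantom is
"tens of ellipses" — count uniform on $[10, 40]$ — with additive
attenuations uniform on $(0, 1]$, semi-axes uniform on
$[\text{grid}/32, \text{grid}/6]$, orientation uniform on $[0, \pi)$, and
centres uniform on the disk that keeps each ellipse inside the inscribed
support disk. The source protocol states only "random attenuation
coefficients, sizes, and locations"; these distributions are this
package's documented defaults, chosen once so that a typical phantom has
moderate overlap and order-one attenuation, and not revisited. Notably,
direct-FBP baselines over 100 such phantoms land within ~0.5 dB of the
published sparse-view baseline table, which suggests the stand-in
distributions are a reasonable proxy — but they remain assumptions, and
absolute aPSNR values depend on them.

Phantoms are projected *analytically*: the fan-beam integral of an
ellipse is its chord length times its attenuation, in closed form, so the
reference sinogram carries no raster error. A raster Joseph-style
projector (bilinear interpolation, 0.5-px steps) provides the independent
cross-check (they agree to 0.26 % relative RMS at 512 px) and generates
the corrupted sinograms inside the pipeline. Its exact adjoint is also
implemented, which lets the test-suite verify
$\langle A I, S\rangle = \langle I, A^\top S\rangle$ to machine
precision.

What a green test does *not* establish: anatomical realism (phantoms are
piecewise-constant ellipse unions), noise robustness (projections are
noiseless), or the published aPSNR of the fully trained framework (see
below).

## The network

The restorer is a 27-layer residual U-net on 720x731 sinograms
(64 base channels, depth 4): three 3x3 convolutions, four encoder stages
(2x2 stride-2 convolution that doubles channels, then a 3x3 convolution),
four decoder stages (3x3 stride-2 transposed convolution, concatenation
with the matching encoder map, two 3x3 convolutions), a linear 1-channel
3x3 convolution, addition of the network input, and a whole-map
standardisation $(I - \mathrm{mean})/\mathrm{std}$. Odd axes ceil-halve
on the way down (731 → 366 → 183 → 92 → 46) and the paired transposed
convolution restores them exactly by forcing its output size.

Choices the source leaves open, and what this package does:

* **Activations / per-layer normalisation** are unstated in the layer
  table; we use batch normalisation + ReLU after every convolution except
  the final 1-channel one (linear), consistent with the stated use of
  batch normalisation. With batch size 1 — the published operating
  regime — batch statistics degenerate to per-feature-map statistics, in
  training and inference alike, which keeps inference deterministic.
* **Down-sampling** is a trainable full 2x2 stride-2 convolution whose
  channel count doubles in the same layer, as the layer table requires;
  the max- and mean-pooling ablation variants pair the fixed pooling with
  a 1x1 channel-doubling convolution so every tabulated shape is
  preserved. The stand-alone `downsample()` operator exposes the
  per-channel four-coefficient filter; with all coefficients $1/4$ it
  reproduces mean-pooling exactly (mean-pooling therefore treats
  out-of-range window positions at odd edges as zeros).
* **Output rescaling.** Inputs and targets are standardised
  ($(I-\mu)/\sigma$, population $\sigma$); the restored sinogram is
  mapped back to physical units with the *corrupted input's* statistics,
  the only ones available at inference time. With the angular-weight
  convention above the corrupted sinogram sits on the complete sinogram's
  scale, so this inversion is benign.
* **Initialisation** draws each weight from
  $\mathcal N(0,\, 2/(n_\text{in} + n_\text{out}))$ with
  $n = \text{kernel area} \times \text{channels}$; biases zero.

The network, its backward pass and the optimiser are implemented natively
(im2col convolutions through compiled code, hand-derived gradients for
batch normalisation, pooling, transposed convolution and the residual /
normalisation head) because no deep-learning framework is assumed; the
transposed convolution is implemented exactly as the adjoint of a 3x3
stride-2 convolution, so its gradient is a plain convolution. Gradients
are verified against central finite differences at $10^{-4}$ relative
tolerance. Biases of convolutions that feed batch normalisation have an
exactly zero loss gradient (the mean subtraction absorbs them); they are
kept because the source trains biases, and they are harmless.

## Training

Loss is $E = \frac{1}{2m}\sum (Y - \hat Y)^2$ over all grid entries with
batch size $m = 1$. Updates use Nadam (Adam with Nesterov momentum,
canonical constants $\beta_1 = 0.9$, $\beta_2 = 0.999$,
$\epsilon = 10^{-8}$, recorded in `train_config()`). The learning rate
starts at $10^{-4}$ and decays as
$\text{rate} \times 0.1^{\lfloor \text{step}/20 \rfloor}$. Two readings
were open here:

* "decay rate is 10 %" is read as multiplicative factor 0.1 per stage
  (the exponential-decay semantics the source cites); the $\times 0.9$
  reading stays available through `train_config(decay_rate = 0.9)`.
* The "global step" is taken as the outer-iteration (epoch) index, so the
  50-epoch schedule traverses $10^{-4}, 10^{-5}, 10^{-6}$; a per-batch
  step with 200 pairs would collapse the rate within the first epoch and
  nothing would train.

Pair order is shuffled each epoch under the run seed (deterministic
reproducibility); training aborts with the epoch and pair index if a loss
goes non-finite.

## Scaled-down evaluation

The published experiments train 200 full-size pairs for 50 outer
iterations (~9 GPU-hours); the package's tests must run on one CPU in
minutes. The test suite therefore uses a reduced profile — 64-px
phantoms, 96x93 sinograms, 8 base channels, depth 2, 20 training and 20
held-out phantoms, 30 epochs — which preserves every architectural
relation (ceil-halving, channel doubling, skip pairing, residual head)
and the information ratio of the degradations (factor 8 of a 96-view scan
vs factor 8 of a 720-view scan). At this scale the claims checked are
*directional*: the trained chain strictly beats direct FBP, in sinogram
and image aPSNR, for a sparse-view and a limited-angle condition, and
for all three down-sampling variants. Absolute full-size aPSNR values of
the trained framework are training-budget-dependent and are not asserted;
the untrained FBP baselines *are* asserted at full size against the
published table within a few dB.

## Numerical notes and limitations

* The PSNR definition printed in the source,
  $20\log_{10}(\mathrm{MAX}/\mathrm{MSE})$, is read as the standard
  $10\log_{10}(\mathrm{MAX}^2/\mathrm{MSE})$ (equivalently
  $\mathrm{MAX}/\sqrt{\mathrm{MSE}}$ inside the log); the literal reading
  double-counts the MSE exponent and is inconsistent with dB magnitudes
  of the published tables. $\mathrm{MAX}$ is the per-image maximum of the
  ground truth; image-domain PSNR is computed inside the reconstruction
  support circle only. Identical images report `Inf`.
* Whole-map standardisation errors out below $10^{-12}$ standard
  deviation (constant input) rather than dividing by ~0.
* Rasterisation uses a pixel-centre membership test (no anti-aliasing);
  its area converges to $\pi a b$ with resolution and the 1 % area check
  is part of the suite.
* Attenuations are drawn positive; the generator does not model negative
  contrast, 3-D phantoms, detector noise or beam hardening. The
  image-domain deep-learning baseline the source compares against is
  exposed only as a plug-in hook (`cmd_evaluate(image_corrector = )`),
  not re-implemented.
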