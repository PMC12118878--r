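---
title: "Methods: single-pulse photoacoustic denoising with a conditional GAN"
author: "PADenoise"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-pulse photoacoustic denoising with a conditional GAN}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Molecular photoacoustic (PA) imaging with exogenous dyes such as ICG is
dose-limited: every laser pulse both generates signal and photobleaches
the chromophore. Acoustic-resolution PA microscopy conventionally averages
20–30 pulses per scan position to reach a usable SNR, multiplying the
delivered dose and hence the bleaching. PADenoise implements the
alternative: acquire a single pulse per position and restore SNR
computationally with a conditional GAN, so the bleaching stays at the
single-pulse level while image quality approaches the averaged
acquisition.

The restorer is a Pix2Pix-style conditional GAN. The generator G maps the
noisy observation $x$ (with stochasticity $z$ realized through dropout,
the standard Pix2Pix convention — there is no explicit noise tensor) to an
estimate of the clean label $y$. The discriminator D scores
channel-concatenated $(x, \cdot)$ pairs patch-wise. The combined
objective is

$$G^* = \arg\min_G \max_D \; L_{cGAN}(G,D) + \lambda\,L_h(G) + \lambda\,L_{SSIM}(G)$$

with $\lambda = 100$; $L_h$ is the Huber penalty with threshold
$\delta = 1$ (quadratic for residuals up to $\delta$, linear beyond, so
single outlier pixels cannot dominate), and $L_{SSIM} = 1 - \mathrm{SSIM}$
emphasizes local structure where pixel-wise losses have vanishing
gradients. One weight $\lambda$ multiplies both reconstruction terms, as
the objective above states.

## Architectures

**Generator.** A U-Net of kernel-4 stride-2 convolutions. Channel widths
double from `baseFilters` up to a factor-8 cap; the default depth
`nLevels = log2(side) − 1` stops at a 2×2 bottleneck (a 1×1 bottleneck is
available via `nLevels = log2(side)`, in which case the normalization of
that block is skipped automatically, since per-image statistics of a
single spatial sample are degenerate). The first encoder block carries no
normalization. Dropout (p = 0.5) sits in every encoder block after the
first three and every decoder block except the last three; it is applied
between normalization and activation. Decoder blocks are transposed
convolutions with skip *concatenations* from the mirror encoder level
(concatenation, not addition, is the Pix2Pix reading of "residual skip
connections"). Hidden activations are ReLU with batch normalization — the
combination adopted as the default — with a
leaky-ReLU option exposed in `generatorSpec()`. The final layer is a
tanh; all network-facing tensors live in $[-1, 1]$ and the
training/inference wrappers own the rescaling from the $[0,1]$ storage
convention. Weights initialize from a truncated normal with
$\mathrm{sd} = \sqrt{2/\mathrm{fan~in}}$ (he-style, truncated at two
standard deviations).

**Discriminator.** The PatchGAN stack `discriminatorSpec(256)` — widths
64, 128, 256, 512 plus a one-channel head, strides 2,2,2,1,1, kernel 4,
padding 1, no normalization in the first block, ReLU in hidden blocks and
a leaky rectifier (slope 0.2) on the head — classifies a 30×30 map of
patches for a 256×256 pair, each map unit tracing back to a 70×70 input
region. Both facts are verifiable at run time: `patchReceptiveField()`
composes the kernel/stride chain ($r_i = r_{i+1} s_i + k_i - s_i$), and
`gradientFootprint()` confirms it empirically by backpropagating from a
single output unit. Adversarial losses are computed from logits for
numerical stability; `discriminatorScores()` exposes the post-sigmoid
map. Inputs smaller than the receptive field are rejected, so
`discriminatorSpec()` selects reduced stacks for small images (receptive
fields 34 px at side 64 and 16 px at side 32).

**Normalization at batch size 1.** Training uses per-image (instance)
statistics, which is what batch normalization degenerates to at batch
size 1; the generator keeps those semantics at inference, the standard
Pix2Pix behaviour. The discriminator's inference mode instead freezes the
normalization to a per-channel affine map: this matters only for the
receptive-field probe, where per-image statistics would couple every
output unit to every input pixel and mask the conv stack's locality.

## Training

Per step (batch size 1): one discriminator update on the binary
cross-entropy of the real-pair score map against ones plus the fake-pair
map against zeros, then one generator update of the combined objective
against the freshly updated discriminator — the conventional Pix2Pix
schedule (the interleaving itself is a convention, not part of the
objective). Adam uses learning rate 1e-4, $\beta_1 = 0.5$,
$\beta_2 = 0.999$, $\epsilon = 10^{-7}$ for both networks, with no decay
(only an *initial* rate is specified; the rate is held constant). Samples
are visited in reshuffled epochs derived from the run seed; weight
initialization, shuffling and dropout are all functions of
`trainConfig(seed=)`, so runs are bit-reproducible. Any non-finite loss
aborts with a diagnostic. The per-step log records every objective
component, and `totalG` always equals
`lAdv + lambdaDl*(lHuber + lSsim)`. The supervised U-Net baseline trains
the same skeleton with mean absolute error and conventional Adam moments
($\beta_1 = 0.9$).

Two profiles are documented: the *full-scale* profile (256×256 images,
base 64 filters, 40,000 steps) and the *desk-scale* profile used as the
package default (64×64, base 32, 2,000 steps, 200 pairs), which trains in
tens of minutes on one CPU. The automated test suite uses a further
reduced *test-scale* benchmark — 32×32 images, base 16 filters, 1,500
steps, 32 training pairs, with held-out fiber targets and the signal box
aligned to the stroke — chosen so the whole suite, including three
trained models, completes in a few minutes. These sizes are the package's
own test-size choices; all architectural and objective facts are
asserted exactly at full scale.

## Synthetic study conditions

No LED-system or AR-PAM acquisitions ship with the package; the
`phantoms` module defines the study conditions synthetically:

* **Geometries.** `tube_cross_section` renders the two bright wall arcs a
  dye-filled polyethylene tube shows in B-mode (a Gaussian-profile ring
  weighted by the squared cosine of the wall angle to the axial
  direction); `fiber` renders a thin stroke whose thickness parameter is
  the full width at half maximum, so its above-half-max pixel count has a
  closed form used as a rasterization oracle; `vessel_tree` renders
  seeded meandering branches. Rendered fields are rescaled so the maximum
  equals the declared amplitude exactly.
* **Frame averaging.** Paired samples follow the averaging law: residual
  noise std $\sigma/\sqrt{F}$ for $F$ averaged frames, with the defaults
  mirroring 128-average inputs against 25,600-average labels at
  per-frame $\sigma = 0.5$. The averaged Gaussian field is drawn directly
  from its exact distribution rather than by materially summing up to
  25,600 frames. Inputs and labels are spatially aligned by construction.
* **Bleaching kinetics.** Point-exposure measurements of aqueous ICG
  typically show aggregate amplitude drops around 35% over prolonged
  exposure, which constrains the scale of the effect but not a rate law. The
  simulator adopts the simplest photochemistry consistent with a
  consistent decrease over time: mono-exponential per-pulse decay, where
  a pulse delivered at lateral position $x_j$ multiplies the local dye
  concentration at $u$ by $1 - \beta\, g(u - x_j)$, $g$ a unit-peak
  Gaussian beam of 1/e² radius `beamSigmaMm`. The default beam radius is
  twice the 100-µm scan step, reflecting the broad optical illumination
  of acoustic-resolution systems; the overlap is what pre-bleaches
  positions before their own scan, and $\beta$ is a free parameter,
  never hard-coded to reproduce any particular percentage. Within an n-pulse
  average, bleaching applies between pulses, so averaged frames reflect
  mid-decay amplitudes — this is why multi-pulse averaging is both
  brighter and more bleaching. `simulatePointExposure()` gives the
  noiseless point-exposure trace $A_0 (1-\beta)^k$; at
  $\beta = 10^{-3}$, 430 pulses reproduce the ~35% scale of drop without
  claiming the real kinetics.
* **Quantification.** Photobleaching percentage is
  $100\,(1 - A_k/A_{\mathrm{ref}})$ against the scan-start position,
  floored at zero with the raw value retained. The headline percentages
  in `bleachingExperiment()` are computed from the *dose trace* (the
  noiseless concentration amplitudes), which depends only on the
  illumination schedule; this makes the single-pulse and
  denoised-single-pulse modes identical by construction — denoising
  changes SNR, never dose — while the peak amplitudes of the noisy and
  denoised frames are also reported.

Seeding everywhere follows one scheme: a master seed plus a fixed counter
derivation per sample, so datasets are order-independent and every
generator is a pure function of its arguments and seed, leaving the
caller's RNG stream untouched.

## Noise operators and characterization

The four injectors are additive Gaussian (`sigma`), scaled-count Poisson
(`out = Poisson(img*scale)/scale`, variance mean/scale; image-domain
Poisson noise has no canonical parameterization, so the scale is exposed),
salt-and-pepper (an exact `round(density*N)` pixel count, salt/pepper
assignment Bernoulli(½)), and multiplicative uniform speckle
(`img*(1+u)`, $u \sim U(-a,a)$, $a = \sqrt{3\,\mathrm{var}}$). None clips
before measurement; clipping happens only at file write.

Noise profiles are $\log(1 + |\mathrm{FFT}|^2)$ — the $+1$ keeps empty
bins defined — zero-frequency centred by quadrant swap, with no windowing.
Normalization divides the *log-compressed* spectrum by its maximum
(pre- and post-log normalization are both defensible; post-log was
chosen for dynamic-range comparability). Cross-power spectra are
$\log(1+|F_a \bar F_b|)$ on the same centring, and profile similarity is
the Pearson correlation of the row-major-flattened log spectra:
correlations well below 0.8 indicate dissimilar noise, the regime in
which cross-platform transfer is a meaningful claim.

`estimateNoiseSigma()` is the one-level Haar diagonal-detail MAD
estimator (Donoho–Johnstone): diagonal wavelet coefficients of a smooth
image are noise-dominated and the MAD/0.6745 rescaling is robust to
structure. It serves as the sigma front end for BM3D; all images here are
single-channel, so a single-channel estimator is the natural choice.

## Quality metrics

SNR $= \mu_{ROI}/\sigma_{BG}$ and CNR $= \sigma_{ROI}/\sigma_{BG}$ are
plain ratios in arbitrary units, never decibels — values in the tens
to hundreds are on the ratio scale. GCNR
$= 1 - \sum_b \min(h_{1,b}, h_{2,b})$ uses 256 shared bins spanning the
pooled range of the two regions (the bin count is exposed and a
convergence-with-bins check is part of the suite); it is invariant under
common monotone intensity remappings and clamped to $[0,1]$. Metrics are
computed on values as-is — no absolute value — since filtered images can
legitimately hold small negatives. Region boxes are inclusive 1-based
`c(row0, col0, row1, col1)` bounds, the idiomatic R indexing convention,
validated to be inside the image, disjoint, and at least 4 pixels each.

## Classical baselines

Savitzky–Golay (order 3, frame 9) filters each *column*, i.e. along the
axial A-line direction, since PA signals are depth-resolved; a separable
2D mode ships behind `axis = "2d"` for whole-image smoothing. Edges use reflection padding: interior
values equal the steady-state least-squares fit (and reproduce cubics
exactly); only the edge transients differ from MATLAB's least-squares
edge handling. The adaptive Wiener filter uses 5×5 local moments with
noise power estimated as the mean local variance; border windows shrink
to in-image pixels so constants pass through unchanged (interior values
match the classic `wiener2`). BM3D itself is an external baseline behind
a pluggable backend — re-implementing it is out of scope — and a missing
backend raises an explicit "optional baseline missing" error rather than
silently substituting another filter; requesting `sigma = 0` returns the
input by convention.

## Numerical choices

* SSIM uses the standard constants $C_1 = (0.01L)^2$, $C_2 = (0.03L)^2$
  and an 11×11 Gaussian window ($\sigma = 1.5$), evaluated over fully
  valid window positions (equivalent to the usual crop of the filtered
  map); $L = 2$ on the network scale, 1 on storage-scale images. The
  analytic gradient is derived through the raw-moment chain rule, with
  the symmetric band matrices serving as their own adjoints; it is
  finite-difference-checked in the suite, and the loss value matches an
  independent reference implementation to 1e-6 on frozen fixtures.
* Binary cross-entropies are computed from logits with the
  `max(z,0) − zt + log(1+e^{−|z|})` stabilization.
* Convolutions lower to BLAS matrix products via precomputed
  im2col/col2im index maps; the col2im scatter iterates over the 16
  kernel offsets, within which sliding-window targets are provably
  disjoint, so each offset is a single vectorized add.
* Images on disk are 32-bit TIFF (sample resolution $2^{-32}$ over the
  $[0,1]$ range), clipped to the storage range only at write time.
* Batch-normalization epsilon is 1e-3; Adam state is per-parameter with
  bias correction.

## What the synthetic tests do and do not show

Passing the suite demonstrates that the architectures, objectives and
parameters are wired exactly as specified; that the generators follow
their declared statistical laws; and that, under the synthetic study
conditions, the trained cGAN beats its noisy inputs and the classical
rows on held-out data while reproducing the qualitative photobleaching
pattern (multi-pulse averaging bleaches most; denoised single-pulse keeps
single-pulse dose at higher SNR). It does not demonstrate performance on
real tissue: the phantoms have piecewise-smooth structure and spatially
white noise, whereas real PA noise is structured and
resolution-dependent, and absolute metric values measured on real ex
vivo tissue are out of reach by construction.

Two desk-scale observations deserve note. First, the noise-invariance
study uses phantoms with a 0.1 background baseline: count and
multiplicative noise are degenerate on an exactly-zero floor, which real
averaged frames never have. Second, under 10% salt-and-pepper corruption
the *noisy* GCNR is inflated — impulses leave the background histogram
concentrated — and a Gaussian-trained compact model smears impulses
rather than removing them, so at test scale GCNR does not separate the
stages there even though median SNR still improves under all four noise
models; this echoes the general caution that GCNR is sensitive to
residual structured noise.

## Known limitations

No acoustic wave propagation or k-space forward model stands behind the
phantoms; the bleaching law is a modelling choice, not measured ICG
photochemistry; the BM3D baseline requires an external backend; and the
desk- and test-scale training budgets are far below the 40,000-step
full-scale profile, which is config-selectable but not exercised by the
automated tests.
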