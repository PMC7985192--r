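---
title: "Virtual refocusing of sparse wide-field z-scans: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual refocusing of sparse wide-field z-scans: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(vrefocus)
```

## The problem

A wide-field fluorescence microscope with a high-NA objective renders only a
thin axial slab in focus (≈ 0.4 µm for a 63×/1.4NA lens), so volumetric
imaging conventionally means dense mechanical z-scanning — slow, phototoxic,
and wasteful when the specimen's axial structure is sparse. `vrefocus` learns
the axial propagation of image content: given M sparsely and even irregularly
placed 2D scans, it synthesizes the image at any requested plane across an
extended axial range, covering with 2–3 exposures what mechanical scanning
covers with ~90.

## Conditioning on axial position: the DPM

Every input image is paired with a digital propagation matrix — a constant
matrix whose value is the signed distance from that image's plane to the
requested output plane, divided by a fixed `scale_constant`. Two conventions
were genuinely open and are fixed here once:

* **Sign**: dz = z_target − z_input, so propagating toward larger z is
  positive. Nothing in the method depends on the choice as long as training
  and inference share it; the model stores its own `scale_constant` in the
  checkpoint so inference can never diverge from training.
* **Scaling**: `scale_constant = 10` µm keeps the DPM channel of order one
  next to normalized image intensities, which conditions the first
  convolution sensibly; the raw micron value would be 1–2 orders larger than
  the image channel.

## Network

A K-scale encoder (two 3×3 conv + BN + ReLU layers per scale, 2×2 max-pooling
between scales) processes the M frames one at a time. The stated width rule
base·2^(k−2)/base·2^(k−1) is applied from k = 2; at k = 1 it would give a
fractional width, so the stem uses `base` for both layers — the smallest
consistent completion. K itself is configurable (default 5; the desk-scale
recipe uses K = 3 at 64×64, where 5 scales would pool 64 px down to 4).

Each scale owns a convolutional GRU whose hidden width equals the scale's
feature width: the residual aggregation s_k = x_k + Conv1×1(GRU(x_k))
requires matching dimensions after the 1×1 convolution, and the matched width
is the minimal consistent choice. Hidden states start at zero for every
sequence and are created afresh inside each forward call, so state can never
leak between reconstructions. No batch norm is applied inside the recurrent
block (a literal reading of the aggregation equation); BN elsewhere uses
per-application spatial statistics at train time (examples are processed
singly) and frozen running averages (momentum 0.99, ε = 10⁻³) at inference,
which makes inference bit-reproducible.

The decoder mirrors the encoder with nearest-neighbour 2×2 upsampling and
skip concatenation of s_k. The output head is a *linear* 1×1 convolution:
normalized targets legitimately dip below zero after background subtraction,
so a ReLU head would clip them.

Because M appears nowhere in the parameterization, the weight count is
invariant to sequence length — verified by running M ∈ {1, 2, 3, 6} through
one weight set — and the same model accepts permuted or repeated inputs.

## Losses

The generator objective is α·BerHu + β·(1 − MSSSIM) + γ·(D(ŷ) − 1)², with
α, β, γ = 3, 1, 0.5 and BerHu threshold c = 0.1.

* **BerHu.** The printed form sums per-pixel penalties; the package's
  `berhu()` defaults to that sum (and reproduces the two-pixel hand example
  exactly), while the training objective uses the mean so that c = 0.1 stays
  on the per-pixel normalized-intensity scale and the α/β/γ balance is
  independent of crop size.
* **MS-SSIM sign.** Added *similarity* would reward dissimilarity when
  minimized; the objective therefore uses the standard conversion
  β·(1 − MSSSIM).
* **MS-SSIM constants.** The canonical 5-level exponents (0.0448, 0.2856,
  0.3001, 0.2363, 0.1333; renormalized when fewer levels fit the crop),
  C₁ = (0.01L)², C₂ = (0.03L)², C₃ = C₂/2 with L = 1 on the normalized
  scale, an 11×11 Gaussian window with σ = 1.5, and 2×2 mean-pool
  downsampling between levels. With C₃ = C₂/2 the contrast·structure product
  collapses to the usual cs term, which is what the implementation evaluates;
  the test oracle evaluates contrast and structure separately and agrees to
  10⁻⁵. Local statistics are averaged over the window-valid interior so that
  boundary handling cancels exactly in the analytic gradient (checked against
  finite differences to 10⁻⁷). Per-level means are clamped below at 10⁻⁶
  before exponentiation; the clamp is inactive on all tested imagery.
* **Adversarial terms.** Least-squares: the discriminator (five conv blocks
  of width 20·2^k, global average pooling, a 20-unit dense layer, sigmoid)
  minimizes ½D(ŷ)² + ½(D(y) − 1)², alternating 1:1 with the generator — no
  schedule is prescribed, so the simplest one is used. With the GAN disabled
  the discriminator is provably untouched (asserted bitwise in tests).

## Training procedure

Each example draws M planes at *exact* spacing Δz from a normalized stack
(Δz must sit on the stack's grid), one target plane uniformly over the full
stack range — including extrapolation beyond the outermost inputs — and one
lateral crop shared by all planes. Adam with the configured learning rate;
batch size defaults to 4 (unstated in the protocol; small values behave
equivalently here). Validation stacks are split off before training, never
contribute gradients, and the "best" checkpoint is selected by the
non-adversarial fidelity loss α·BerHu + β·(1 − MSSSIM), since the adversarial
term is not a fidelity measure. No augmentation is applied by default.

## The synthetic study conditions

The simulator emulates sparse wide-field z-scanning of point-like emitters:

* separable Gaussian PSF with σ(dz) = σ₀√(1 + (dz/z_R)²); σ₀ = 0.2 µm gives
  an in-focus FWHM of 0.47 µm, and z_R = 0.2 µm makes the variance double at
  ±0.2 µm — a 0.4 µm DOF, matching the 63×/1.4NA regime. The functional form
  is chosen for its analytic FWHM and energy conservation, both used as
  oracles.
* 0.1 µm lateral pixels (63×-class sampling); Poisson shot noise at a gain of
  200 photons per intensity unit plus Gaussian read noise (SD 0.01) — the
  camera's true noise statistics are unstated, so these are realistic free
  parameters, not calibrated values.
* Desk-scale geometry: 64×64×3.6 µm phantoms with 25 beads, dense 0.2 µm
  ground-truth grids (19 planes), M = 3 inputs at Δz = 1.2 µm placed at
  0.6/1.8/3.0 µm — the sparse-scan regime (inputs spaced ⅓ of the axial
  extent apart, Δz = 3× DOF... 6× DOF gaps between input and the farthest
  target) scaled so that training finishes in minutes on one CPU. The
  demonstration trains K = 3, base 8, 400 Adam steps at 10⁻³ (the 10⁻⁵
  default suits long production runs, not a 400-step demonstration), batch 2,
  3-level MS-SSIM (a 64 px crop supports at most 3 dyadic scales of the
  11-px window).

What the phantoms do **not** emulate: optical aberrations, vectorial PSF
asymmetries, photobleaching, sample motion, or the dense textured structure
of real specimens. Passing the desk-scale tests therefore demonstrates that
the implementation learns genuine depth-conditioned propagation on controlled
data — not that this particular 71k-parameter model matches production-scale
reconstruction fidelity on real tissue.

## Preprocessing

The normalization reference is an extended-depth-of-field image. The package
uses the per-pixel maximum projection: monotone, parameter-free, and entirely
sufficient as a *reference for thresholding* (wavelet EDF fusion matters for
presentation, not for separating foreground from background). Triangle
thresholding runs on a 256-bin histogram (the images' 8-bit display
convention); the shift factor is the mean of EDF *background* pixels and the
scale factor the linear-interpolation 99th percentile of EDF *foreground*
pixels. Whether those statistics should come from EDF pixels or from all
volume pixels under the EDF mask is ambiguous; EDF-pixel statistics are used,
and the factors are returned with every normalized stack so the choice is
invertible and auditable. Lateral stage registration is out of scope — real
data must arrive aligned; synthetic data needs none.

## Inference and the adaptive stopping rule

Reconstruction assembles the sequence toward each requested z (inputs sorted
by z, the training scheme, by default — users supplying unsorted planes get
the training ordering unless they ask for `given`), resets state, and runs
one forward pass per output plane; there is no cross-plane coupling, so a
volume equals its pointwise planes exactly. Images not divisible by 2^(K−1)
are reflect-padded and cropped back. The number of scans can be chosen
online: acquisition stops at the first M with ‖V_M − V_{M−1}‖_F ≤ ε,
computed on normalized intensities (so ε is in normalized units).

## Evaluation harness

* NRMSE = 100·RMSE / (reference dynamic range) — the reference-range percent
  convention reproduces the magnitude regime of reported values; PSNR uses
  the same range. Identical images report PSNR = ∞ as a sentinel.
* ROI-RMSE maps both images to the 0–255 display scale with the *reference's*
  affine map before comparing, so a reconstruction offset is penalized rather
  than silently rescaled away.
* Bead FWHM: strict 8-neighbour local maxima above a relative threshold, an
  exclusion radius rejecting beads with close neighbours, and per-axis 1D
  Gaussian fits (Levenberg–Marquardt, 7-px half-window, centroid-seeded);
  FWHM = 2√(2 ln 2)·σ averaged over the two axes.
* KL divergence between FWHM histograms uses 30 equal-width bins over the
  pooled range with ε = 10⁻⁴ add-smoothing before renormalization (binning
  and smoothing are unstated conventions; the smoothing's effect vanishes on
  populated histograms, verified in tests).
* Permutation statistics evaluate every permutation of the M inputs (guarded
  at 24 volumes; sample beyond that) and report per-plane mean and
  *population* SD of ROI-RMSE, plus the pixel-wise SD map.
* The stability sweep perturbs each input's recorded axial position by an
  i.i.d. Gaussian draw — equivalent to adding z_d·J to its DPM — over 50
  trials per σ by default.

## Numerical choices and degenerate inputs

All learning runs on exact analytic gradients (finite-difference-verified for
every layer type); Adam uses β₁ = 0.9, β₂ = 0.999, ε = 10⁻⁸. Max-pool ties
route gradients to the first maximum. Seeds fan out from one global seed via
a module-tag hash, so e.g. adding a rendering call never shifts the training
stream. Degenerate inputs fail loudly: constant images for triangle
thresholding, empty foregrounds, non-grid Δz, undersized crops for the
MS-SSIM level count, and sequences with mismatched dimensions all raise
informative errors rather than propagating nonsense.

## Known limitations

Pure-R training is practical at desk scale (≈ 1 s per step at 64×64) but not
at 256×256 production scale. The simulator's Gaussian PSF cannot probe
aberration robustness. The learning demonstration uses one phantom family;
cross-modality (wide-field → confocal) training is supported only as a
configuration of training pairs, with no confocal-specific forward model.
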