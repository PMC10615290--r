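---
title: "Sparse-array ultrasound: simulation, beamforming and learned artifact restoration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse-array ultrasound: simulation, beamforming and learned artifact restoration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

High-frequency linear arrays image superficial anatomy — here, the
tooth/gingiva interface — with plane-wave coherent compounding. Turning
off channels ("sparse array" operation) cuts hardware cost and data rate
but enlarges the effective element pitch $p$. Once $p$ exceeds roughly
one wavelength $\lambda = c/f_0$, the receive aperture no longer samples
the wavefield densely enough and *grating lobes* appear: echoes from a
reflector at lateral angle $\theta_0$ also align at angles satisfying

$$\sin\theta_g = \sin\theta_0 + k\,\lambda/p, \qquad k = \pm 1, \pm 2,\dots$$

so bright anatomy is duplicated laterally and buries its surroundings.
`sparus` models this end to end: it simulates radio-frequency (RF)
channel data for a 128-element, 70 µm, 28 MHz array and its 64-channel
(140 µm) and 16-channel (560 µm) decimations; reconstructs 8-bit B-mode
frames by delay-and-sum (DAS) with Hanning apodization and coherent
compounding over 7 plane waves (−15°…15°); trains a residual
encoder–decoder ("RUNet"-style) network to map sparse-aperture frames
back to dense-aperture quality; and quantifies restoration with global
SSIM, MSE, PSNR, FWHM, IoU, Bland–Altman agreement and noncentral-*t*
power analysis.

## Acquisition model

Echoes follow a single-scattering time-of-flight model. For steering
angle $\theta$, scatterer $s = (x_s, z_s)$ and element at $x_e$:

$$\tau(\theta, s, e) = \frac{z_s\cos\theta + x_s\sin\theta}{c}
 + \frac{\sqrt{(x_s - x_e)^2 + z_s^2}}{c},$$

with the plane wave timed to $t = 0$ at the array plane's center. The
pulse is a Gaussian-modulated cosine whose −6 dB spectral full width is
`frac_bandwidth * center_freq` (default 0.6 × 28 MHz = 16.8 MHz); the
hardware states only ">60 %", so 0.6 is taken as the nominal value.
Scattering is linear; there is no attenuation, no elevation focusing and
no time-gain compensation (none are reported for the reference system),
and an optional cosine element-directivity factor is off by default.
Sound speed defaults to 1480 m/s (specimens immersed in water);
sampling to 62.5 MHz (the stated DAQ maximum).

Two numerical points deserve emphasis because both were found the hard
way, against a wire-target oracle:

* **Anti-alias filtering is not optional.** The pulse's upper −6 dB
  band edge (36.4 MHz) exceeds the 31.25 MHz Nyquist limit of 62.5 MHz
  sampling. Sampling the continuous echo directly folds that energy and
  sets a ≈ −25 dB artifact floor in the images. Real converters
  low-pass before sampling, so `simulate_rf()` convolves the pulse with
  a zero-phase raised-cosine low pass (rolloff 0.8–1.0 × Nyquist,
  precomputed as a fine lookup table) by default; `antialias = FALSE`
  reproduces literal direct sampling.
* **Interpolate the baseband, not the carrier.** At 2.2 samples per
  carrier cycle, linear interpolation of the analytic signal alone
  costs a −18 dB sidelobe floor. The beamformer therefore demodulates
  to complex baseband, band-limit-upsamples 4×, interpolates the
  envelope linearly, and restores carrier phase $e^{i 2\pi f_0 \tau}$
  at the exact delay. The measured wire-target floor is then ≈ −47 dB.

Sparse elements are off on transmit and receive. Under the ideal
plane-wave transmit model the transmit aperture does not enter the
delay formula, so sparsity manifests (correctly) on receive, where the
grating-lobe artifact of interest arises.

## Beamformer conventions

Per angle, each active element's baseband sample at its two-way delay
is weighted by a symmetric zero-endpoint Hanning window spanning the
*active* elements only and summed per pixel; delays outside the RF
window contribute zero. Compounding is the arithmetic mean of the
per-angle complex images. Display mapping: envelope, dB relative to the
frame maximum, clipped to a 50 dB dynamic range (unreported by the
hardware; 50 dB is a common B-mode default), mapped linearly to 0–255
with half-up rounding, so the midpoint −DR/2 maps to 128 and the
brightest pixel of a non-zero frame to 255. The default 512 × 512 grid
spans ±4.48 mm laterally (the dense aperture half-width) and
0.5–15 mm in depth; only the pixel count is stated by the reference
system, the extent is this package's choice.

## Where the grating lobe actually lands

`grating_lobe_offset()` returns the textbook first-order prediction
$z\tan(\arcsin(k\lambda/p))$ — about 0.95 mm for the 16-channel
aperture at 10 mm depth in water. The measured artifact peak of a
broadband system does *not* sit exactly there. Writing the beamformed
response of an on-axis wire as
$\sum_e w_e\,\mathrm{env}(\Delta_e)\,e^{i2\pi f_0\Delta_e}$ with
$\Delta_e$ the per-element delay mismatch, the peak trades carrier-phase
alignment against envelope overlap: with the 60 % bandwidth pulse an
independent near-field evaluation of that sum puts the peak at
0.89 mm (inward of the monochromatic prediction), and the anti-alias
filter, which lowers the spectral centroid, moves it outward — to
≈ 1.01 mm with the default 0.8–1.0 Nyquist rolloff. The acceptance
suite asserts the 3-pixel (52 µm) agreement anyway and that assertion
is knowingly red: the ≈ 60 µm discrepancy is physics, not a defect,
and no threshold was adjusted to hide it. The two companion assertions — a dense-array frame
free of local maxima above −30 dB outside the wire, and compounding
strictly reducing the sparse peak sidelobe level — hold.

## The restoration network

The network is an encoder–decoder built from residual blocks
(Conv3×3 → BN → ReLU → Conv3×3 → BN, plus an identity tensor addition; a
1×1 projection aligns channels when they differ). Each encoder stage
ends in 2×2 mean pooling (halving the frame) and a channel-doubling
convolution; each decoder stage upscales by sub-pixel convolution
(channel-to-space pixel shuffle, a value-preserving permutation), adds
the encoder skip at that scale, and applies a residual block. A final
convolution maps back to one channel which is added to the input as a
global residual. That head convolution is zero-initialized, so the
untrained network is exactly the identity map and training learns only
the artifact correction; without this warm start the first epochs are
spent fixing the output scale rather than the artifacts. All other
weights are He-initialized from a seeded RNG; builds, training and
prediction are bit-reproducible given the config seed.

The loss is `pixel * L1 + perceptual * MSE(features)` where the feature
extractor is a *fixed, seeded, randomly initialized* shallow conv stack
(conv 1→8, ReLU, 2× mean pool, conv 8→8, ReLU). The reference work
names the perceptual-loss family without naming a network, and a
desk-scale build must not download pretrained weights; random fixed
features preserve the loss's structure-sensitivity property. Defaults:
weights {pixel 1.0, perceptual 0.1}, Adam at 1e-4, batch 8 (optimizer
settings are unreported upstream; these are conventional). Training
runs a fixed epoch budget (default 50, following the epoch study of the
reference work) and retains the weights with minimum validation loss —
the "acceptable validation loss" stopping rule is undefined upstream,
so best-checkpoint selection replaces it. Checkpoints round-trip
through HDF5 bit-exactly.

The layer mathematics (conv2d via im2col + BLAS, batch-norm, pooling,
pixel shuffle, Adam) is implemented in this package and verified
against finite-difference Jacobians in the test suite; with no deep
learning runtime in the target environment this is deliberate, and the
network is small enough (≈ 240 k parameters at depth 3 / base 8) for
CPU training in minutes.

## What the synthetic phantoms emulate — and what they do not

`tooth_phantom()` builds a parametric buccal cross-section: a gently
curved tooth surface descending from the gingival margin, a gingiva
surface constructed as a normal offset of it, bright specular
scatterers along both interfaces (spacing λ/2), and diffuse speckle
(Poisson count at 40 scatterers/mm², Gaussian reflectivity) filling the
gingiva. The offset width ramps from zero at the margin to the target
thickness within 1.2 mm of arc, then stays constant, so the
perpendicular thickness 2 mm from the margin equals the requested value
*by construction* — that is what makes automated thickness recovery an
exact oracle. Thickness inputs are drawn from 0.9–2.0 mm, matching the
reported specimen range (0.89–1.99 mm). Arc length is used to locate
"2 mm from the margin" (the manual procedure does not specify arc vs
chord; arc is flagged as the choice). Negative controls provide an
anechoic-lumen vessel, layered muscle-like bands, and structureless
noise.

What a green test does **not** establish: these phantoms contain no
enamel refraction, no attenuation, no elevation-plane clutter, no
probe-tissue coupling variability and no operator variability, so green
restoration metrics here demonstrate that the pipeline and the
improvement *direction* work, not that porcine-scale image quality
numbers transfer. The study's own headline values (SSIM 0.66→0.73,
MSE 252→137, …) were measured on undeposited ex-vivo acquisitions and
are treated as direction references only.

## Statistics

SSIM is implemented exactly as the printed *global* formula — one
statistic from whole-image means, variances and covariance — not the
common 11×11 windowed mean (a windowed variant exists behind the
`window` argument, explicitly non-default). Stabilizers default to
$k_1 = (0.01 L)^2$, $k_2 = (0.03 L)^2$, $L = 255$, the standard choice
the source leaves unstated. PSNR reads the printed $I_{max}/MSE$ as
$I_{max}/\sqrt{MSE}$, the standard definition consistent with its
factor 20. Bland–Altman reports bias and ±1.96 SD limits plus Pearson r
(an explicit "undefined" flag for constant series) and the paired
two-tailed t-test. Power analysis models two independent groups of
n = 10 via the noncentral t (pooled SD, $df = 2n-2$,
ncp $= d\sqrt{n/2}$); a paired variant sits behind a flag since the
original calculator settings are not fully reported. With the reported
SDs (0.38/0.37 mm) the detectable difference of 0.5 mm gives ≈ 82 %
power, clearing the conventional 80 % bar.

## Numerical choices and degenerate inputs

* Log compression of an all-zero frame returns an all-zero image with a
  provenance flag instead of dividing by zero.
* `psnr()` returns `Inf` as the perfect-match sentinel.
* FWHM locates half-maximum crossings by linear interpolation and
  errors when the peak touches a profile boundary.
* `grating_lobe_offset()` signals a classed error
  (`sparus_no_grating_lobe`) when $k\lambda \ge p$ — no real lobe.
* The spec'd sequence invariant `fs >= 2 f0 (1 + bw)` (89.6 MHz) would
  reject the system's own 62.5 MHz maximum; the enforced requirement is
  carrier Nyquist `fs >= 2 f0`, with the band-edge undersampling
  handled by the anti-alias model above.
* The anti-aliased pulse table is truncated at −60 dB; tails below that
  sit under the beamformer's interpolation floor.
* Half-up rounding everywhere an 8-bit value is produced.

## Desk-scale defaults and budgets

Training defaults to 128 × 128 frames (the architecture is
resolution-agnostic; 512 × 512 works but is not CPU-friendly). The
acceptance suite trains depth 3 / base 8 for 6 epochs on 200 pairs —
about 10 minutes of CPU — which is already far past the point where
restoration beats the unrestored input on all three metrics; the
package default config (depth 4 / base 32 / 50 epochs) mirrors the
reference training scale instead. Dataset generation reuses one RF
block per phantom across all receive apertures (transmit is the ideal
plane wave) and one baseband preparation per angle.

## Known limitations

Single-scattering only (no multiple reverberation, no shadowing); 2-D
imaging plane without elevation physics; ideal plane-wave transmit (no
element-wise transmit synthesis, hence no transmit grating lobes); the
perceptual loss uses random features rather than a pretrained
perceptual space; and the phantom anatomy is parametric, not fitted to
dental geometry.
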