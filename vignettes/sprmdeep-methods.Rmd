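---
title: "Models and methods behind sprmdeep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind sprmdeep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`sprmdeep` is a simulation, denoising and analysis toolkit for surface
plasmon resonance microscopy (SPRM) image sequences of single
nanoparticles. This vignette documents the models it implements, the
parameters that matter, the numerical choices made where the design was
genuinely open, and what the synthetic-data tests do and do not establish.

## 1. Image formation

An SPRM frame records the interference of the plane reflected field
$E_R$ with the field $E_S$ scattered by a particle out of the surface
plasmon polariton (SPP) wave:

$$ I_\mathrm{raw} = |E_R + E_S|^2
   = |E_R|^2 + |E_S|^2 + 2\,|E_R||E_S|\cos\Delta\varphi . $$

`optical_model()` stores $|E_R|^2$ as `background_level` (photons per
pixel per frame) and the geometry of the scattered wave. The scattered
field of a particle at the origin is modeled as a damped cylindrical SPP
wave referenced to the plane leakage wave travelling along $+x$:

$$ E_S(\rho,\theta) \propto A\, e^{i\varphi}\,
   e^{i k_\mathrm{sp} (\rho - \Delta x)}\,
   \frac{e^{-\rho/\ell}}{\sqrt{1+\rho/\rho_0}}\,
   \cos^2\!\left(\tfrac{\theta}{2}\right), $$

with $\rho$ the distance from the particle, $\theta$ measured from the
propagation axis, $\ell$ the SPP damping length, $\rho_0 = 1$ px a
near-field cutoff, and $k_\mathrm{sp}$ set by the fringe period
(`sp_wavelength`, default 610 nm, i.e. ~5.6 px at the default
0.108 µm/px pitch). The relative phase $k_\mathrm{sp}(\rho - \Delta x)$
makes the interference fringes the loci $\rho - \Delta x = \mathrm{const}$
— parabolas opening along $+x$ — which is the characteristic
parabolic-tail morphology; a plane-wave phase $k_\mathrm{sp}\Delta x$
alone would give straight fringes, which is why the cylindrical form was
chosen. No electromagnetic rigor (Mie/FDTD, objective NA, camera QE) is
claimed; the analysis only needs a consistent, invertible forward model
shared by the simulator, the matched-filter detector, the
Richardson–Lucy kernel and the SSIM phase fit.

Conventions: coordinates are 0-based pixel-center, $x$ = column,
$y$ = row, SPP propagation along $+x$, $z = 0$ at the gold film. The
central lobe of the differential pattern has the sign of
$\cos\varphi$: *white-center* for $\cos\varphi > 0$ (e.g.
$\varphi = 0.13\pi$), *black-center* for $\cos\varphi < 0$
($\varphi = 0.58\pi$).

**Amplitude–size calibration.** `amplitude_from_diameter()` uses Rayleigh
(volume) scaling $A = c\,d^3$, with $c$ anchored so that a 50 nm particle
on the surface has a nominal single-frame SNR of 25 dB at the default
background (in terms of the center contrast $2A\sqrt{\mathrm{bg}}$ over
the single-pixel shot SD). A consequence worth stating plainly: under
$d^3$ scaling the nominal SNR is linear in $\log_{10} d$ with slope
60 dB/decade, so 5 nm particles sit ~60 dB below 50 nm ones and are
far below the 9.54 dB detection limit at the default photon budget. The
published experimental SNR spread across 5–50 nm is much flatter; that
regime is instrument physics the cubic toy law deliberately does not
reproduce. Tests that probe log-linearity across the whole 5–50 nm span
therefore raise the photon budget so every size clears the measurement
noise floor.

**Evanescent decay.** Detected intensity scales as $e^{-z/d}$
($d = 100$ nm default), hence field amplitude as $e^{-z/2d}$.
`infer_z()` inverts the intensity law, with $I_0$ taken as the
trajectory's maximum 5×5 reconstructed intensity (particle closest to
the surface).

## 2. Shot noise as a Cox process

Background-subtracted SPRM sequences are shot-noise limited, with rate
$\lambda(u,t) = \lambda_1(u)\,\lambda_2(t)\,S(u,t)$: a deterministic
spatial rate (background + signal), a unit-mean temporal modulation, and
a unit-mean spatio-temporal field. The decomposition is specified; the
stochastic processes behind $\lambda_2$ and $S$ are not, so the package
chooses log-Gaussian forms and documents them as placeholders:

* $\lambda_2(t) = \exp(a_t - \sigma_t^2/2)$ with $a_t$ a stationary
  AR(1) series (coefficient $\rho_t$, SD $\sigma_t$) — exactly unit
  mean;
* $S(u,t) = \exp(g_t(u) - \sigma_s^2/2)$ with $g_t$ a spatially
  Gaussian-smoothed white field (correlation length $\ell_s$ px,
  marginal SD $\sigma_s$) evolving as AR(1) in time ($\rho_s$).

Setting $\sigma_t = \sigma_s = 0$ recovers pure Poisson noise; the test
suite verifies the Poisson index of dispersion in $[0.9, 1.1]$, the
analytic overdispersion $1 + c\,(e^{\sigma_s^2}-1)$ under modulation,
photon conservation, and bit-exact seed determinism.

## 3. The denoising network

The denoiser is a four-level residual U-Net applied per frame (shared
weights) followed by a bidirectional convolutional LSTM over the feature
sequence. The residual block is
`y = conv(relu(conv(x))) + proj(x)` with a 1×1 projection only where
channel counts differ; down/up-sampling is 2×2 max-pool and
nearest-upsample + conv (the choice is not prescribed anywhere, so the
simplest standard pair is used). Four pooling stages are why inputs must
be multiples of 16 in both dimensions and at least 4 frames long. The
two ConvLSTM directions scan the feature sequence forward and backward;
their hidden states are concatenated per frame and fused by a 1×1
convolution into the intensity prediction (the fusion operator is
unspecified in the source material; concatenation + 1×1 conv was chosen
for simplicity, and one ResUNet + one Bi-ConvLSTM block is built, the
repetition count being an open question there too).

Because the pre-installed stack has no deep-learning framework, forward
and backward passes are implemented natively: im2col + BLAS GEMM
convolutions in C++ (Rcpp/Armadillo), pooling/gates/BPTT/Adam in R.
Correctness rests on finite-difference gradient checks over every
parameter group (relative error ~1e-8 in exploration, asserted at 1e-4
in the suite).

**Training protocol** (`train_config()` defaults): Adam, initial learning
rate 1e-4 halved every 50 epochs, 0.7/0.3 train/validation split,
per-epoch shuffling, checkpoints every 5 epochs, final model = lowest
validation loss, MSE objective
$\frac{1}{NM}\sum_{n,m}(\mathrm{out}_{nm}-\mathrm{target}_{nm})^2$.
Inputs are standardized per sequence to zero mean/unit SD (statistics
inverted at the output; whether experimental inputs were normalized is
unknown, so this is the package's choice). Training pairs are (noisy
differential, clean differential); half the scenes are stationary, half
moving, mirroring the mixed-motion composition of the published corpus.
The published scale (1000 pairs, 1000 epochs, batch 32, 500×500 frames)
is recorded in `inst/configs/full-scale.yaml`; desk defaults are 60
epochs, batch 8. The acceptance suite scales further down for a 1-CPU
budget (64 pairs of 4×32×32, base 4 channels, 30 epochs) — this is
compute scaling only and is stated where it happens.

Two optimization findings shaped the defaults and the tests:

* *Output formulation.* A DnCNN-style global residual skip
  (`residual_output = TRUE`: the network predicts a correction added to
  the input) was implemented and compared against direct prediction. At
  desk-scale step budgets the residual form barely moves off the
  identity (the noise-subtraction correction must be built up through a
  1×1 fusion whose weights advance only ~lr per Adam step), while
  direct prediction converges fast and delivers the denoising gain;
  direct prediction is therefore the default, with the skip retained as
  an option for long training runs.
* *Sanity floors.* With per-sequence standardization an untrained
  network emitting near-zero output can have a *lower* MSE-to-clean
  than the noisy input whenever the signal is weak (its error is the
  clean signal's variance, the input's the noise variance), so
  "untrained is no better than the input" is not a valid invariant
  here. Likewise, driving a one-pair overfit below 1% of the initial
  loss requires memorizing a specific noise realization, which the
  bounded ConvLSTM output path cannot do within a desk-scale step
  budget (it plateaus near 20% with the residual skip, flat over a
  further 1200 epochs). The suite asserts what the stated world
  achieves: a large structured loss reduction on the one-pair test
  (with output/target correlation > 0.6), untrained worse than trained,
  and — the core claim — the trained model beating the 4-frame average
  on held-out particles.

## 4. SNR convention and detection

SNR is an amplitude ratio in dB: the line profile through the particle
(horizontal, averaged over a 15-pixel height) gives the peak as the
extremum of the absolute deviation from the background mean, and
`snr_db = 20 log10((peak - bg_mean)/bg_sd)`. Two details are fixed here
because the source leaves them open:

* background mean/SD are measured on the *same* 15-row-averaged image as
  the profile, so peak and noise share one averaging scale and a
  3σ peak is exactly $20\log_{10}3 = 9.54$ dB;
* the default background region is an annulus (radii 16–30 px) with the
  forward wedge ($|\theta| < 100^\circ$ off the propagation axis)
  excluded, because the simulated tail trails along $+x$ and would
  otherwise contaminate the noise estimate.

The measured SNR of a particle depends on its phase (a quadrature-phase
particle has a dim center), which is physical under this convention, not
an artifact.

Detection is a phase-invariant quadrature matched filter: templates
rendered at phases 0 and $\pi/2$, orthonormalized; the response
magnitude $\sqrt{R_0^2 + R_{90}^2}$ is insensitive to particle phase.
Local maxima are pruned by non-maximum suppression within one PSF
footprint, gated at 4.5 response SDs (Rayleigh gate, Monte-Carlo
calibrated so pure-noise frames produce <5% false positives), then
required to exceed the 9.54 dB profile-SNR threshold. Frame averaging
(`frame_average()`) uses non-overlapping blocks by default; a rolling
mode emulates the 100-adjacent-frame averages used as high-SNR targets.

## 5. Reconstruction, phase, tracking

**Richardson–Lucy.** RL deconvolution needs nonnegative data and kernel,
but differential SPRM images are bipolar. The implemented route:
estimate the particle phase (SSIM fit, or the detector's quadrature
estimate), flip the image polarity so the central lobe is positive,
shift by the image minimum, run multiplicative RL updates with a kernel
equal to the positive part of the phase-matched differential PSF
(unit-sum), then remove the shifted baseline. Division is guarded by
$\varepsilon = 10^{-12}$; per-iteration flux is exposed for the
conservation check. On noiseless renders the reconstruction arg-max
lands within 1 px of the true center.

**Phase by SSIM.** Model crops are rendered over a 64-point phase grid
at the measured amplitude (sequential amplitude-then-phase fitting; a
joint fit is plausible but unspecified), compared by single-window SSIM
with standard stabilizers ($k_1=0.01$, $k_2=0.03$ on the pair's dynamic
range), and the arg-max is refined by a parabolic fit on the circular
grid. Noiseless self-rendered crops recover every grid phase exactly;
at nominal SNR ≥ 15 dB, simulated recovery is within $0.05\pi$ in over
90% of noise draws for the transition phases of interest
($0.58\pi \to 0.13\pi$, $0.59\pi \to 0.09\pi$).

**Localization and tracking.** Sub-pixel positions come from an
isotropic 2-D Gaussian least-squares fit around the reconstruction
arg-max (centroid fallback, flagged). Detections are linked by nearest
neighbors under a 5 px/frame gate with gaps ≤ 2 frames bridged. Axial
positions invert the evanescent law against the trajectory's maximum
intensity. Displacement summaries restrict the lateral statistics to
$z \le 20$ nm, where localization is reliable.

**Tethered motion.** A particle of diameter $D$ on a tether of contour
length $L$ (PEG convention: $L = \mathrm{MW}/44 \times 0.28$ nm per
ethylene-oxide monomer — the only convention reproducing both printed
bounds, 78.73 and 170.08 nm) has its center confined to
$|c - a| \le L + D/2$, $c_z \ge D/2$. The simulator takes Gaussian steps
(default SD 50 nm/frame — free Brownian steps of a 50 nm sphere at 2 ms
are larger still, so the cap is effectively equilibrated; the default
keeps step projection rare while exploring the cap within thousands of
frames) and projects violations back onto the set. Lateral range is
bounded by $D_{xy}^{max} = 2\sqrt{(D/2+L)^2 - (D/2)^2}$ and axial range
by $L$, both verified against brute-force simulation.

**Binding events.** Appearance/disappearance are threshold crossings of
the per-frame SNR with ±1 dB hysteresis around 9.54 dB, minimum dwell 3
frames, right-censoring for events open at the end. Dwell classes:
≥ 0.5 s long-lived specific; shorter, nonspecific; series with ≥ 3 short
events, intermittent (Brownian revisiting).

## 6. What the synthetic tests do and do not establish

The simulator emulates: 500 fps / 2 ms frames, 0.108 µm pixels,
parabolic interference patterns with tunable amplitude/phase, Cox-process
shot noise, collision staging with a phase flip at a configurable
quantum-coupling height (default 1 nm; no tunneling physics), scheduled
oxidation phase/amplitude switches, binding windows, and tethered or
random-walk motion. It does not emulate: mechanical vibration or drift,
illumination nonuniformity beyond $\lambda_1$, camera read-out structure
beyond optional Gaussian read noise, refractive-index differences
between particle species (exposed only as a user scalar), aggregation,
or any instrument optics. A green denoising test therefore establishes
that the network exploits spatio-temporal shot-noise structure on this
stated world — it does not reproduce published instrument SNR tables,
which depend on the real optics and are out of scope.

## 7. Numerical choices

* FFT correlations/convolutions are zero-padded to full linear size (no
  wrap-around); RL boundary loss shows up in the flux check (<1%).
* `sample_shot_noise()` errors on negative clean rates; deep fringes are
  clipped at zero in the simulator before sampling.
* SSIM refinement step is clamped to ±half a grid step; ties in max-pool
  routing take the first maximum.
* Degenerate inputs: flat crops (SSIM) and zero-variance backgrounds
  (SNR) raise errors rather than returning NaN; intensities above $I_0$
  clamp $z$ to 0 with a warning.
* TIFF IO is a minimal baseline codec (little-endian, uncompressed,
  grayscale, uint16/float32) written because the pre-installed R stack
  has none; it is cross-checked against an independent reader in the
  suite. Intensities are stored as float32 photons; uint16 only on
  explicit export.
* One global seed fans out to per-stage child seeds via a stable integer
  hash (`stage_seed()`), all below $2^{31}$.

## 8. Known limitations

* The PSF is a stated stand-in; its exact experimental counterpart (and
  the SPP parameters) are not public, so absolute SNR values are not
  comparable to the published instrument tables.
* The $S(u,t)$ covariance is a placeholder; only the multiplicative
  decomposition and unit-mean constraints are specified.
* Training at the published scale is impractical on one CPU; the
  desk-scale claim verified here is the *ordering* (trained denoiser >
  4-frame average on matched data), not published effect sizes.
* The line-profile SNR of a quadrature-phase particle underestimates its
  detectability; the quadrature matched filter compensates at the
  detection stage, but population SNR statistics over random phases are
  phase-diluted by construction.
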