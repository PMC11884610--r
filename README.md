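# sprmdeep

Simulation, deep denoising and single-particle analysis for surface
plasmon resonance microscopy (SPRM) image sequences.

## The problem

SPRM images single nanoparticles label-free by recording the interference
of the reflected field with light the particle scatters out of the
surface plasmon wave — each particle appears as a parabolic-tailed
pattern riding on a bright background. After background subtraction the
dominant noise is shot noise, with spatio-temporal correlations described
by a doubly stochastic Poisson (Cox) process
`lambda(u,t) = lambda1(u) * lambda2(t) * S(u,t)`. Weak scatterers (tens
of nm) sit at or below the 3-sigma detection limit, which under the
amplitude-ratio dB convention `SNR = 20*log10((peak - bg)/sd_bg)` equals
`20*log10(3) = 9.54 dB`.

`sprmdeep` provides, for anyone analyzing such sequences (or developing
methods for them) without access to instrument data:

* a physics-based **forward simulator** — parabolic interference PSFs
  with tunable amplitude/phase, evanescent z-attenuation
  `I = I0*exp(-z/d)`, Cox-process shot noise, and scripted scenes
  (collisions with a quantum-coupling phase flip, oxidation phase
  switches, binding/unbinding, tethered Brownian motion);
* a **spatio-temporal denoiser** — a four-level residual U-Net applied
  per frame feeding a bidirectional convolutional LSTM, trained with
  Adam on the MSE between output and high-SNR targets (implemented
  natively in R/C++ with analytic gradients; no deep-learning framework
  required);
* **analysis tools** — differential imaging, N-frame averaging (the
  sqrt(N) baseline), line-profile SNR, phase-invariant matched-filter
  detection, Gaussian SNR population fits, size-calibration curves
  (SNR in dB is linear in log10 diameter under Rayleigh `A = c*d^3`
  scaling);
* **reconstruction and tracking** — Richardson-Lucy interferometric
  reconstruction, SSIM-based phase estimation over a 64-point grid,
  sub-pixel Gaussian localization, evanescent-decay axial inference,
  nearest-neighbor trajectory linking, chord-geometry displacement
  bounds `Dxy_max = 2*sqrt((D/2+L)^2 - (D/2)^2)` for tethered particles,
  and binding-lifetime extraction `dt = t2 - t1`.

## Worked example

```r
library(sprmdeep)

opt <- optical_model()                      # 655 nm, 0.108 um/px, bg 500
p   <- particle_state(x = 40, y = 32, diameter = 50, phase_phi = 0.58*pi)
sim <- simulate_sequence(particle_scene(list(particle = p)),
                         opt, noise_model(), T = 8, shape = c(64, 64),
                         seed = 7)

diff <- subtract_background(sim$noisy, opt$background_level)
fa   <- frame_average(diff, 4)
compute_snr_db(get_frame(diff, 1), c(40, 32))$snr_db   # 19.15
compute_snr_db(get_frame(fa, 1),   c(40, 32))$snr_db   # 25.46

detect_particles(get_frame(fa, 1), opt)
#>      x  y response   phase0   snr_db
#> col 40 32 40.14317 1.996411 19.19688

rec <- richardson_lucy(get_frame(fa, 1),
                       rl_kernel(opt, phase_phi = 0.58*pi),
                       iterations = 30, phase_phi = 0.58*pi)
localize_xy(rec, c(40, 32))                 # (39.03, 31.94) px

crop <- get_frame(fa, 1)[(33-16):(33+16), (41-16):(41+16)]
estimate_phase_ssim(crop, opt, amplitude_from_diameter(50, opt))$phi_hat / pi
#> 0.584                                     # truth: 0.58

theoretical_dmax(50, peg_contour_length(3400))
#> $dxy_max 78.74  $dz_max 21.64             # nm
```

Reading the numbers: a 50 nm particle lands at ~19 dB in a single 2 ms
frame; averaging 4 frames adds the expected ~6 dB (sqrt(N) law). The
matched filter finds it at the true pixel, Richardson-Lucy collapses the
parabolic pattern into a spot localized to sub-pixel precision, and the
SSIM fit recovers the scattering phase to 0.004 pi — the observable that
distinguishes black-center from white-center particles during collision
and oxidation events. The chord-geometry bound is the reference value
for tethered-motion experiments (78.74 nm lateral for a 50 nm particle
on a PEG 3400 linker; the axial bound is the 21.64 nm contour length).

Training the denoiser (see `vignettes/sprmdeep-methods.Rmd` and
`tests/testthat/test-acceptance.R` for a complete run):

```r
pairs <- make_training_pairs(64, opt, noise_model(), T = 4,
                             shape = c(32, 32), seed = 11)
model <- train_denoiser(lapply(pairs, function(p) p[c("input", "target")]),
                        denoiser_spec(base_channels = 4,
                                      lstm_hidden_channels = 4),
                        train_config(epochs = 30, batch = 8))
out <- denoise(diff, model)   # same T x H x W shape, higher SNR
```

On 60 held-out synthetic particles spanning 5-50 nm, the desk-scale
model reaches a mean SNR of ~17.6 dB versus ~13.1 dB for the 4-frame
average.

## Command line

```sh
Rscript -e 'sprmdeep::sprm_cli()' pipeline --config run.yaml --seed 7 --out results/
```

Subcommands: `simulate`, `train`, `denoise`, `snr`, `track`, `pipeline`.
Stacks are multi-page grayscale TIFF (float32 or uint16), tables CSV,
configs YAML; every run writes its resolved config next to the outputs.

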