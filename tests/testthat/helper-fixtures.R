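# Shared fixtures: small optical model and simulation shortcuts.
# All data is generated in code at test time; seeds are fixed per test.

tiny_optical <- function(...) optical_model(psf_extent = 16, ...)

# One-particle simulation shortcut returning the differential sequence.
sim_particle_diff <- function(diameter = 50, phase = 0, x = 40, y = 32,
                              T = 4, shape = c(64, 64), seed = 1,
                              optical = tiny_optical(),
                              noise = noise_model()) {
  p <- particle_state(x = x, y = y, diameter = diameter, phase_phi = phase)
  sim <- simulate_sequence(particle_scene(list(particle = p)), optical,
                           noise, T = T, shape = shape, seed = seed)
  subtract_background(sim$noisy, optical$background_level)
}

# Left-side rectangle background mask, guaranteed free of the +x tail.
left_bg_mask <- function(shape, width = 16) {
  m <- matrix(FALSE, shape[1], shape[2])
  m[, seq_len(width)] <- TRUE
  m
}

# Tiny network spec used by gradient and smoke tests.
tiny_spec <- function() denoiser_spec(base_channels = 2,
                                      lstm_hidden_channels = 2)
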