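#' Optical model of the SPRM imaging system
#'
#' Bundles the optical constants that determine how a nanoparticle appears in
#' a surface plasmon resonance microscopy (SPRM) image. The far-field image is
#' the interference of the plane reflected field \eqn{E_R} with the field
#' \eqn{E_S} scattered by the particle out of the surface plasmon polariton
#' (SPP) wave; the model stores \eqn{|E_R|^2} as `background_level` and the
#' geometry of the scattered wave (fringe period, lateral damping, forward
#' directivity) that produces the characteristic parabolic tail.
#'
#' @param wavelength Illumination wavelength in nm (default 655).
#' @param pixel_size Pixel pitch on the sample plane in micrometres per pixel
#'   (default 0.108, i.e. a 54 um field of view over 500 px).
#' @param sp_wavelength SPP fringe period as seen on the image, in nm
#'   (default 610). Sets the spacing of the parabolic interference fringes.
#' @param sp_decay_length Lateral 1/e damping length of the scattered SPP
#'   wave in micrometres (default 3). Controls the tail length.
#' @param evanescent_decay_d 1/e decay length of the evanescent field along
#'   z, in nm (default 100).
#' @param background_level Mean background photon count per pixel per frame,
#'   the \eqn{|E_R|^2} term (default 500).
#' @param psf_extent Half-extent, in pixels, of the rendered pattern
#'   (default 32; must be at least 16).
#' @param snr50_db Calibration anchor for [amplitude_from_diameter()]: the
#'   single-frame SNR, in dB, of a 50 nm particle sitting on the surface at
#'   this background level (default 25).
#' @return An object of class `sprm_optical`.
#' @export
optical_model <- function(wavelength = 655, pixel_size = 0.108,
                          sp_wavelength = 610, sp_decay_length = 3,
                          evanescent_decay_d = 100, background_level = 500,
                          psf_extent = 32, snr50_db = 25) {
  lens <- c(wavelength = wavelength, pixel_size = pixel_size,
            sp_wavelength = sp_wavelength, sp_decay_length = sp_decay_length,
            evanescent_decay_d = evanescent_decay_d)
  if (any(!is.finite(lens)) || any(lens <= 0))
    stop("all optical lengths must be positive and finite")
  if (!is.finite(background_level) || background_level <= 0)
    stop("background_level must be > 0")
  if (psf_extent < 16) stop("psf_extent must be >= 16 px")
  structure(list(
    wavelength = wavelength, pixel_size = pixel_size,
    sp_wavelength = sp_wavelength, sp_decay_length = sp_decay_length,
    evanescent_decay_d = evanescent_decay_d,
    background_level = background_level,
    psf_extent = as.integer(psf_extent), snr50_db = snr50_db
  ), class = "sprm_optical")
}

#' @export
print.sprm_optical <- function(x, ...) {
  cat("SPRM optical model\n")
  cat(sprintf("  wavelength      : %g nm\n", x$wavelength))
  cat(sprintf("  pixel size      : %g um/px\n", x$pixel_size))
  cat(sprintf("  SPP fringe      : %g nm (%.2f px)\n", x$sp_wavelength,
              x$sp_wavelength / (x$pixel_size * 1000)))
  cat(sprintf("  SPP damping     : %g um\n", x$sp_decay_length))
  cat(sprintf("  evanescent d    : %g nm\n", x$evanescent_decay_d))
  cat(sprintf("  background      : %g photons/px/frame\n",
              x$background_level))
  invisible(x)
}

#' Single-particle state
#'
#' Describes one scatterer: continuous image position (0-based, pixel-center
#' convention, `x` = column, `y` = row), height `z` of the particle bottom
#' above the gold film in nm, physical diameter, dimensionless scattered-field
#' amplitude `amplitude_A` (relative to the square root of the background) and
#' scattering phase `phase_phi` in radians. Phase convention: the central lobe
#' of the differential pattern is bright when `cos(phase_phi) > 0`
#' (white-center) and dark when `cos(phase_phi) < 0` (black-center).
#'
#' @param x,y Image coordinates in pixels (0-based, pixel-center).
#' @param z Height above the gold film in nm (>= 0).
#' @param diameter Particle diameter in nm.
#' @param amplitude_A Scattered-field amplitude relative to sqrt(background);
#'   `NA` (the default) lets the simulator derive it from `diameter` via
#'   [amplitude_from_diameter()].
#' @param phase_phi Scattering phase in radians; normalized to `[0, 2*pi)`.
#' @return An object of class `sprm_particle`.
#' @export
particle_state <- function(x, y, z = 0, diameter = 50, amplitude_A = NA,
                           phase_phi = 0) {
  if (z < 0) stop("z must be >= 0")
  if (!is.na(amplitude_A) && amplitude_A < 0)
    stop("amplitude_A must be >= 0")
  structure(list(x = x, y = y, z = z, diameter = diameter,
                 amplitude_A = amplitude_A,
                 phase_phi = phase_phi %% (2 * pi)),
            class = "sprm_particle")
}

#' Evanescent-field intensity scaling
#'
#' The plasmonic field decays exponentially with height above the film, so a
#' particle at height `z` is detected with intensity `I = I0 * exp(-z/d)`.
#' The returned factor applies to detected intensity; the field amplitude is
#' scaled by its square root, `exp(-z/(2d))`.
#'
#' @param z Height above the gold surface in nm (>= 0, vectorized).
#' @param optical An [optical_model()] supplying the decay length `d`.
#' @return Multiplicative intensity factor(s) in (0, 1].
#' @export
evanescent_scale <- function(z, optical = optical_model()) {
  if (any(z < 0)) stop("z must be >= 0")
  exp(-z / optical$evanescent_decay_d)
}

#' Scattered amplitude from particle diameter
#'
#' Rayleigh scaling of the scattered field with particle volume:
#' `A = c * d^3`. The calibration constant `c` is fixed by requiring that a
#' 50 nm particle on the surface reaches `optical$snr50_db` (default 25 dB)
#' single-frame SNR at the model's background level, so SNR in dB is linear
#' in `log10(d)` with slope 60 dB/decade.
#'
#' @param diameter Particle diameter in nm (> 0, vectorized).
#' @param optical An [optical_model()].
#' @return Dimensionless amplitude(s) `A`.
#' @export
amplitude_from_diameter <- function(diameter, optical = optical_model()) {
  if (any(diameter <= 0)) stop("diameter must be > 0")
  # 2*A*sqrt(bg) is the peak photon contrast; anchor it at snr50_db for 50 nm
  a50 <- 10^(optical$snr50_db / 20) / (2 * sqrt(optical$background_level))
  a50 * (diameter / 50)^3
}

# Complex scattered-field map of one particle over an (H, W) frame.
# Cylindrical SPP wave launched at the particle, referenced to the plane
# leakage wave travelling along +x: relative phase k_sp*(rho - dx), damped
# envelope exp(-rho/l)/sqrt(1 + rho/rho0) with a forward cos^2(theta/2)
# directivity lobe. Returns the complex E_S / sqrt(background) map.
scattered_field <- function(optical, particle, shape) {
  H <- shape[1]; W <- shape[2]
  px_nm <- optical$pixel_size * 1000
  k_sp <- 2 * pi / (optical$sp_wavelength / px_nm)   # rad per pixel
  ell <- optical$sp_decay_length / optical$pixel_size # damping in px
  rho0 <- 1                                           # near-field cutoff, px
  # 0-based pixel-center coordinates
  dx <- matrix(rep(0:(W - 1) - particle$x, each = H), H, W)
  dy <- matrix(rep(0:(H - 1) - particle$y, times = W), H, W)
  rho <- sqrt(dx^2 + dy^2)
  # forward directivity: cos^2(theta/2) = (1 + cos(theta))/2, theta from +x
  ct <- ifelse(rho > 0, dx / pmax(rho, 1e-12), 1)
  direct <- (1 + ct) / 2
  env <- exp(-rho / ell) / sqrt(1 + rho / rho0) * direct
  amp <- particle$amplitude_A * exp(-particle$z /
                                      (2 * optical$evanescent_decay_d))
  amp * env * exp(1i * (particle$phase_phi + k_sp * (rho - dx)))
}

#' Render the SPRM point-spread pattern of one particle
#'
#' Computes `|E_R + E_S|^2` over the frame: the background level plus the
#' interference cross term `2*|E_R|*|E_S|*cos(dphi)` plus `|E_S|^2`. The
#' scattered wave is a damped cylindrical SPP wave with a forward directivity
#' lobe along +x; its interference with the plane reflected field yields the
#' parabolic fringes characteristic of SPRM. With `cos(phase_phi) > 0` the
#' central lobe is brighter than background (white-center), with
#' `cos(phase_phi) < 0` darker (black-center).
#'
#' @param optical An [optical_model()].
#' @param particle A [particle_state()]; must lie inside the frame.
#' @param shape Integer vector `c(H, W)`.
#' @return An `H x W` matrix of mean photon counts (background included).
#' @export
render_psf <- function(optical, particle, shape) {
  H <- shape[1]; W <- shape[2]
  if (H < optical$psf_extent || W < optical$psf_extent)
    stop("frame smaller than psf_extent")
  if (particle$x < 0 || particle$x > W - 1 ||
      particle$y < 0 || particle$y > H - 1)
    stop("particle outside frame bounds")
  if (is.na(particle$amplitude_A))
    particle$amplitude_A <- amplitude_from_diameter(particle$diameter,
                                                    optical)
  bg <- optical$background_level
  if (particle$amplitude_A == 0) return(matrix(bg, H, W))
  es <- scattered_field(optical, particle, shape)
  bg * (1 + 2 * Re(es) + Mod(es)^2)
}

# Differential (background-subtracted) pattern; the quantity every analysis
# stage works with.
render_psf_diff <- function(optical, particle, shape) {
  render_psf(optical, particle, shape) - optical$background_level
}
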