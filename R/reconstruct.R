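#' Richardson-Lucy deconvolution of an interferometric image
#'
#' SPRM differential images are bipolar interference patterns, while
#' Richardson-Lucy (RL) deconvolution requires nonnegative data and kernel.
#' The interferometric reconstruction therefore (i) flips the image polarity
#' so the central lobe is positive (sign of `cos(phase_phi)`), (ii) shifts
#' it by its minimum to nonnegativity, (iii) runs standard multiplicative RL
#' updates `u <- u * (psf* (*) (d / (psf (*) u)))` with a nonnegative,
#' unit-sum kernel, and (iv) removes the shifted baseline, leaving a compact
#' spot per particle whose integrated intensity tracks the scattered power.
#'
#' @param diff_image An `H x W` differential image.
#' @param psf Nonnegative kernel of unit sum (see [rl_kernel()]).
#' @param iterations Number of RL iterations (>= 1).
#' @param phase_phi Particle phase; sets the polarity flip (default 0,
#'   bright center).
#' @return The reconstructed `H x W` image (baseline removed). The total
#'   intensity of the internal nonnegative estimate after every iteration is
#'   attached as `attr(, "flux")`.
#' @export
richardson_lucy <- function(diff_image, psf, iterations = 30,
                            phase_phi = 0) {
  if (iterations < 1) stop("iterations must be >= 1")
  if (any(psf < 0) || abs(sum(psf) - 1) > 1e-8)
    stop("psf must be nonnegative with unit sum")
  s <- if (cos(phase_phi) >= 0) 1 else -1
  work <- s * diff_image
  shift <- min(work)
  d <- work - shift
  u <- d
  eps <- 1e-12
  flux <- numeric(iterations)
  psf_flip <- psf[nrow(psf):1, ncol(psf):1]
  for (it in seq_len(iterations)) {
    conv <- fft_convolve(u, psf)
    ratio <- d / pmax(conv, eps)
    u <- u * fft_convolve(ratio, psf_flip)
    u[u < 0] <- 0                       # clip FFT round-off
    flux[it] <- sum(u)
  }
  structure(u + shift, flux = flux)
}

#' Nonnegative reconstruction kernel from the optical model
#'
#' The positive part of the phase-matched differential PSF (after the
#' polarity flip that makes its central lobe positive), normalized to unit
#' sum — a valid RL kernel that concentrates the pattern's energy back into
#' a compact spot. Matching the kernel phase to the particle phase (from
#' [estimate_phase_ssim()] or the detector's quadrature estimate) keeps the
#' reconstruction centered on the particle.
#'
#' @param optical An [optical_model()].
#' @param extent Half-size of the kernel in px (default `psf_extent`).
#' @param phase_phi Particle phase the kernel is matched to (default 0).
#' @return A `(2*extent+1)` square matrix.
#' @export
rl_kernel <- function(optical, extent = optical$psf_extent,
                      phase_phi = 0) {
  n <- 2 * extent + 1
  p <- particle_state(x = extent, y = extent, amplitude_A = 1,
                      phase_phi = phase_phi %% (2 * pi))
  k <- render_psf_diff(optical, p, c(n, n))
  if (cos(phase_phi) < 0) k <- -k
  k[k < 0] <- 0
  k / sum(k)
}

#' Mean intensity in the 5x5 analysis window
#'
#' Amplitude and reconstructed intensity of a particle are measured as the
#' mean over the 5 x 5 pixel area centered on its brightest point.
#'
#' @param image An `H x W` image.
#' @param center_xy `c(x, y)`, 0-based; the window must fit inside the
#'   image.
#' @return Mean of the 25 pixels.
#' @export
measure_amplitude <- function(image, center_xy) {
  x <- round(center_xy[1]); y <- round(center_xy[2])
  if (x < 2 || y < 2 || x > ncol(image) - 3 || y > nrow(image) - 3)
    stop("5x5 window clipped by image border")
  mean(image[(y - 1):(y + 3), (x - 1):(x + 3)])
}

#' Structural similarity index of two images
#'
#' Single-window SSIM with the standard luminance/contrast/structure form
#' and stabilizing constants `C1 = (k1*L)^2`, `C2 = (k2*L)^2` where `L` is
#' the dynamic range of the pair.
#'
#' @param a,b Equal-size matrices.
#' @param k1,k2 Stabilizer fractions (defaults 0.01, 0.03).
#' @return SSIM in `[-1, 1]`.
#' @export
ssim <- function(a, b, k1 = 0.01, k2 = 0.03) {
  if (!identical(dim(a), dim(b))) stop("SSIM: shape mismatch")
  L <- max(max(a), max(b)) - min(min(a), min(b))
  if (L == 0) L <- 1
  c1 <- (k1 * L)^2; c2 <- (k2 * L)^2
  ma <- mean(a); mb <- mean(b)
  va <- mean((a - ma)^2); vb <- mean((b - mb)^2)
  vab <- mean((a - ma) * (b - mb))
  ((2 * ma * mb + c1) * (2 * vab + c2)) /
    ((ma^2 + mb^2 + c1) * (va + vb + c2))
}

#' Estimate the scattering phase by SSIM template matching
#'
#' Renders the model differential pattern over a grid of candidate phases
#' (default 64 points on `[0, 2*pi)`) at the given amplitude, computes the
#' SSIM against the observed crop, and returns the arg-max refined by a
#' parabolic fit through the peak and its circular neighbors. This is the
#' phase metric used to follow collision and oxidation transitions (e.g.
#' black-center 0.58 pi to white-center 0.13 pi).
#'
#' @param observed_crop Square differential crop centered on the particle.
#' @param optical An [optical_model()].
#' @param amplitude Scattered amplitude used for rendering (> 0); estimated
#'   beforehand (sequential amplitude-then-phase fitting).
#' @param n_grid Grid resolution (default 64).
#' @return A list of class `sprm_phase` with `phi_hat`, `ssim_max`,
#'   `phi_grid`, `ssim_profile`.
#' @export
estimate_phase_ssim <- function(observed_crop, optical, amplitude,
                                n_grid = 64) {
  if (amplitude <= 0) stop("amplitude must be > 0")
  if (stats::sd(as.numeric(observed_crop)) == 0)
    stop("flat observed crop: SSIM undefined")
  H <- nrow(observed_crop); W <- ncol(observed_crop)
  cx <- (W - 1) / 2; cy <- (H - 1) / 2
  grid <- seq(0, 2 * pi, length.out = n_grid + 1)[seq_len(n_grid)]
  prof <- vapply(grid, function(phi) {
    m <- render_psf_diff(optical,
                         particle_state(x = cx, y = cy,
                                        amplitude_A = amplitude,
                                        phase_phi = phi), c(H, W))
    ssim(observed_crop, m)
  }, numeric(1))
  i <- which.max(prof)
  im <- if (i == 1) n_grid else i - 1
  ip <- if (i == n_grid) 1 else i + 1
  # parabolic refinement on the circular grid
  y1 <- prof[im]; y2 <- prof[i]; y3 <- prof[ip]
  denom <- y1 - 2 * y2 + y3
  delta <- if (abs(denom) > 1e-12) 0.5 * (y1 - y3) / denom else 0
  delta <- max(min(delta, 0.5), -0.5)
  step <- 2 * pi / n_grid
  structure(list(phi_hat = (grid[i] + delta * step) %% (2 * pi),
                 ssim_max = y2, phi_grid = grid, ssim_profile = prof),
            class = "sprm_phase")
}

#' Sub-pixel localization by 2-D Gaussian fitting
#'
#' Least-squares fit of an isotropic 2-D Gaussian plus constant baseline to
#' the neighborhood of the reconstruction's brightest point. Falls back to
#' the intensity centroid (flagged) on non-convergence.
#'
#' @param reconstructed An `H x W` reconstructed image (compact spots).
#' @param approx_xy Optional `c(x, y)` start, 0-based; default: global
#'   arg-max.
#' @param window Half-size of the fitting window (default 5 px).
#' @param pixel_size Pixel pitch in um/px for the nm output.
#' @return A list with `x`, `y` (0-based px), `x_nm`, `y_nm`, `sigma`,
#'   `converged`.
#' @export
localize_xy <- function(reconstructed, approx_xy = NULL, window = 5,
                        pixel_size = 0.108) {
  H <- nrow(reconstructed); W <- ncol(reconstructed)
  if (is.null(approx_xy)) {
    i <- which.max(reconstructed)
    approx_xy <- c((i - 1) %/% H, (i - 1) %% H)   # (x, y), 0-based
  }
  x0 <- round(approx_xy[1]); y0 <- round(approx_xy[2])
  xs <- max(0, x0 - window):min(W - 1, x0 + window)
  ys <- max(0, y0 - window):min(H - 1, y0 + window)
  patch <- reconstructed[ys + 1, xs + 1, drop = FALSE]
  gx <- matrix(rep(xs, each = length(ys)), length(ys))
  gy <- matrix(rep(ys, times = length(xs)), length(ys))
  b0 <- min(patch); a0 <- max(patch) - b0
  obj <- function(p) {
    mdl <- p[1] + p[2] * exp(-((gx - p[3])^2 + (gy - p[4])^2) /
                               (2 * p[5]^2))
    sum((patch - mdl)^2)
  }
  fit <- tryCatch(
    stats::optim(c(b0, a0, x0, y0, 2), obj, method = "BFGS",
                 control = list(maxit = 500, reltol = 1e-12)),
    error = function(e) NULL)
  ok <- !is.null(fit) && fit$convergence == 0 && fit$par[5] > 0 &&
    abs(fit$par[3] - x0) <= window && abs(fit$par[4] - y0) <= window
  if (ok) {
    x <- fit$par[3]; y <- fit$par[4]; sg <- abs(fit$par[5])
  } else {
    w <- patch - min(patch)
    x <- sum(gx * w) / sum(w); y <- sum(gy * w) / sum(w); sg <- NA_real_
  }
  list(x = x, y = y, x_nm = x * pixel_size * 1000,
       y_nm = y * pixel_size * 1000, sigma = sg, converged = ok)
}

#' Axial position from evanescent decay
#'
#' Inverts the evanescent intensity law `I = I0 * exp(-z/d)`:
#' `z = -d * log(I/I0)`. `I0` is the intensity detected when the particle is
#' closest to the surface (in a trajectory, the maximum 5x5 reconstructed
#' intensity).
#'
#' @param intensity Detected intensity (> 0, vectorized).
#' @param I0 Reference intensity at the surface.
#' @param d Evanescent decay length in nm (default 100).
#' @return Height(s) `z` in nm; intensities above `I0` clamp to 0 with a
#'   warning.
#' @export
infer_z <- function(intensity, I0, d = 100) {
  if (any(intensity <= 0)) stop("intensity must be > 0")
  if (any(intensity > I0)) {
    warning("intensity exceeds I0; clamping z to 0")
    intensity <- pmin(intensity, I0)
  }
  -d * log(intensity / I0)
}

#' Contour length of a PEG linker
#'
#' `L = (MW / 44 Da) * 0.28 nm` per ethylene-oxide monomer — the convention
#' under which the chord-geometry bound reproduces 78.73 nm (PEG 3400) and
#' 170.08 nm (PEG 10000) for a 50 nm particle.
#'
#' @param mw Molecular weight in Da.
#' @return Contour length in nm.
#' @export
peg_contour_length <- function(mw) {
  if (any(mw <= 0)) stop("molecular weight must be > 0")
  mw / 44 * 0.28
}

#' Theoretical maximum displacement of a tethered particle
#'
#' A sphere of diameter `D` on a tether of contour length `L` anchored at
#' the surface can move its center laterally by at most
#' `Dxy_max = 2*sqrt((D/2 + L)^2 - (D/2)^2)` (chord geometry) and axially by
#' `Dz_max = L`.
#'
#' @param gnp_diameter Particle diameter `D` in nm (> 0).
#' @param peg_contour_length Tether contour length `L` in nm (> 0).
#' @return A list with `dxy_max` and `dz_max` in nm.
#' @export
theoretical_dmax <- function(gnp_diameter, peg_contour_length) {
  if (gnp_diameter <= 0 || peg_contour_length <= 0)
    stop("diameter and contour length must be > 0")
  r <- gnp_diameter / 2
  list(dxy_max = 2 * sqrt((r + peg_contour_length)^2 - r^2),
       dz_max = peg_contour_length)
}
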