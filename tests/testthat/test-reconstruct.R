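ns <- asNamespace("sprmdeep")

test_that("Richardson-Lucy: delta kernel is a fixed point", {
  psf <- matrix(0, 5, 5); psf[3, 3] <- 1
  set.seed(1)
  img <- matrix(runif(32 * 32, 0.1, 2), 32, 32)
  rec <- richardson_lucy(img, psf, iterations = 7, phase_phi = 0)
  expect_equal(unclass(rec), img, tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_error(richardson_lucy(img, psf * 2, 5), "unit sum")
  expect_error(richardson_lucy(img, psf, 0), "iterations")
})

test_that("RL localizes a noiseless particle and conserves flux", {
  opt <- tiny_optical()
  for (phi in c(0.13 * pi, 0.58 * pi)) {
    p <- particle_state(x = 30, y = 28, diameter = 50, phase_phi = phi)
    clean <- ns$render_psf_diff(opt, p, c(64, 64))
    rec <- richardson_lucy(clean, rl_kernel(opt, phase_phi = phi),
                           iterations = 30, phase_phi = phi)
    i <- which.max(rec)
    xy <- c((i - 1) %/% 64, (i - 1) %% 64)
    expect_lte(max(abs(xy - c(30, 28))), 1)
    flux <- attr(rec, "flux")
    expect_lt(max(abs(diff(flux))) / flux[1], 0.01)
    # internal estimate stays nonnegative: output >= baseline shift
    s <- if (cos(phi) >= 0) 1 else -1
    expect_gte(min(rec - min(s * clean)), -1e-9)
  }
})

test_that("reconstruction peak grows monotonically with amplitude", {
  opt <- tiny_optical()
  set.seed(5)
  peaks <- vapply(c(0.1, 0.2, 0.4), function(A) {
    p <- particle_state(x = 30, y = 28, amplitude_A = A, phase_phi = 0)
    sim <- simulate_sequence(particle_scene(list(particle = p)), opt,
                             noise_model(), T = 4, shape = c(64, 64),
                             seed = round(1000 * A))
    d <- get_frame(frame_average(
      subtract_background(sim$noisy, opt$background_level), 4), 1)
    rec <- richardson_lucy(d, rl_kernel(opt), 20, phase_phi = 0)
    measure_amplitude(rec, c(30, 28))
  }, numeric(1))
  expect_true(all(diff(peaks) > 0))
})

test_that("5x5 amplitude window", {
  img <- matrix(2.5, 20, 20)
  expect_equal(measure_amplitude(img, c(10, 10)), 2.5)
  img0 <- matrix(0, 20, 20); img0[11, 11] <- 5
  expect_equal(measure_amplitude(img0, c(10, 10)), 5 / 25)
  expect_error(measure_amplitude(img, c(1, 10)), "border")
})

test_that("SSIM identity and grid-exact phase recovery", {
  opt <- tiny_optical()
  a <- matrix(rnorm(25), 5, 5)
  expect_equal(ssim(a, a), 1)
  expect_error(ssim(a, matrix(0, 4, 4)), "shape")
  # noiseless self-rendered crops: arg-max lands on the true grid phase
  grid <- seq(0, 2 * pi, length.out = 65)[1:64]
  probe <- grid[seq(1, 64, by = 4)]        # every 4th of the 64 grid points
  for (phi in probe) {
    crop <- ns$render_psf_diff(
      opt, particle_state(x = 16, y = 16, amplitude_A = 0.2,
                          phase_phi = phi), c(33, 33))
    est <- estimate_phase_ssim(crop, opt, 0.2)
    expect_equal(est$ssim_max, 1, tolerance = 1e-9)
    derr <- abs(est$phi_hat - phi) %% (2 * pi)
    expect_lt(min(derr, 2 * pi - derr), 0.02 * pi)
  }
  expect_error(estimate_phase_ssim(matrix(1, 33, 33), opt, 0.2), "flat")
  expect_error(estimate_phase_ssim(a, opt, 0), "amplitude")
})

test_that("Gaussian localization: sub-pixel accuracy and equivariance", {
  mk <- function(x0, y0, H = 64, W = 64) {
    gx <- matrix(rep(0:(W - 1), each = H), H, W)
    gy <- matrix(rep(0:(H - 1), times = W), H, W)
    0.3 + 5 * exp(-((gx - x0)^2 + (gy - y0)^2) / (2 * 1.8^2))
  }
  loc <- localize_xy(mk(32.25, 30.75))
  expect_lt(abs(loc$x - 32.25), 0.05)
  expect_lt(abs(loc$y - 30.75), 0.05)
  expect_true(loc$converged)
  expect_equal(loc$x_nm, loc$x * 108)
  # integer-pixel translation shifts the result exactly
  loc2 <- localize_xy(mk(35.25, 26.75))
  expect_equal(loc2$x - loc$x, 3, tolerance = 1e-6)
  expect_equal(loc2$y - loc$y, -4, tolerance = 1e-6)
})

test_that("localization precision improves with SNR", {
  opt <- tiny_optical()
  set.seed(11)
  prec <- vapply(c(0.1, 0.4), function(A) {
    xs <- vapply(1:12, function(k) {
      p <- particle_state(x = 30, y = 28, amplitude_A = A, phase_phi = 0)
      sim <- simulate_sequence(particle_scene(list(particle = p)), opt,
                               noise_model(), T = 4, shape = c(64, 64),
                               seed = 100 * A + k)
      d <- get_frame(frame_average(
        subtract_background(sim$noisy, opt$background_level), 4), 1)
      rec <- richardson_lucy(d, rl_kernel(opt), 15, phase_phi = 0)
      localize_xy(rec, c(30, 28))$x
    }, numeric(1))
    stats::sd(xs)
  }, numeric(1))
  expect_lt(prec[2], prec[1])
})

test_that("evanescent z-inversion", {
  opt <- tiny_optical()
  expect_equal(infer_z(10, 10), 0)
  expect_equal(infer_z(10 / exp(1), 10), 100)
  # exact round trip against the forward scaling
  for (z in c(0, 12.5, 60, 99.9)) {
    I <- 7 * evanescent_scale(z, opt)
    expect_lt(abs(infer_z(I, 7, opt$evanescent_decay_d) - z), 1e-9)
  }
  expect_warning(zc <- infer_z(12, 10), "clamping")
  expect_equal(zc, 0)
  expect_error(infer_z(0, 10), "intensity")
})

test_that("tether chord geometry reproduces the printed bounds", {
  # PEG 3400: L = (3400/44) * 0.28 nm
  d1 <- theoretical_dmax(50, peg_contour_length(3400))
  expect_equal(d1$dxy_max, 78.73, tolerance = 0.05)
  expect_equal(d1$dz_max, 21.64, tolerance = 0.005)
  # PEG 10000
  d2 <- theoretical_dmax(50, peg_contour_length(10000))
  expect_equal(d2$dxy_max, 170.08, tolerance = 0.05)
  # L -> 0 collapses the reachable set
  expect_lt(theoretical_dmax(50, 1e-9)$dxy_max, 1e-3)
  expect_error(theoretical_dmax(0, 10), "must be > 0")
  expect_error(peg_contour_length(-1), "weight")
})
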