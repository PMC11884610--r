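test_that("background subtraction is exact, signed and linear", {
  set.seed(1)
  raw <- image_sequence(array(rpois(4 * 16 * 16, 50), c(4, 16, 16)))
  bg <- matrix(50, 16, 16)
  d <- subtract_background(raw, bg)
  expect_equal(d$frames, raw$frames - 50)
  same <- subtract_background(image_sequence(array(50, c(2, 16, 16))), bg)
  expect_true(all(same$frames == 0))
  # subtract-then-average == average-then-subtract
  a1 <- frame_average(subtract_background(raw, bg), 4)
  a2 <- subtract_background(frame_average(raw, 4), bg)
  expect_equal(a1$frames, a2$frames)
  expect_error(subtract_background(raw, matrix(0, 8, 8)), "shape")
})

test_that("frame_average block and rolling modes", {
  set.seed(2)
  s <- image_sequence(array(rnorm(12 * 8 * 8), c(12, 8, 8)), signed = TRUE)
  expect_identical(frame_average(s, 1), s)
  expect_error(frame_average(s, 13), "N must")
  b <- frame_average(s, 4)
  expect_equal(dim(b$frames)[1], 3)
  expect_equal(b$frames[2, , ],
               apply(s$frames[5:8, , ], c(2, 3), mean))
  cst <- image_sequence(array(3, c(6, 8, 8)))
  expect_true(all(frame_average(cst, 3)$frames == 3))
  r <- frame_average(s, 5, rolling = TRUE)
  expect_equal(dim(r$frames), dim(s$frames))
  expect_equal(r$frames[6, , ], apply(s$frames[4:8, , ], c(2, 3), mean))
})

test_that("SNR closed forms: 3 sigma is 9.54 dB by construction", {
  H <- 64; W <- 64; x <- 40; y <- 32
  set.seed(3)
  img <- matrix(0, H, W)
  bgm <- sprmdeep:::bg_annulus(c(H, W), x, y, 16, 30)
  v <- rnorm(sum(bgm))
  v <- (v - mean(v)) / stats::sd(v)        # exactly mean 0, sd 1
  mk <- function(k) {
    im <- img
    im[bgm] <- v
    im[(y - 7):(y + 7) + 1, x + 1] <- k    # peak k on the profile scale
    im
  }
  snr <- function(im) compute_snr_db(im, c(x, y), bg_region = bgm,
                                     peak_halfwidth = 2)
  # anchor peaks at exact multiples of the measured background SD above
  # the measured background mean, so the dB values are closed-form
  s0 <- snr(mk(0))
  at_sigma <- function(k) {
    im <- mk(0)
    im[(y - 7):(y + 7) + 1, x + 1] <- k * s0$bg_sd + s0$bg_mean
    snr(im)
  }
  # a 3-sigma peak is exactly the 9.54 dB limit of detection
  expect_equal(at_sigma(3)$snr_db, detection_limit_db(), tolerance = 1e-9)
  expect_equal(detection_limit_db(), 20 * log10(3))
  # 1 sigma -> 0 dB, 10 sigma -> 20 dB
  expect_equal(at_sigma(1)$snr_db, 0, tolerance = 1e-9)
  expect_equal(at_sigma(10)$snr_db, 20, tolerance = 1e-9)
  # doubling the amplitude ratio is +6.02 dB under this convention
  expect_equal(at_sigma(4)$snr_db - at_sigma(2)$snr_db, 20 * log10(2),
               tolerance = 1e-9)
})

test_that("SNR is invariant to affine intensity rescaling", {
  diff <- get_frame(sim_particle_diff(50, seed = 4), 1)
  a <- compute_snr_db(diff, c(40, 32))
  b <- compute_snr_db(3.7 * diff + 12, c(40, 32))
  expect_equal(a$snr_db, b$snr_db, tolerance = 1e-9)
  expect_error(compute_snr_db(matrix(1, 64, 64), c(40, 32)), "zero")
})

test_that("detector finds separated particles and rejects pure noise", {
  opt <- tiny_optical()
  noi <- noise_model()
  p1 <- particle_state(x = 24, y = 24, diameter = 50, phase_phi = 0)
  p2 <- particle_state(x = 70, y = 64, diameter = 50,
                       phase_phi = 0.58 * pi)
  sim <- simulate_sequence(particle_scene(list(particle = p1),
                                          list(particle = p2)),
                           opt, noi, T = 4, shape = c(96, 96), seed = 6)
  img <- get_frame(subtract_background(sim$noisy, opt$background_level), 1)
  det <- detect_particles(img, opt)
  expect_equal(nrow(det), 2)
  hit <- function(x, y) any(sqrt((det$x - x)^2 + (det$y - y)^2) < 6)
  expect_true(hit(24, 24) && hit(70, 64))
  # pure noise: no detections expected in a short run (FP < 5% per image)
  fp <- sum(vapply(1:15, function(k) {
    s <- simulate_sequence(particle_scene(), opt, noi, T = 4,
                           shape = c(64, 64), seed = 600 + k)
    i <- get_frame(subtract_background(s$noisy, opt$background_level), 1)
    nrow(detect_particles(i, opt)) > 0
  }, logical(1)))
  expect_lte(fp, 1)
})

test_that("Gaussian SNR fit recovers simulated population statistics", {
  # a published denoised 5 nm population benchmark: 14.53 +/- 1.09 dB
  set.seed(9)
  mu <- 14.53; sg <- 1.09; n <- 1000
  fit <- fit_snr_distribution(rnorm(n, mu, sg))
  expect_lt(abs(fit$mu - mu), 3 * sg / sqrt(n))
  expect_lt(abs(fit$sigma - sg), 3 * sg / sqrt(2 * n))
  expect_error(fit_snr_distribution(rep(5, 100)), "zero variance")
  expect_error(fit_snr_distribution(rnorm(5)), "at least 10")
  two <- fit_snr_distribution(rep(c(7, 9), 50))
  expect_equal(two$mu, 8)
})

test_that("calibration curve: monotone fit, invariances, guards", {
  set.seed(10)
  sizes <- c(5, 10, 20, 40, 50)
  rec <- do.call(rbind, lapply(sizes, function(d)
    data.frame(diameter = d,
               snr_db = 25 + 60 * log10(d / 50) + rnorm(30, 0, 0.5))))
  cal <- calibration_curve(rec)
  expect_true(all(diff(cal$table$snr_mean) > 0))
  expect_equal(cal$slope, 60, tolerance = 1)
  # reorder invariance
  cal2 <- calibration_curve(rec[sample(nrow(rec)), ])
  expect_equal(cal$slope, cal2$slope)
  expect_equal(cal$table, cal2$table)
  # flat input -> zero slope (lm warns about the degenerate perfect fit)
  flat <- data.frame(diameter = rep(sizes, each = 4), snr_db = 12)
  expect_equal(suppressWarnings(calibration_curve(flat)$slope), 0)
  expect_error(calibration_curve(rec[rec$diameter < 11, ]), "3 diameters")
})
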