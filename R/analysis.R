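#' Background subtraction
#'
#' Differential SPRM images isolate a particle's interference contribution:
#' `differential = raw - background`. Values are signed.
#'
#' @param raw An [image_sequence()].
#' @param background An `H x W` background image (typically the clean
#'   background level or a particle-free frame).
#' @return A signed differential [image_sequence()].
#' @export
subtract_background <- function(raw, background) {
  d <- dim(raw$frames)
  if (length(background) == 1) background <- matrix(background, d[2], d[3])
  if (!identical(dim(background), d[2:3]))
    stop("background shape does not match frames")
  out <- raw$frames - rep(as.numeric(background), each = d[1])
  as_sequence_like(out, raw, signed = TRUE)
}

#' Frame averaging (FA)
#'
#' The classical denoising baseline: average `N` consecutive frames. With
#' shot-noise-limited data the background SD shrinks by `sqrt(N)`, so the
#' SNR in dB rises by `20*log10(sqrt(N))` (+6.02 dB at N = 4). By default
#' non-overlapping blocks are averaged (`T -> floor(T/N)` frames); with
#' `rolling = TRUE` a centered rolling mean of width `N` is returned at full
#' length, which is how high-SNR training targets ("average of 100 adjacent
#' frames") are emulated.
#'
#' @param seq An [image_sequence()].
#' @param N Frames per average (1 <= N <= T).
#' @param rolling Use a rolling window instead of disjoint blocks.
#' @return An [image_sequence()].
#' @export
frame_average <- function(seq, N, rolling = FALSE) {
  d <- dim(seq$frames)
  if (N < 1 || N > d[1]) stop("N must be in [1, T]")
  if (N == 1) return(seq)
  if (rolling) {
    cs <- apply(seq$frames, c(2, 3), cumsum)      # T x H x W
    out <- array(0, d)
    for (t in seq_len(d[1])) {
      a <- max(1, t - N %/% 2); b <- min(d[1], a + N - 1); a <- max(1, b - N + 1)
      upper <- cs[b, , ]
      lower <- if (a > 1) cs[a - 1, , ] else 0
      out[t, , ] <- (upper - lower) / (b - a + 1)
    }
  } else {
    nb <- d[1] %/% N
    out <- array(0, c(nb, d[2], d[3]))
    for (k in seq_len(nb))
      out[k, , ] <- apply(seq$frames[((k - 1) * N + 1):(k * N), , ,
                                     drop = FALSE], c(2, 3), mean)
  }
  as_sequence_like(out, seq, signed = TRUE)
}

# Logical mask of the default background region: an annulus around (x, y)
# (0-based center), inner radius past the PSF core, excluding the forward
# wedge where the SPP tail trails (propagation along +x) so the region is
# disjoint from the particle footprint.
bg_annulus <- function(shape, x, y, r_in, r_out, exclude_forward = TRUE) {
  H <- shape[1]; W <- shape[2]
  dx <- matrix(rep(0:(W - 1) - x, each = H), H, W)
  dy <- matrix(rep(0:(H - 1) - y, times = W), H, W)
  rr <- sqrt(dx^2 + dy^2)
  m <- rr >= r_in & rr <= r_out
  if (exclude_forward) {
    theta <- atan2(dy, dx)                 # 0 along the tail direction
    m <- m & abs(theta) > 100 / 180 * pi
  }
  m
}

# Vertical boxcar mean of half-width hh (edge-truncated): row y of the
# result is the mean of rows y-hh..y+hh — i.e. the "line profile averaged
# over (2*hh+1)-pixel height" evaluated at every y.
profile_image <- function(img, hh) {
  H <- nrow(img)
  cs <- rbind(0, apply(img, 2, cumsum))
  lo <- pmax(seq_len(H) - hh, 1); hi <- pmin(seq_len(H) + hh, H)
  (cs[hi + 1, , drop = FALSE] - cs[lo, , drop = FALSE]) / (hi - lo + 1)
}

#' Single-particle SNR in dB
#'
#' The SNR of a particle in a differential image is computed from the line
#' profile through its center: the horizontal profile averaged over a
#' 15-pixel height, with the peak taken as the extremum of the absolute
#' deviation from the mean background. Background mean and SD are measured
#' on the same 15-row-averaged image (same noise scale as the profile) over
#' `bg_region`. In dB: `snr_db = 20*log10((peak - bg_mean)/bg_sd)`. Under
#' this amplitude-ratio convention a 3-sigma peak equals
#' `20*log10(3) = 9.54` dB, the limit of detection. The statistic is
#' invariant to affine intensity rescaling of the whole image.
#'
#' @param diff_image An `H x W` differential image.
#' @param particle_xy `c(x, y)` center, 0-based pixel coordinates.
#' @param bg_region Optional logical `H x W` mask of background pixels;
#'   default is an annulus of radii `[bg_inner, bg_outer]` around the
#'   particle. Must be disjoint from the particle's PSF footprint (tails
#'   trail along +x; a region left of the particle is cleanest).
#' @param profile_halfheight Half-height of the averaged profile band
#'   (default 7, i.e. 15 rows).
#' @param bg_inner,bg_outer Default annulus radii in px.
#' @param peak_halfwidth Optional restriction of the peak search to
#'   `x +/- peak_halfwidth` (used by the detector); default: the whole
#'   profile.
#' @return A list of class `sprm_snr` with `peak_minus_bg`, `bg_mean`,
#'   `bg_sd`, `snr_db` and `detected` (peak above background at all).
#' @export
compute_snr_db <- function(diff_image, particle_xy, bg_region = NULL,
                           profile_halfheight = 7, bg_inner = 16,
                           bg_outer = 30, peak_halfwidth = NULL) {
  H <- nrow(diff_image); W <- ncol(diff_image)
  x <- particle_xy[1]; y <- particle_xy[2]
  if (is.null(bg_region))
    bg_region <- bg_annulus(c(H, W), x, y, bg_inner, bg_outer)
  if (!any(bg_region)) stop("empty background region")
  pimg <- profile_image(diff_image, profile_halfheight)
  bg <- pimg[bg_region]
  bg_mean <- mean(bg); bg_sd <- stats::sd(bg)
  if (!is.finite(bg_sd) || bg_sd == 0) stop("zero background SD")
  profile <- pimg[min(max(round(y), 0), H - 1) + 1, ]
  cols <- seq_len(W)
  if (!is.null(peak_halfwidth))
    cols <- cols[abs(cols - 1 - round(x)) <= peak_halfwidth]
  peak <- max(abs(profile[cols] - bg_mean))
  detected <- peak > 0
  structure(list(peak_minus_bg = peak, bg_mean = bg_mean, bg_sd = bg_sd,
                 snr_db = if (detected) 20 * log10(peak / bg_sd)
                 else NA_real_,
                 detected = detected), class = "sprm_snr")
}

#' Detection limit of the dB convention
#'
#' A peak exactly 3 background SDs above the background corresponds to
#' `20*log10(3) = 9.542` dB, the 3-sigma limit of detection.
#' @return The threshold in dB.
#' @export
detection_limit_db <- function() 20 * log10(3)

#' Detect particles in a differential image
#'
#' Phase-invariant matched filtering: the image is correlated with a
#' quadrature pair of model differential PSF templates (phases 0 and pi/2,
#' orthonormalized), and the response magnitude
#' `R = sqrt(R0^2 + R90^2)` is used, which is insensitive to the particle's
#' scattering phase (any polarity from white- to black-center). Local
#' maxima of `R` undergo non-maximum suppression within one PSF footprint;
#' a candidate is reported if `R` exceeds `response_z` response-SDs
#' (Rayleigh specificity gate, Monte-Carlo calibrated so pure-noise images
#' yield under 5 percent false positives) and its line-profile SNR at the
#' candidate exceeds the threshold (default the 9.54 dB 3-sigma limit).
#'
#' @param diff_image An `H x W` differential image.
#' @param optical An [optical_model()] supplying the templates.
#' @param threshold_db Detection threshold in dB.
#' @param max_candidates Cap on reported detections.
#' @param response_z Matched-filter magnitude gate in response SDs
#'   (default 4.5).
#' @return A data.frame with columns `x`, `y` (0-based), `response`
#'   (magnitude z-score), `phase0` (coarse phase from the quadrature
#'   responses, rad) and `snr_db`; zero rows if nothing passes.
#' @export
detect_particles <- function(diff_image, optical = optical_model(),
                             threshold_db = detection_limit_db(),
                             max_candidates = 20, response_z = 4.5) {
  H <- nrow(diff_image); W <- ncol(diff_image)
  tm <- psf_template_pair(optical)
  r0 <- fft_correlate(diff_image, tm$t0)
  r90 <- fft_correlate(diff_image, tm$t90)
  rsd <- stats::mad(r0)
  if (rsd == 0) rsd <- max(stats::sd(r0), 1e-12)
  aresp <- sqrt((r0 - stats::median(r0))^2 + (r90 - stats::median(r90))^2)
  # local maxima in a 3x3 neighborhood, excluding a one-pixel border
  loc <- matrix(FALSE, H, W)
  ii <- 2:(H - 1); jj <- 2:(W - 1)
  a <- aresp[ii, jj]
  loc[ii, jj] <- a >= aresp[ii - 1, jj] & a >= aresp[ii + 1, jj] &
    a >= aresp[ii, jj - 1] & a >= aresp[ii, jj + 1] &
    a >= aresp[ii - 1, jj - 1] & a >= aresp[ii + 1, jj + 1] &
    a >= aresp[ii - 1, jj + 1] & a >= aresp[ii + 1, jj - 1]
  cand <- which(loc, arr.ind = TRUE)
  if (!nrow(cand)) return(empty_detections())
  ord <- order(aresp[cand], decreasing = TRUE)
  cand <- cand[ord, , drop = FALSE]
  # non-maximum suppression within one PSF footprint, plus dominance
  # suppression: fringe satellites of a much stronger detection within
  # the pattern's tail radius are discarded
  keep <- logical(nrow(cand))
  sep <- optical$psf_extent / 2
  dom_r <- 2 * optical$psf_extent
  sel <- matrix(0, 0, 2); selr <- numeric(0)
  for (i in seq_len(nrow(cand))) {
    ri <- aresp[cand[i, 1], cand[i, 2]]
    if (nrow(sel)) {
      dd <- sqrt(rowSums((sel - matrix(cand[i, ], nrow(sel), 2,
                                       byrow = TRUE))^2))
      if (any(dd < sep)) next
      if (any(dd < dom_r & selr > 2.5 * ri)) next
    }
    keep[i] <- TRUE
    sel <- rbind(sel, cand[i, ]); selr <- c(selr, ri)
    if (nrow(sel) >= max_candidates) break
  }
  cand <- cand[keep, , drop = FALSE]
  out <- lapply(seq_len(nrow(cand)), function(i) {
    rz <- aresp[cand[i, 1], cand[i, 2]] / rsd
    if (rz <= response_z) return(NULL)
    x <- cand[i, 2] - 1; y <- cand[i, 1] - 1
    s <- tryCatch(compute_snr_db(diff_image, c(x, y), peak_halfwidth = 3),
                  error = function(e) NULL)
    if (is.null(s) || !s$detected || !is.finite(s$snr_db)) return(NULL)
    if (s$snr_db <= threshold_db) return(NULL)
    data.frame(x = x, y = y, response = rz,
               phase0 = atan2(r90[cand[i, 1], cand[i, 2]],
                              r0[cand[i, 1], cand[i, 2]]) %% (2 * pi),
               snr_db = s$snr_db)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) empty_detections() else out
}

empty_detections <- function()
  data.frame(x = numeric(), y = numeric(), response = numeric(),
             phase0 = numeric(), snr_db = numeric())

# Quadrature pair of differential PSF templates: phase 0 and pi/2,
# zero-mean, t90 orthogonalized against t0, both unit norm.
psf_template_pair <- function(optical) {
  n <- 2 * optical$psf_extent + 1
  ctr <- optical$psf_extent
  mk <- function(phi) {
    p <- particle_state(x = ctr, y = ctr, amplitude_A = 1, phase_phi = phi)
    t <- render_psf_diff(optical, p, c(n, n))
    t - mean(t)
  }
  t0 <- mk(0)
  t0 <- t0 / sqrt(sum(t0^2))
  t90 <- mk(pi / 2)
  t90 <- t90 - sum(t90 * t0) * t0
  t90 <- t90 / sqrt(sum(t90^2))
  list(t0 = t0, t90 = t90)
}

# 2-D cross-correlation, 'same' output, zero-padded FFT.
fft_correlate <- function(img, tmpl) {
  H <- nrow(img); W <- ncol(img)
  h <- nrow(tmpl); w <- ncol(tmpl)
  ph <- H + h - 1; pw <- W + w - 1
  A <- matrix(0, ph, pw); A[1:H, 1:W] <- img
  B <- matrix(0, ph, pw); B[1:h, 1:w] <- tmpl[h:1, w:1]  # flip: correlation
  r <- Re(stats::fft(stats::fft(A) * stats::fft(B), inverse = TRUE)) /
    (ph * pw)
  r[(h %/% 2 + 1):(h %/% 2 + H), (w %/% 2 + 1):(w %/% 2 + W)]
}

# 2-D convolution, 'same' output, zero-padded FFT.
fft_convolve <- function(img, k) {
  H <- nrow(img); W <- ncol(img)
  h <- nrow(k); w <- ncol(k)
  ph <- H + h - 1; pw <- W + w - 1
  A <- matrix(0, ph, pw); A[1:H, 1:W] <- img
  B <- matrix(0, ph, pw); B[1:h, 1:w] <- k
  r <- Re(stats::fft(stats::fft(A) * stats::fft(B), inverse = TRUE)) /
    (ph * pw)
  r[(h %/% 2 + 1):(h %/% 2 + H), (w %/% 2 + 1):(w %/% 2 + W)]
}

#' Gaussian fit of an SNR distribution
#'
#' Maximum-likelihood Gaussian fit (sample mean and SD) of a set of
#' per-particle SNR values, as used to summarize size populations.
#'
#' @param snr_values Numeric vector, `n >= 10`, finite, non-constant.
#' @param breaks Histogram breaks for the overlay export.
#' @return A list of class `sprm_snr_fit` with `mu`, `sigma`, `n` and a
#'   `histogram` (counts/mids) for plotting.
#' @export
fit_snr_distribution <- function(snr_values, breaks = "Sturges") {
  snr_values <- snr_values[is.finite(snr_values)]
  if (length(snr_values) < 10) stop("need at least 10 finite SNR values")
  s <- stats::sd(snr_values)
  if (s == 0) stop("zero variance: SNR values are constant")
  h <- graphics::hist(snr_values, breaks = breaks, plot = FALSE)
  structure(list(mu = mean(snr_values), sigma = s, n = length(snr_values),
                 histogram = list(mids = h$mids, counts = h$counts,
                                  density = h$density)),
            class = "sprm_snr_fit")
}

#' @export
print.sprm_snr_fit <- function(x, ...) {
  cat(sprintf("Gaussian SNR fit: %.2f +/- %.2f dB (n = %d)\n",
              x$mu, x$sigma, x$n))
  invisible(x)
}

#' Size-calibration curve
#'
#' Per-diameter mean and SD of SNR plus a least-squares fit of mean SNR (dB)
#' on `log10(diameter)`. With Rayleigh amplitude scaling the relationship is
#' linear with slope 60 dB/decade.
#'
#' @param records A data.frame with columns `diameter` (nm) and `snr_db`.
#' @return A list of class `sprm_calibration` with per-size summaries and
#'   the `slope`/`intercept` of the fit.
#' @export
calibration_curve <- function(records) {
  records <- records[is.finite(records$snr_db), , drop = FALSE]
  sizes <- sort(unique(records$diameter))
  if (length(sizes) < 3) stop("need at least 3 diameters")
  summ <- do.call(rbind, lapply(sizes, function(d) {
    v <- records$snr_db[records$diameter == d]
    data.frame(diameter = d, snr_mean = mean(v),
               snr_sd = if (length(v) > 1) stats::sd(v) else 0,
               n = length(v))
  }))
  fit <- stats::lm(snr_mean ~ log10(diameter), data = summ)
  structure(list(table = summ,
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = summary(fit)$r.squared),
            class = "sprm_calibration")
}

#' @export
print.sprm_calibration <- function(x, ...) {
  cat("SNR calibration curve (dB vs log10 diameter)\n")
  print(x$table, row.names = FALSE)
  cat(sprintf("  fit: snr = %.2f + %.2f * log10(d), R^2 = %.3f\n",
              x$intercept, x$slope, x$r_squared))
  invisible(x)
}
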