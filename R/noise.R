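#' Cox-process shot-noise model
#'
#' Shot noise in SPRM sequences is a doubly stochastic Poisson (Cox) process:
#' the photon rate at pixel `u` and frame `t` factorizes as
#' `lambda(u, t) = lambda1(u) * lambda2(t) * S(u, t)`, where `lambda1` is the
#' deterministic spatial rate (background plus particle signal), `lambda2` a
#' unit-mean temporal modulation, and `S` a unit-mean spatio-temporal field.
#' Both stochastic factors are log-Gaussian: `lambda2` exponentiates a
#' stationary AR(1) series, `S` exponentiates a spatially smoothed white
#' field with AR(1) temporal persistence; each is mean-corrected so its
#' expectation is exactly 1. Setting `sigma_t = sigma_s = 0` recovers pure
#' Poisson shot noise.
#'
#' @param rho_t,sigma_t AR(1) coefficient and stationary SD of the log
#'   temporal modulation `lambda2(t)`.
#' @param ell_s Spatial correlation length of `S` in pixels.
#' @param rho_s,sigma_s Temporal AR(1) coefficient and stationary log-SD of
#'   `S(u, t)`.
#' @param read_noise_sd Additive Gaussian read noise SD in photons
#'   (default 0).
#' @param lambda1_map Optional per-pixel mean rate map used when sampling
#'   noise without an explicit clean sequence.
#' @return An object of class `sprm_noise`.
#' @export
noise_model <- function(rho_t = 0.8, sigma_t = 0, ell_s = 2, rho_s = 0.5,
                        sigma_s = 0, read_noise_sd = 0, lambda1_map = NULL) {
  if (sigma_t < 0 || sigma_s < 0 || read_noise_sd < 0)
    stop("noise SDs must be >= 0")
  if (abs(rho_t) >= 1 || abs(rho_s) >= 1)
    stop("AR(1) coefficients must satisfy |rho| < 1")
  if (!is.null(lambda1_map) && any(lambda1_map < 0))
    stop("lambda1_map must be >= 0 everywhere")
  structure(list(rho_t = rho_t, sigma_t = sigma_t, ell_s = ell_s,
                 rho_s = rho_s, sigma_s = sigma_s,
                 read_noise_sd = read_noise_sd, lambda1_map = lambda1_map),
            class = "sprm_noise")
}

# Unit-mean log-AR(1) temporal modulation lambda2(t).
make_lambda2 <- function(n, noise) {
  if (noise$sigma_t == 0) return(rep(1, n))
  a <- numeric(n)
  a[1] <- rnorm(1, 0, noise$sigma_t)
  if (n > 1) {
    innov <- rnorm(n - 1, 0, noise$sigma_t * sqrt(1 - noise$rho_t^2))
    for (t in 2:n) a[t] <- noise$rho_t * a[t - 1] + innov[t - 1]
  }
  exp(a - noise$sigma_t^2 / 2)
}

# Gaussian smoothing with reflecting boundaries, separable.
smooth_gauss <- function(m, ell) {
  if (ell <= 0) return(m)
  r <- max(1L, ceiling(3 * ell))
  k <- dnorm(-r:r, sd = ell); k <- k / sum(k)
  pad_reflect <- function(v, r) c(rev(v[seq_len(r)]), v,
                                  rev(v[length(v) - seq_len(r) + 1]))
  smooth1 <- function(v) {
    vp <- pad_reflect(v, r)
    stats::filter(vp, k, sides = 2)[(r + 1):(r + length(v))]
  }
  m <- apply(m, 2, smooth1)
  t(apply(m, 1, smooth1))
}

# One unit-variance smoothed white-noise field.
smoothed_white <- function(H, W, ell) {
  f <- smooth_gauss(matrix(rnorm(H * W), H, W), ell)
  f / sqrt(mean(f^2) + 1e-300)
}

# Unit-mean spatio-temporal field S(u, t) as a T x H x W array.
make_s_field <- function(nT, H, W, noise) {
  if (noise$sigma_s == 0) return(NULL)
  s <- array(0, c(nT, H, W))
  g <- noise$sigma_s * smoothed_white(H, W, noise$ell_s)
  s[1, , ] <- g
  if (nT > 1) {
    sc <- noise$sigma_s * sqrt(1 - noise$rho_s^2)
    for (t in 2:nT) {
      g <- noise$rho_s * g + sc * smoothed_white(H, W, noise$ell_s)
      s[t, , ] <- g
    }
  }
  exp(s - noise$sigma_s^2 / 2)
}

#' Sample Cox-process shot noise onto a clean sequence
#'
#' Draws, for every pixel and frame, a Poisson count with rate
#' `clean(u, t) * lambda2(t) * S(u, t)` (the clean sequence already carries
#' the spatial rate `lambda1` through background plus signal), then adds
#' optional Gaussian read noise. Fully reproducible under a fixed seed.
#'
#' @param clean An [image_sequence()] of nonnegative mean rates.
#' @param noise A [noise_model()].
#' @param seed Integer seed.
#' @return An [image_sequence()] of noisy counts (signed only if read noise
#'   is enabled). The realized `lambda2` series is attached as
#'   `meta$lambda2`.
#' @export
sample_shot_noise <- function(clean, noise = noise_model(), seed = NULL) {
  if (any(clean$frames < 0)) stop("clean rates must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  d <- dim(clean$frames)
  lam2 <- make_lambda2(d[1], noise)
  rate <- clean$frames * lam2            # recycles over t (first margin)
  s <- make_s_field(d[1], d[2], d[3], noise)
  if (!is.null(s)) rate <- rate * s
  x <- array(rpois(length(rate), rate), d)
  if (noise$read_noise_sd > 0)
    x <- x + array(rnorm(length(x), 0, noise$read_noise_sd), d)
  meta <- clean$meta
  meta$lambda2 <- lam2
  as_sequence_like(x, clean, signed = noise$read_noise_sd > 0, meta = meta)
}
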