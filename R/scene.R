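#' Event schedules for scripted particle dynamics
#'
#' Scenes are scripted from a small vocabulary of single-particle events:
#'
#' * `stationary_event()` — the particle sits still for the whole sequence.
#' * `collision_event()` — the particle descends along piecewise-linear
#'   `z(t)` waypoints; when it crosses `coupling_z` (default 1 nm) the
#'   quantum-coupling regime replaces classical electromagnetic coupling and
#'   the scattering phase switches instantaneously from `phase_before` to
#'   `phase_after`.
#' * `oxidation_event()` — amplitude and phase switch at `t_switch`
#'   (e.g. an Ag particle converting to AgCl under oxidation).
#' * `tether_event()` — Brownian motion constrained by a flexible linker of
#'   contour length `L` anchored at the particle's initial position.
#' * `binding_event()` — the particle is present only between frames `t1`
#'   and `t2` (binding/unbinding at a functionalized surface).
#'
#' Frames are 1-based indices into the simulated sequence; `z` waypoints are
#' heights of the particle bottom above the film in nm.
#'
#' @param t_frames,z_nm Waypoint frames and heights for a collision.
#' @param coupling_z Height (nm) at which the phase switch occurs.
#' @param phase_before,phase_after Scattering phases (rad).
#' @param t_switch Switch frame for an oxidation event.
#' @param amplitude_before,amplitude_after Amplitude multipliers applied to
#'   the particle's base amplitude before/after the switch.
#' @param L Tether contour length in nm (>= 0).
#' @param step_sd Per-frame Brownian step SD in nm.
#' @param t1,t2 Binding and unbinding frames.
#' @name event_schedule
NULL

#' @rdname event_schedule
#' @export
stationary_event <- function() structure(list(kind = "stationary"),
                                         class = "sprm_event")

#' @rdname event_schedule
#' @export
collision_event <- function(t_frames, z_nm, coupling_z = 1,
                            phase_before = 0.58 * pi,
                            phase_after = 0.13 * pi) {
  if (length(t_frames) != length(z_nm) || length(t_frames) < 2)
    stop("need matching waypoint vectors of length >= 2")
  if (any(diff(t_frames) <= 0)) stop("waypoint frames must increase")
  if (any(z_nm < 0)) stop("z waypoints must be >= 0")
  structure(list(kind = "collision", t_frames = t_frames, z_nm = z_nm,
                 coupling_z = coupling_z, phase_before = phase_before,
                 phase_after = phase_after), class = "sprm_event")
}

#' @rdname event_schedule
#' @export
oxidation_event <- function(t_switch, phase_before = 0.59 * pi,
                            phase_after = 0.09 * pi,
                            amplitude_before = 1, amplitude_after = 1) {
  structure(list(kind = "oxidation", t_switch = t_switch,
                 phase_before = phase_before, phase_after = phase_after,
                 amplitude_before = amplitude_before,
                 amplitude_after = amplitude_after), class = "sprm_event")
}

#' @rdname event_schedule
#' @export
tether_event <- function(L, step_sd = 50) {
  if (L < 0) stop("tether length must be >= 0")
  structure(list(kind = "tether", L = L, step_sd = step_sd),
            class = "sprm_event")
}

#' @rdname event_schedule
#' @param step_px Per-frame lateral random-walk step SD in pixels.
#' @export
walk_event <- function(step_px = 1) {
  structure(list(kind = "walk", step_px = step_px), class = "sprm_event")
}

#' @rdname event_schedule
#' @export
binding_event <- function(t1, t2, phase = 0.13 * pi) {
  if (t2 <= t1) stop("t2 must be > t1")
  structure(list(kind = "binding", t1 = t1, t2 = t2, phase = phase),
            class = "sprm_event")
}

#' Particle scene
#'
#' A list of particles, each a [particle_state()] paired with an event
#' schedule, that drives [simulate_sequence()].
#'
#' @param ... Entries of the form `list(particle = particle_state(...),
#'   event = <sprm_event>)`; the event defaults to [stationary_event()].
#' @return An object of class `sprm_scene`.
#' @export
particle_scene <- function(...) {
  entries <- list(...)
  for (e in entries) {
    if (!inherits(e$particle, "sprm_particle")) stop("missing particle state")
    if (!is.null(e$event) && !inherits(e$event, "sprm_event"))
      stop("event must be an sprm_event")
  }
  structure(entries, class = "sprm_scene")
}

#' Brownian motion of a tethered particle
#'
#' Simulates the reflected random walk of the center of a sphere of diameter
#' `D` attached to a flexible tether of contour length `L` anchored at a
#' point on the surface. The reachable set is the spherical cap
#' `|c - anchor| <= L + D/2` with `c_z >= D/2`; Gaussian steps are projected
#' back onto that set. The lateral range of the center is therefore bounded
#' by the chord-geometry value [theoretical_dmax()] and the axial excursion
#' of the particle bottom by `L`.
#'
#' @param L Tether contour length in nm (>= 0).
#' @param diameter Particle diameter in nm (> 0).
#' @param steps Number of frames.
#' @param step_sd Per-frame Gaussian step SD in nm (default 50; tethered
#'   particles are effectively equilibrated within the cap at 2 ms frames).
#' @param seed Integer seed.
#' @return A data.frame with per-frame center offsets `x`, `y` (nm, relative
#'   to the anchor) and `z`, the height of the particle bottom (nm).
#' @export
simulate_tethered_motion <- function(L, diameter, steps, step_sd = 50,
                                     seed = NULL) {
  if (L < 0) stop("L must be >= 0")
  if (diameter <= 0) stop("diameter must be > 0")
  if (!is.null(seed)) set.seed(seed)
  r <- diameter / 2
  rmax <- L + r
  c0 <- c(0, 0, r)                      # center start: resting on surface
  out <- matrix(0, steps, 3)
  pos <- c0
  dx <- matrix(rnorm(3 * steps, 0, step_sd), steps, 3)
  for (t in seq_len(steps)) {
    p <- pos + dx[t, ]
    if (p[3] < r) p[3] <- 2 * r - p[3]  # reflect at the surface
    nrm <- sqrt(sum(p^2))
    if (nrm > rmax) p <- p * (rmax / nrm)  # project onto the tether sphere
    if (p[3] < r) {                     # projection may re-violate the floor
      lat <- sqrt(max(rmax^2 - r^2, 0))
      xy <- p[1:2]
      nxy <- sqrt(sum(xy^2))
      if (nxy > 0) xy <- xy * (lat / nxy)
      p <- c(xy, r)
    }
    pos <- p
    out[t, ] <- pos
  }
  data.frame(x = out[, 1], y = out[, 2], z = out[, 3] - r)
}

# Resolve the per-frame state table of one scene entry.
schedule_states <- function(entry, optical, nT, px_nm, shape) {
  p <- entry$particle
  ev <- if (is.null(entry$event)) stationary_event() else entry$event
  base_A <- if (is.null(p$amplitude_A) || is.na(p$amplitude_A))
    amplitude_from_diameter(p$diameter, optical) else p$amplitude_A
  x <- rep(p$x, nT); y <- rep(p$y, nT); z <- rep(p$z, nT)
  A <- rep(base_A, nT); phi <- rep(p$phase_phi, nT)
  live <- rep(TRUE, nT)
  if (ev$kind == "collision") {
    tt <- pmin(pmax(seq_len(nT), min(ev$t_frames)), max(ev$t_frames))
    z <- approx(ev$t_frames, ev$z_nm, xout = tt)$y
    z[seq_len(nT) < min(ev$t_frames)] <- ev$z_nm[1]
    phi <- ifelse(z <= ev$coupling_z, ev$phase_after, ev$phase_before)
  } else if (ev$kind == "oxidation") {
    after <- seq_len(nT) >= ev$t_switch
    phi <- ifelse(after, ev$phase_after, ev$phase_before)
    A <- base_A * ifelse(after, ev$amplitude_after, ev$amplitude_before)
  } else if (ev$kind == "walk") {
    x <- p$x + cumsum(c(0, rnorm(nT - 1, 0, ev$step_px)))
    y <- p$y + cumsum(c(0, rnorm(nT - 1, 0, ev$step_px)))
    x <- pmin(pmax(x, 0), shape[2] - 1)
    y <- pmin(pmax(y, 0), shape[1] - 1)
  } else if (ev$kind == "tether") {
    tr <- simulate_tethered_motion(ev$L, p$diameter, nT, ev$step_sd)
    x <- pmin(pmax(p$x + tr$x / px_nm, 0), shape[2] - 1)
    y <- pmin(pmax(p$y + tr$y / px_nm, 0), shape[1] - 1)
    z <- tr$z
  } else if (ev$kind == "binding") {
    live <- seq_len(nT) >= ev$t1 & seq_len(nT) <= ev$t2
    phi <- rep(ev$phase, nT)
  }
  data.frame(t = seq_len(nT), x = x, y = y, z = z, amplitude = A,
             phase = phi, live = live)
}

#' Simulate a ground-truthed SPRM image sequence
#'
#' Renders the clean sequence (background plus every live particle's
#' interference pattern, with evanescent z-attenuation), samples Cox-process
#' shot noise on top, and returns both together with a per-frame ground-truth
#' table. Frame sizes that are not multiples of 16 are simulated with a
#' warning, since they cannot be fed to the denoising network downstream.
#'
#' @param scene A [particle_scene()] (may be empty).
#' @param optical An [optical_model()].
#' @param noise A [noise_model()].
#' @param T Number of frames (>= 4).
#' @param shape `c(H, W)` frame size in pixels.
#' @param seed Integer seed (drives scheduling and noise).
#' @param frame_interval Frame interval in ms (default 2).
#' @return A list with elements `noisy` and `clean` ([image_sequence()]s)
#'   and `truth`, a data.frame with one row per live particle per frame
#'   (`particle_id`, `t`, `x_px`, `y_px`, `z_nm`, `amplitude`, `phase`).
#' @export
simulate_sequence <- function(scene = particle_scene(),
                              optical = optical_model(),
                              noise = noise_model(), T = 8,
                              shape = c(64, 64), seed = NULL,
                              frame_interval = 2) {
  if (T < 4) stop("T must be >= 4")
  if (any(shape %% 16 != 0))
    warning("frame size not a multiple of 16; sequence cannot feed the ",
            "denoising network without cropping")
  if (!is.null(seed)) set.seed(seed)
  H <- shape[1]; W <- shape[2]
  px_nm <- optical$pixel_size * 1000
  clean <- array(optical$background_level, c(T, H, W))
  truth <- list()
  for (i in seq_along(scene)) {
    st <- schedule_states(scene[[i]], optical, T, px_nm, shape)
    for (t in seq_len(T)) {
      if (!st$live[t] || st$amplitude[t] == 0) next
      ps <- particle_state(x = st$x[t], y = st$y[t], z = st$z[t],
                           diameter = scene[[i]]$particle$diameter,
                           amplitude_A = st$amplitude[t],
                           phase_phi = st$phase[t])
      clean[t, , ] <- clean[t, , ] + render_psf_diff(optical, ps, shape)
    }
    tr <- st[st$live, , drop = FALSE]
    truth[[i]] <- data.frame(particle_id = i, t = tr$t, x_px = tr$x,
                             y_px = tr$y, z_nm = tr$z,
                             amplitude = tr$amplitude, phase = tr$phase)
  }
  clean[clean < 0] <- 0                 # deep fringes cannot go below zero
  meta <- list(optical = optical, seed = seed)
  clean_seq <- image_sequence(clean, frame_interval = frame_interval,
                              pixel_size = optical$pixel_size, meta = meta)
  noisy <- sample_shot_noise(clean_seq, noise)
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(particle_id = integer(), t = integer(), x_px = numeric(),
               y_px = numeric(), z_nm = numeric(), amplitude = numeric(),
               phase = numeric())
  list(noisy = noisy, clean = clean_seq, truth = truth)
}
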