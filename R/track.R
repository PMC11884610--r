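#' Track particles through a differential sequence
#'
#' Per-frame pipeline: (optional) denoising, matched-filter detection,
#' Richardson-Lucy reconstruction of a crop around each detection, sub-pixel
#' Gaussian localization, 5x5 intensity measurement and evanescent-decay
#' axial inference. Detections are linked frame-to-frame by nearest
#' neighbors under a maximum-jump gate; gaps up to `max_gap` frames are
#' bridged. `I0` for the z-inversion is each trajectory's maximum 5x5
#' reconstructed intensity (the particle closest to the surface).
#'
#' @param diff_seq A differential [image_sequence()].
#' @param optical An [optical_model()].
#' @param model Optional trained [build_denoiser()] model applied before
#'   detection.
#' @param threshold_db Detection threshold (default 9.54 dB).
#' @param max_jump Link gate in px per frame (default 5).
#' @param max_gap Longest bridged gap in frames (default 2).
#' @param rl_iterations RL iterations per crop.
#' @return A list of class `sprm_tracks`: `trajectories` (list of
#'   data.frames with `t`, `frame`, `x_px`, `y_px`, `x_nm`, `y_nm`, `z_nm`,
#'   `intensity`, `snr_db`) and `unlinked` (detections in no trajectory).
#' @export
track_particles <- function(diff_seq, optical = optical_model(),
                            model = NULL, threshold_db =
                              detection_limit_db(), max_jump = 5,
                            max_gap = 2, rl_iterations = 20) {
  if (!is.null(model)) diff_seq <- denoise(diff_seq, model)
  d <- dim(diff_seq$frames)
  kern <- rl_kernel(optical, extent = min(optical$psf_extent,
                                          (min(d[2:3]) - 1) %/% 2))
  px <- diff_seq$pixel_size
  active <- list()   # each: list(rows = data.frame, last_frame, last_xy)
  done <- list()
  unlinked <- list()
  for (t in seq_len(d[1])) {
    img <- get_frame(diff_seq, t)
    det <- detect_particles(img, optical, threshold_db)
    meas <- lapply(seq_len(nrow(det)), function(i) {
      refine_detection(img, c(det$x[i], det$y[i]), optical, kern,
                       rl_iterations, px, det$snr_db[i])
    })
    used <- logical(length(meas))
    # extend active tracks by nearest unused detection within the gate
    for (k in seq_along(active)) {
      tr <- active[[k]]
      if (t - tr$last_frame > max_gap + 1) next
      if (!length(meas)) next
      dd <- vapply(meas, function(m)
        sqrt(sum((c(m$x, m$y) - tr$last_xy)^2)), numeric(1))
      dd[used] <- Inf
      j <- which.min(dd)
      if (length(j) && is.finite(dd[j]) &&
          dd[j] <= max_jump * (t - tr$last_frame)) {
        used[j] <- TRUE
        m <- meas[[j]]
        tr$rows <- rbind(tr$rows, track_row(t, m, diff_seq$frame_interval))
        tr$last_frame <- t; tr$last_xy <- c(m$x, m$y)
        active[[k]] <- tr
      }
    }
    # retire stale tracks
    stale <- vapply(active, function(tr) t - tr$last_frame > max_gap,
                    logical(1))
    done <- c(done, active[stale])
    active <- active[!stale]
    # new tracks from unused detections
    for (j in which(!used)) {
      m <- meas[[j]]
      active[[length(active) + 1]] <-
        list(rows = track_row(t, m, diff_seq$frame_interval),
             last_frame = t, last_xy = c(m$x, m$y))
    }
  }
  done <- c(done, active)
  singles <- vapply(done, function(tr) nrow(tr$rows) == 1, logical(1))
  unlinked <- if (any(singles))
    do.call(rbind, lapply(done[singles], function(tr) tr$rows)) else NULL
  trajs <- lapply(done[!singles], function(tr) {
    rows <- tr$rows
    i0 <- max(rows$intensity)
    rows$z_nm <- infer_z(pmax(rows$intensity, 1e-12 * i0), i0,
                         optical$evanescent_decay_d)
    rows
  })
  structure(list(trajectories = trajs, unlinked = unlinked,
                 pixel_size = px), class = "sprm_tracks")
}

refine_detection <- function(img, xy, optical, kern, rl_iterations, px,
                             snr_db) {
  H <- nrow(img); W <- ncol(img)
  ext <- (nrow(kern) - 1) %/% 2
  # phase estimate from the central-pixel polarity, then reconstruct
  cx <- round(xy[1]); cy <- round(xy[2])
  phi <- if (img[cy + 1, cx + 1] >= 0) 0 else pi
  rec <- richardson_lucy(img, kern, rl_iterations, phase_phi = phi)
  loc <- localize_xy(rec, xy, pixel_size = px)
  inten <- tryCatch(measure_amplitude(rec, c(loc$x, loc$y)),
                    error = function(e) rec[cy + 1, cx + 1])
  list(x = loc$x, y = loc$y, x_nm = loc$x_nm, y_nm = loc$y_nm,
       intensity = max(inten, 0), snr_db = snr_db)
}

track_row <- function(t, m, frame_interval) {
  data.frame(frame = t, t_ms = (t - 1) * frame_interval, x_px = m$x,
             y_px = m$y, x_nm = m$x_nm, y_nm = m$y_nm, z_nm = NA_real_,
             intensity = m$intensity, snr_db = m$snr_db)
}

#' @export
print.sprm_tracks <- function(x, ...) {
  cat(sprintf("%d trajectories, %d unlinked detections\n",
              length(x$trajectories),
              if (is.null(x$unlinked)) 0 else nrow(x$unlinked)))
  invisible(x)
}

#' Displacement summary of a trajectory
#'
#' Empirical per-axis ranges (max minus min) of a trajectory, optionally
#' restricted to frames with `z <= z_max` (localization degrades away from
#' the surface), next to the chord-geometry bounds.
#'
#' @param traj A trajectory data.frame from [track_particles()], or any
#'   data.frame with `x_nm`, `y_nm`, `z_nm`.
#' @param diameter,L Particle diameter and tether contour length (nm) for
#'   the theoretical bounds; omit for empirical-only output.
#' @param z_max Axial cutoff in nm (default 20).
#' @return A list with `dx_max`, `dy_max`, `dz_max` and, when `diameter`
#'   and `L` are given, `dxy_max_theory`, `dz_max_theory`.
#' @export
displacement_summary <- function(traj, diameter = NULL, L = NULL,
                                 z_max = 20) {
  sel <- if (all(is.finite(traj$z_nm))) traj$z_nm <= z_max else
    rep(TRUE, nrow(traj))
  sub <- traj[sel, , drop = FALSE]
  out <- list(dx_max = diff(range(sub$x_nm)),
              dy_max = diff(range(sub$y_nm)),
              dz_max = diff(range(traj$z_nm[is.finite(traj$z_nm)])))
  if (!is.null(diameter) && !is.null(L)) {
    th <- theoretical_dmax(diameter, L)
    out$dxy_max_theory <- th$dxy_max
    out$dz_max_theory <- th$dz_max
  }
  out
}

#' Extract binding and unbinding events from an SNR time series
#'
#' Binding (appearance) and unbinding (disappearance) are detected as the
#' SNR crossing the detection threshold with hysteresis: a particle binds at
#' `t1` when SNR exceeds `threshold_db + hysteresis_db`, unbinds at `t2`
#' when it falls below `threshold_db - hysteresis_db`. Events shorter than
#' `min_dwell` frames are discarded; an event still open at the end of the
#' series is flagged right-censored. The bound lifetime is `dt = t2 - t1`.
#' Events are classified by dwell time: `>= long_s` seconds is long-lived
#' specific binding, shorter events are nonspecific; a series with
#' `>= intermittent_k` short events is intermittent Brownian revisiting.
#'
#' @param snr_series Numeric vector of per-frame SNR (dB); NA = below
#'   detection.
#' @param fps Frame rate (default 500).
#' @param threshold_db Detection threshold (default 9.54 dB).
#' @param hysteresis_db Hysteresis half-width (default 1 dB).
#' @param min_dwell Minimum event length in frames (default 3).
#' @param long_s Specific-binding dwell threshold in seconds (default 0.5).
#' @param intermittent_k Short-event count that marks a series intermittent
#'   (default 3).
#' @return A list of class `sprm_events`: `events` data.frame (`t1`, `t2`
#'   frames, `t1_ms`, `t2_ms`, `dt_ms`, `censored`, `class`) and
#'   `series_class` (`"specific"`, `"nonspecific"`, `"intermittent"`, or
#'   `"none"`).
#' @export
extract_binding_events <- function(snr_series, fps = 500,
                                   threshold_db = detection_limit_db(),
                                   hysteresis_db = 1, min_dwell = 3,
                                   long_s = 0.5, intermittent_k = 3) {
  n <- length(snr_series)
  if (n <= min_dwell) stop("series shorter than minimum dwell")
  hi <- threshold_db + hysteresis_db
  lo <- threshold_db - hysteresis_db
  v <- ifelse(is.na(snr_series), -Inf, snr_series)
  bound <- FALSE; t1 <- NA_integer_
  ev <- list()
  for (t in seq_len(n)) {
    if (!bound && v[t] >= hi) { bound <- TRUE; t1 <- t }
    else if (bound && v[t] <= lo) {
      if (t - t1 >= min_dwell)
        ev[[length(ev) + 1]] <- c(t1 = t1, t2 = t, censored = 0)
      bound <- FALSE
    }
  }
  if (bound && n - t1 >= min_dwell)
    ev[[length(ev) + 1]] <- c(t1 = t1, t2 = n, censored = 1)
  ms <- 1000 / fps
  if (!length(ev)) {
    return(structure(list(events = data.frame(
      t1 = integer(), t2 = integer(), t1_ms = numeric(), t2_ms = numeric(),
      dt_ms = numeric(), censored = logical(), class = character()),
      series_class = "none"), class = "sprm_events"))
  }
  m <- do.call(rbind, ev)
  events <- data.frame(t1 = m[, 1], t2 = m[, 2],
                       t1_ms = (m[, 1] - 1) * ms, t2_ms = (m[, 2] - 1) * ms,
                       dt_ms = (m[, 2] - m[, 1]) * ms,
                       censored = m[, 3] == 1)
  events$class <- ifelse(events$dt_ms >= long_s * 1000, "specific",
                         "nonspecific")
  n_short <- sum(events$class == "nonspecific")
  series_class <- if (n_short >= intermittent_k) "intermittent"
  else if (any(events$class == "specific")) "specific"
  else if (n_short > 0) "nonspecific" else "none"
  structure(list(events = events, series_class = series_class),
            class = "sprm_events")
}
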