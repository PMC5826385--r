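#' Lag-waveform parameters
#'
#' The brain-skull relative-displacement waveform used by
#' [synthesize_trajectories()]: two smooth bumps tied to the acceleration
#' and deceleration phases of the pulse.  The first (lag) bump peaks near
#' the end of acceleration at `accel_frac * peak_rel_disp`; the second
#' (overshoot) bump rises through the deceleration ramp, attains exactly
#' `peak_rel_disp` at the end of deceleration, then relaxes over
#' `relax_time` toward `residual_frac * peak_rel_disp` and holds.  This
#' reproduces the qualitative structure observed in transection
#' experiments — two displacement peaks per pulse with the global maximum
#' at the end of deceleration and a small persistent post-motion offset —
#' without asserting any particular tissue dynamics.
#'
#' @param peak_rel_disp Peak relative displacement (mm), >= 0. Set 0 to
#'   disable the lag model entirely.
#' @param accel_frac First-bump amplitude as a fraction of the peak.
#' @param residual_frac Post-motion residual as a fraction of the peak.
#' @param relax_time Relaxation time after deceleration end (s).
#' @return List of class `lag_model`.
#' @export
lag_model <- function(peak_rel_disp = 0.75, accel_frac = 0.55,
                      residual_frac = 0.2, relax_time = 0.01) {
  stopifnot(peak_rel_disp >= 0, accel_frac >= 0, accel_frac < 1,
            residual_frac >= 0, residual_frac < 1, relax_time > 0)
  structure(list(peak_rel_disp = peak_rel_disp, accel_frac = accel_frac,
                 residual_frac = residual_frac, relax_time = relax_time),
            class = "lag_model")
}

# Signed tangential lag waveform on times t (s), for a pulse whose motion
# starts at t = t0.  Negative during acceleration (brain trails the
# skull), positive through deceleration with maximum +peak at decel end.
lag_waveform <- function(t, pulse, lag, t0 = 0) {
  ph <- pulse_phases(pulse)
  peak <- lag$peak_rel_disp
  if (peak == 0) return(numeric(length(t)))
  c1 <- t0 + ph$accel_end
  c2 <- t0 + ph$decel_end
  w1 <- ph$accel_end                         # lag bump halfwidth
  rise <- c2 - c1                            # overshoot rise span
  b1 <- raised_cos(t, c1, w1)
  # overshoot: raised-cosine rise on [c1, c2], relaxation after c2
  b2 <- numeric(length(t))
  i <- t > c1 & t <= c2
  b2[i] <- 0.5 * (1 - cos(pi * (t[i] - c1) / rise))
  j <- t > c2
  s <- pmin((t[j] - c2) / lag$relax_time, 1)
  b2[j] <- lag$residual_frac + (1 - lag$residual_frac) * 0.5 * (1 + cos(pi * s))
  -lag$accel_frac * peak * b1 + peak * b2
}

raised_cos <- function(t, center, halfwidth) {
  u <- abs(t - center) / halfwidth
  ifelse(u < 1, 0.5 * (1 + cos(pi * u)), 0)
}

#' Synthesize ground-truth marker trajectories
#'
#' Moves a [generate_layout()] marker set through a [generate_pulse()]
#' rotation about `rotation_center`.  Rigid markers undergo the exact
#' rigid-body rotation; brain markers additionally slide along their local
#' tangential direction (the direction of motion about the rotation
#' centre) by the signed [lag_model()] waveform, emulating inertial
#' brain-skull lag.  Independent Gaussian jitter of `noise_sd` mm per
#' coordinate per sample emulates centroid digitization noise; the
#' ground-truth relative displacement (|waveform|) is recorded before
#' jitter is applied.
#'
#' @param layout A `marker_layout`.
#' @param pulse A `rotation_pulse`.
#' @param lag A [lag_model()]; `lag_model(0)` disables relative motion.
#' @param noise_sd Coordinate jitter SD (mm); 0.13 mm per axis per marker
#'   reproduces the ~0.31 mm pre-motion pair error scale of the physical
#'   experiments.
#' @param seed Integer seed for the jitter.
#' @param rotation_center Rotation centre (mm) in layout coordinates;
#'   default `c(0, -40)` places it inferior to the section, within the
#'   cervical spine of the potted specimen.
#' @param lead_in Static time before motion starts (s); default 0.02 s
#'   (>= 50 pre-motion frames at 2500 fps).
#' @param hold Static-skull time appended after the pulse ends (s).
#' @param radial_frac Fraction of the lag applied along the local radial
#'   (outward) direction instead of tangentially; default 0.
#'
#' @return A tibble of class `marker_trajectories` with columns `time`
#'   (s), `marker_id`, `label`, `x_mm`, `y_mm`; attributes `truth` (tibble
#'   `time`, `marker_id`, `rel_disp_mm` for brain markers),
#'   `motion_start_time`, `rotation_center`, `dot_diameter`, `pulse`.
#' @export
synthesize_trajectories <- function(layout, pulse, lag = lag_model(0),
                                    noise_sd = 0, seed = 0,
                                    rotation_center = c(0, -40),
                                    lead_in = 0.02, hold = 0.02,
                                    radial_frac = 0) {
  stopifnot(inherits(layout, "marker_layout"), inherits(pulse, "rotation_pulse"),
            noise_sd >= 0, lead_in >= 0, hold >= 0)
  dt <- pulse$time[2] - pulse$time[1]
  dur <- pulse_phases(pulse)$duration
  time <- seq(0, lead_in + dur + hold, by = dt)

  omega <- pulse_omega_at(pulse, time - lead_in)
  theta <- pulse_angle(time, omega)
  ct <- cos(theta); st <- sin(theta)

  n_t <- length(time)
  ids <- layout$marker_id
  lab <- layout$label
  px <- layout$x_mm - rotation_center[1]
  py <- layout$y_mm - rotation_center[2]

  # rigid motion for every marker: outer products give (time x marker)
  X <- outer(ct, px) - outer(st, py) + rotation_center[1]
  Y <- outer(st, px) + outer(ct, py) + rotation_center[2]

  w <- lag_waveform(time, pulse, lag, t0 = lead_in)
  is_brain <- lab == "brain"
  if (any(is_brain) && lag$peak_rel_disp > 0) {
    # unit tangential direction (direction of motion) at each time/marker
    for (k in which(is_brain)) {
      rx <- X[, k] - rotation_center[1]
      ry <- Y[, k] - rotation_center[2]
      rn <- sqrt(rx^2 + ry^2)
      tx <- -ry / rn; ty <- rx / rn
      ox <- (1 - radial_frac) * tx + radial_frac * rx / rn
      oy <- (1 - radial_frac) * ty + radial_frac * ry / rn
      X[, k] <- X[, k] + w * ox
      Y[, k] <- Y[, k] + w * oy
    }
  }

  truth <- tidyr::expand_grid(marker_id = ids[is_brain], time = time) %>%
    mutate(rel_disp_mm = rep(abs(w), times = sum(is_brain))) %>%
    select("time", "marker_id", "rel_disp_mm")

  if (noise_sd > 0) {
    set.seed(seed)
    X <- X + rnorm(length(X), sd = noise_sd)
    Y <- Y + rnorm(length(Y), sd = noise_sd)
  }

  out <- tibble(
    time = rep(time, times = length(ids)),
    marker_id = rep(ids, each = n_t),
    label = rep(lab, each = n_t),
    x_mm = as.vector(X),
    y_mm = as.vector(Y))
  structure(out,
            truth = truth,
            motion_start_time = lead_in,
            rotation_center = rotation_center,
            dot_diameter = attr(layout, "dot_diameter"),
            rigid_radius = attr(layout, "rigid_radius"),
            pulse = pulse,
            class = c("marker_trajectories", class(out)))
}

#' Write / read trajectories CSV (`frame, marker_id, label, x, y`)
#'
#' Pixel-unit export is produced by [rasterize_frames()] bookkeeping; this
#' writer stores the ground-frame mm columns (`x_mm`, `y_mm`).
#' @param traj A `marker_trajectories` tibble.
#' @param path File path.
#' @export
write_trajectories_csv <- function(traj, path) {
  readr::write_csv(as_tibble(traj), path)
  invisible(path)
}

#' @rdname write_trajectories_csv
#' @export
read_trajectories_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}
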