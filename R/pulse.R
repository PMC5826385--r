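#' Generate an angular-velocity rotation pulse
#'
#' Constructs the angular velocity-time history of a single rapid head
#' rotation: a half-cosine ramp up limited by `peak_accel`, an optional
#' constant-velocity plateau, and a half-cosine ramp down limited by
#' `peak_decel`.  The profile is C1-smooth, starts and ends at zero
#' velocity, reaches exactly `peak_velocity`, and integrates to exactly
#' `total_angle`.  Defaults emulate a 65 degree sagittal-plane rotation of
#' a transected neonatal piglet head on a pneumatic rotation device
#' (peak velocity near 52 rad/s, accelerations of several krad/s^2),
#' sampled at the 10 kHz rate of the angular-rate sensors.
#'
#' For a half-cosine ramp of duration `T` to velocity `V`, the peak
#' acceleration is `V * pi / (2 * T)`, so the ramp durations are fixed by
#' the requested peaks; the plateau absorbs the remaining angle.  When the
#' requested `total_angle` is smaller than the angle swept by the two ramps
#' alone the pulse is infeasible and an error names the minimum achievable
#' angle.
#'
#' @param peak_velocity Peak angular velocity (rad/s), > 0.
#' @param peak_accel Peak angular acceleration (rad/s^2), > 0.
#' @param peak_decel Peak angular deceleration magnitude (rad/s^2), > 0.
#' @param total_angle Total rotation angle (rad), > 0. Default 65 degrees.
#' @param dt Sample interval (s). Default 1e-4 (10 kHz).
#'
#' @return A tibble of class `rotation_pulse` with columns `time` (s),
#'   `omega` (rad/s) and `alpha` (rad/s^2, central finite difference of
#'   `omega`), and attributes `total_angle`, `peak_velocity`,
#'   `ramp_up`, `plateau`, `ramp_down` (durations, s).
#' @examples
#' p <- generate_pulse(52, 9600, 6800, total_angle = 1.134)
#' max(p$omega)
#' @export
generate_pulse <- function(peak_velocity, peak_accel, peak_decel,
                           total_angle = 65 * pi / 180, dt = 1e-4) {
  if (!is.finite(peak_velocity) || peak_velocity <= 0) {
    abort("`peak_velocity` must be positive (zero motion cannot sweep a positive angle).")
  }
  stopifnot(peak_accel > 0, peak_decel > 0, total_angle > 0, dt > 0)

  t_up <- peak_velocity * pi / (2 * peak_accel)
  t_down <- peak_velocity * pi / (2 * peak_decel)
  ramp_angle <- peak_velocity * (t_up + t_down) / 2
  if (total_angle < ramp_angle - 1e-12) {
    abort(sprintf(
      paste0("Infeasible pulse: total_angle = %.4g rad is below the ",
             "minimum achievable angle %.4g rad for the requested peaks."),
      total_angle, ramp_angle))
  }
  t_plateau <- (total_angle - ramp_angle) / peak_velocity
  t_end <- t_up + t_plateau + t_down

  # uniform grid covering the pulse exactly (step adjusted below dt if needed)
  n <- ceiling(t_end / dt)
  time <- seq(0, n) * (t_end / n)
  omega <- pulse_omega(time, peak_velocity, t_up, t_plateau, t_down)
  alpha <- finite_diff(omega, time)

  out <- tibble(time = time, omega = omega, alpha = alpha)
  structure(
    out,
    total_angle = total_angle,
    peak_velocity = peak_velocity,
    ramp_up = t_up, plateau = t_plateau, ramp_down = t_down,
    class = c("rotation_pulse", class(out))
  )
}

# Piecewise half-cosine / plateau / half-cosine velocity profile.
pulse_omega <- function(t, v, t_up, t_plateau, t_down) {
  t1 <- t_up
  t2 <- t_up + t_plateau
  t3 <- t2 + t_down
  w <- numeric(length(t))
  i <- t >= 0 & t < t1
  w[i] <- v / 2 * (1 - cos(pi * t[i] / t_up))
  i <- t >= t1 & t <= t2
  w[i] <- v
  i <- t > t2 & t <= t3
  w[i] <- v / 2 * (1 + cos(pi * (t[i] - t2) / t_down))
  w
}

# Central finite difference on a (possibly non-uniform) grid.
finite_diff <- function(y, x) {
  n <- length(y)
  if (n < 3) return(rep(0, n))
  d <- numeric(n)
  d[2:(n - 1)] <- (y[3:n] - y[1:(n - 2)]) / (x[3:n] - x[1:(n - 2)])
  d[1] <- (y[2] - y[1]) / (x[2] - x[1])
  d[n] <- (y[n] - y[n - 1]) / (x[n] - x[n - 1])
  d
}

#' Integrated angle of a rotation pulse
#'
#' Trapezoidal integral of the angular velocity; also usable on any
#' time/velocity pair.
#'
#' @param time Time vector (s).
#' @param omega Angular velocity vector (rad/s).
#' @return Cumulative angle (rad) at each sample.
#' @export
pulse_angle <- function(time, omega) {
  n <- length(time)
  c(0, cumsum((omega[-1] + omega[-n]) / 2 * diff(time)))
}

#' Evaluate pulse angular velocity at arbitrary times
#'
#' Linear interpolation; zero outside the pulse support.
#' @param pulse A `rotation_pulse`.
#' @param t Times (s) at which to evaluate.
#' @return Angular velocity (rad/s) at `t`.
#' @export
pulse_omega_at <- function(pulse, t) {
  approx(pulse$time, pulse$omega, xout = t, yleft = 0, yright = 0)$y
}

#' Key instants of a rotation pulse
#'
#' @param pulse A `rotation_pulse`.
#' @return Named list with `accel_end`, `decel_start`, `decel_end` (s) and
#'   `duration` (s).
#' @export
pulse_phases <- function(pulse) {
  t_up <- attr(pulse, "ramp_up")
  t_pl <- attr(pulse, "plateau")
  t_dn <- attr(pulse, "ramp_down")
  list(accel_end = t_up,
       decel_start = t_up + t_pl,
       decel_end = t_up + t_pl + t_dn,
       duration = t_up + t_pl + t_dn)
}

#' Write / read a pulse CSV (`time_s, omega_rad_s`)
#'
#' @param pulse A `rotation_pulse` (or tibble with `time`, `omega`).
#' @param path File path.
#' @return `read_pulse_csv()` returns a `rotation_pulse` rebuilt from the
#'   file (angle and peaks recomputed from the samples).
#' @export
write_pulse_csv <- function(pulse, path) {
  readr::write_csv(tibble(time_s = pulse$time, omega_rad_s = pulse$omega), path)
  invisible(path)
}

#' @rdname write_pulse_csv
#' @export
read_pulse_csv <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  out <- tibble(time = d$time_s, omega = d$omega_rad_s,
                alpha = finite_diff(d$omega_rad_s, d$time_s))
  ang <- pulse_angle(out$time, out$omega)
  structure(out,
            total_angle = ang[length(ang)],
            peak_velocity = max(out$omega),
            class = c("rotation_pulse", class(out)))
}

#' @export
autoplot.rotation_pulse <- function(object, ...) {
  d <- tidyr::pivot_longer(
    tibble(time = object$time, `angular velocity (rad/s)` = object$omega,
           `angular acceleration (rad/s²)` = object$alpha),
    -"time", names_to = "channel", values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(.data$time, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~channel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL)
}
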