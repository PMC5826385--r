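#' Cross-section outline profiles
#'
#' Polar outline radius r(theta) of the transected cross-section, in mm
#' about the section centroid.  Three profiles are available:
#'
#' * `"sagittal"`: irregular closed curve emulating a midsagittal neonatal
#'   piglet brain section — anterior-posterior elongation, a smooth
#'   superior arc, an olfactory prominence anterior-inferiorly, a
#'   cerebellar lobe posteriorly and a motion-restricting brainstem notch
#'   inferior-posteriorly.  Convention: theta = 0 anterior, pi/2 superior.
#' * `"axial"`: smooth ovoid (the axially transected section is rounder
#'   and more symmetric).
#' * `"circle"`: reference disc.
#'
#' All profiles are star-shaped about the origin, so a point is inside the
#' section iff its radius is below `section_radius(theta)`.
#'
#' @param theta Angle(s), rad.
#' @param profile One of `"sagittal"`, `"axial"`, `"circle"`.
#' @param base_radius Overall scale (mm). Default 25 mm (neonatal piglet
#'   hemisection scale).
#' @return Radius (mm) at each `theta`.
#' @export
section_radius <- function(theta, profile = c("sagittal", "axial", "circle"),
                           base_radius = 25) {
  profile <- match.arg(profile)
  switch(profile,
    circle = rep(base_radius, length(theta)),
    axial = {
      a <- 1.12 * base_radius
      b <- 0.92 * base_radius
      r <- a * b / sqrt((b * cos(theta))^2 + (a * sin(theta))^2)
      r * (1 + 0.04 * cos(theta))
    },
    sagittal = {
      r <- base_radius * (1 + 0.14 * cos(2 * theta))
      r * (1 +
        0.10 * ang_bump(theta, -30 * pi / 180, 18 * pi / 180) +  # olfactory
        0.14 * ang_bump(theta, 205 * pi / 180, 20 * pi / 180) -  # cerebellum
        0.22 * ang_bump(theta, 250 * pi / 180, 16 * pi / 180))   # brainstem notch
    })
}

# Wrapped Gaussian bump in angle.
ang_bump <- function(theta, mu, sigma) {
  d <- atan2(sin(theta - mu), cos(theta - mu))
  exp(-d^2 / (2 * sigma^2))
}

#' Dense polyline of a section outline
#'
#' @inheritParams section_radius
#' @param n Number of vertices.
#' @return Tibble with `theta`, `x_mm`, `y_mm`, and cumulative arclength
#'   `s_mm` (starting at 0 for theta = 0).
#' @export
section_outline <- function(profile = c("sagittal", "axial", "circle"),
                            base_radius = 25, n = 720) {
  profile <- match.arg(profile)
  theta <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  r <- section_radius(theta, profile, base_radius)
  x <- r * cos(theta)
  y <- r * sin(theta)
  ds <- sqrt(diff(c(x, x[1]))^2 + diff(c(y, y[1]))^2)
  tibble(theta = theta, x_mm = x, y_mm = y, s_mm = cumsum(c(0, ds[-n])))
}
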