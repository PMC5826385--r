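#' Generate an ink-dot marker layout
#'
#' Places `n_brain` dots on the periphery of the transected brain surface
#' and `n_rigid` dots on the surrounding rigid (skull / potting) annulus,
#' emulating the India-ink dot pattern of a transection experiment: 24-48
#' brain dots and 6-16 rigid dots of roughly 2-3 mm diameter under the
#' default configuration.  Dots are spread evenly in arclength with a
#' small seeded jitter; no two dot centres come closer than one dot
#' diameter (an error names the maximum feasible count otherwise).
#'
#' @param n_brain Number of brain-surface dots.
#' @param n_rigid Number of rigid-surface dots.
#' @param profile Section profile for the brain outline (see
#'   [section_radius()]).
#' @param seed Integer seed; layouts are reproducible for a fixed seed.
#' @param dot_diameter Dot diameter (mm), default 2.5.
#' @param base_radius Brain outline scale (mm).
#' @param rigid_offset Radial gap between the brain outline and the rigid
#'   annulus (mm), default 7.
#' @param inset Fraction of the local outline radius at which brain dots
#'   sit (slightly inside the cut surface edge), default 0.92.
#'
#' @return A tibble of class `marker_layout` with columns `marker_id`,
#'   `label` (`"brain"`/`"rigid"`), `x_mm`, `y_mm`; attributes
#'   `dot_diameter`, `profile`, `base_radius`, `rigid_radius`, `center`
#'   (section centroid, always `c(0, 0)`).
#' @examples
#' lay <- generate_layout(13, 6, "sagittal", seed = 1)
#' table(lay$label)
#' @export
generate_layout <- function(n_brain = 30, n_rigid = 10,
                            profile = c("sagittal", "axial", "circle"),
                            seed = 0, dot_diameter = 2.5, base_radius = 25,
                            rigid_offset = 7, inset = 0.92) {
  profile <- match.arg(profile)
  stopifnot(n_brain >= 0, n_rigid >= 0)
  outline <- section_outline(profile, base_radius)
  perim <- max(outline$s_mm) + sqrt(
    (outline$x_mm[1] - outline$x_mm[nrow(outline)])^2 +
    (outline$y_mm[1] - outline$y_mm[nrow(outline)])^2)
  max_brain <- floor(0.85 * perim / dot_diameter)
  if (n_brain > max_brain) {
    abort(sprintf("Overcrowded layout: at most %d brain dots fit on a %.0f mm perimeter.",
                  max_brain, perim))
  }
  rigid_radius <- max(section_radius(seq(0, 2 * pi, length.out = 361), profile,
                                     base_radius)) + rigid_offset
  max_rigid <- floor(0.85 * 2 * pi * rigid_radius / dot_diameter)
  if (n_rigid > max_rigid) {
    abort(sprintf("Overcrowded layout: at most %d rigid dots fit on the annulus.",
                  max_rigid))
  }

  set.seed(seed)
  brain <- if (n_brain > 0) {
    s <- even_jittered(n_brain, perim, jitter_frac = 0.2)
    th <- approx(c(outline$s_mm, perim), c(outline$theta, 2 * pi), xout = s)$y
    r <- inset * section_radius(th, profile, base_radius)
    tibble(marker_id = sprintf("b%02d", seq_len(n_brain)), label = "brain",
           x_mm = r * cos(th), y_mm = r * sin(th))
  } else {
    tibble(marker_id = character(), label = character(),
           x_mm = numeric(), y_mm = numeric())
  }
  rigid <- if (n_rigid > 0) {
    th <- even_jittered(n_rigid, 2 * pi, jitter_frac = 0.2)
    tibble(marker_id = sprintf("r%02d", seq_len(n_rigid)), label = "rigid",
           x_mm = rigid_radius * cos(th), y_mm = rigid_radius * sin(th))
  } else {
    tibble(marker_id = character(), label = character(),
           x_mm = numeric(), y_mm = numeric())
  }
  out <- bind_rows(brain, rigid)

  if (nrow(out) > 1) {
    d <- as.matrix(stats::dist(out[, c("x_mm", "y_mm")]))
    diag(d) <- Inf
    if (min(d) < dot_diameter) {
      abort(sprintf("Layout violates minimum spacing: closest centres %.2f mm < dot diameter %.2f mm.",
                    min(d), dot_diameter))
    }
  }
  structure(out,
            dot_diameter = dot_diameter, profile = profile,
            base_radius = base_radius, rigid_radius = rigid_radius,
            center = c(0, 0),
            class = c("marker_layout", class(out)))
}

# n positions evenly spread over [0, total) with bounded jitter, so the
# minimum gap stays >= (1 - 2*jitter_frac) * total/n.
even_jittered <- function(n, total, jitter_frac = 0.2) {
  base <- (seq_len(n) - 0.5) / n * total
  jit <- runif(n, -jitter_frac, jitter_frac) * total / n
  (base + jit) %% total
}

#' @export
autoplot.marker_layout <- function(object, ...) {
  outline <- section_outline(attr(object, "profile"), attr(object, "base_radius"))
  ggplot2::ggplot(object, ggplot2::aes(.data$x_mm, .data$y_mm,
                                       colour = .data$label)) +
    ggplot2::geom_path(data = outline, ggplot2::aes(.data$x_mm, .data$y_mm),
                       inherit.aes = FALSE, colour = "grey50") +
    ggplot2::geom_point(size = 2) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)")
}
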