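#' Rasterize trajectories into a grayscale frame stack
#'
#' Renders each marker as an anti-aliased dark disk on a lighter
#' background, emulating the high-speed video of a transection experiment
#' (default 2,500 fps, 320 x 480 px, 0.41 mm/px, 8-bit).  Trajectories are
#' temporally resampled to the frame rate; the frame count equals the
#' resampled sample count.  Pixel coverage of each disk is computed with a
#' linear edge ramp (area-weighted anti-aliasing), so the intensity
#' centroid quantization error is well below one pixel.
#'
#' Coordinate convention: image pixels use 0-based (x = column, y = row)
#' indices with x rightward and y downward; pixel centres sit at integer
#' coordinates.  Physical coordinates are x-right / y-up in mm.  The
#' mapping is `x_px = (x_mm - origin[1]) * px_per_mm`,
#' `y_px = (origin[2] - y_mm) * px_per_mm`; `origin` defaults to centring
#' the swept marker bounding box in the frame.
#'
#' @param traj A `marker_trajectories` tibble.
#' @param px_per_mm Pixels per mm (default 1/0.41).
#' @param frame_rate Frames per second (default 2500).
#' @param shape Frame shape `c(rows, cols)` (default `c(320, 480)`).
#' @param bit_depth Intensity quantization depth (default 8; use `NULL`
#'   for unquantized doubles).
#' @param background Background intensity in \[0, 1\].
#' @param dot_intensity Disk core intensity in \[0, 1\] (darker than
#'   background).
#' @param flicker_amp Relative amplitude of a 120 Hz sinusoidal
#'   illumination flicker (ambient-light aliasing); 0 disables it.
#' @param origin Optional `c(x_mm, y_mm)` of the physical point mapped to
#'   pixel `(x = 0, y = 0)` (top-left pixel centre).
#'
#' @return A list of class `frame_stack`: `frames` (array frame x row x
#'   col, values in \[0, 1\]), `times` (s), `px_per_mm`, `frame_rate`,
#'   `origin`, `dot_radius_px`, and `truth_px` (tibble `frame`,
#'   `marker_id`, `label`, `x_px`, `y_px` of resampled true centroids).
#' @export
rasterize_frames <- function(traj, px_per_mm = 1 / 0.41, frame_rate = 2500,
                             shape = c(320, 480), bit_depth = 8,
                             background = 0.8, dot_intensity = 0.12,
                             flicker_amp = 0, origin = NULL) {
  stopifnot(inherits(traj, "marker_trajectories") || is.data.frame(traj))
  dot_diameter <- attr(traj, "dot_diameter") %||% 2.5
  t_end <- max(traj$time)
  times <- seq(0, t_end, by = 1 / frame_rate)
  nf <- length(times)
  nr <- shape[1]; nc <- shape[2]

  resampled <- traj %>%
    group_by(.data$marker_id, .data$label) %>%
    summarise(
      frame = list(seq_len(nf) - 1L),
      x_mm = list(approx(.data$time, .data$x_mm, xout = times, rule = 2)$y),
      y_mm = list(approx(.data$time, .data$y_mm, xout = times, rule = 2)$y),
      .groups = "drop") %>%
    tidyr::unnest(c("frame", "x_mm", "y_mm"))

  if (is.null(origin)) {
    # centre the swept bounding box in the frame
    cx <- (min(resampled$x_mm) + max(resampled$x_mm)) / 2
    cy <- (min(resampled$y_mm) + max(resampled$y_mm)) / 2
    origin <- c(cx - (nc - 1) / 2 / px_per_mm, cy + (nr - 1) / 2 / px_per_mm)
  }
  resampled <- resampled %>%
    mutate(x_px = (.data$x_mm - origin[1]) * px_per_mm,
           y_px = (origin[2] - .data$y_mm) * px_per_mm)

  radius_px <- dot_diameter / 2 * px_per_mm
  out_of_frame <- resampled %>%
    filter(.data$x_px < radius_px | .data$x_px > nc - 1 - radius_px |
           .data$y_px < radius_px | .data$y_px > nr - 1 - radius_px)
  if (nrow(out_of_frame) > 0) {
    bad <- out_of_frame %>% slice(1)
    abort(sprintf(
      "Marker %s leaves the field of view at frame %d (%.1f, %.1f px); %d offending samples total.",
      bad$marker_id, bad$frame, bad$x_px, bad$y_px, nrow(out_of_frame)))
  }

  frames <- array(0, dim = c(nf, nr, nc))
  flick <- 1 + flicker_amp * sin(2 * pi * 120 * times)
  by_frame <- split(resampled, factor(resampled$frame, levels = seq_len(nf) - 1L))
  for (f in seq_len(nf)) {
    img <- matrix(background * flick[f], nr, nc)
    mk <- by_frame[[f]]
    cov <- matrix(0, nr, nc)
    for (k in seq_len(nrow(mk))) {
      xc <- mk$x_px[k]; yc <- mk$y_px[k]
      j0 <- max(0L, floor(xc - radius_px - 1)); j1 <- min(nc - 1L, ceiling(xc + radius_px + 1))
      i0 <- max(0L, floor(yc - radius_px - 1)); i1 <- min(nr - 1L, ceiling(yc + radius_px + 1))
      jj <- j0:j1; ii <- i0:i1
      d <- sqrt(outer((ii - yc)^2, (jj - xc)^2, "+"))
      c_loc <- pmin(pmax(radius_px + 0.5 - d, 0), 1)
      sub <- cov[ii + 1L, jj + 1L, drop = FALSE]
      cov[ii + 1L, jj + 1L] <- pmax(sub, c_loc)
    }
    img <- img - (img - dot_intensity * flick[f]) * cov
    frames[f, , ] <- img
  }
  if (!is.null(bit_depth)) {
    lev <- 2^bit_depth - 1
    frames <- round(pmin(pmax(frames, 0), 1) * lev) / lev
  }
  structure(list(frames = frames, times = times, px_per_mm = px_per_mm,
                 frame_rate = frame_rate, origin = origin,
                 dot_radius_px = radius_px,
                 truth_px = resampled %>%
                   select("frame", "marker_id", "label", "x_px", "y_px")),
            class = "frame_stack")
}

#' Convert between physical mm and pixel coordinates of a frame stack
#'
#' @param xy Two-column matrix or data frame (`x`, `y`).
#' @param stack A `frame_stack` (uses its `origin` and `px_per_mm`).
#' @return Two-column matrix in the target coordinates.
#' @export
mm_to_px <- function(xy, stack) {
  xy <- as.matrix(xy)
  cbind(x_px = (xy[, 1] - stack$origin[1]) * stack$px_per_mm,
        y_px = (stack$origin[2] - xy[, 2]) * stack$px_per_mm)
}

#' @rdname mm_to_px
#' @export
px_to_mm <- function(xy, stack) {
  xy <- as.matrix(xy)
  cbind(x_mm = xy[, 1] / stack$px_per_mm + stack$origin[1],
        y_mm = stack$origin[2] - xy[, 2] / stack$px_per_mm)
}

#' Write a frame stack as plain-text PGM (P2) files
#'
#' One ASCII PGM per frame (`frame_0000.pgm`, ...), a portable text image
#' format viewable with standard tools.
#'
#' @param stack A `frame_stack`.
#' @param dir Output directory (created if missing).
#' @param bit_depth Output depth (default 8).
#' @return Invisibly, the written file paths.
#' @export
write_frames_pgm <- function(stack, dir, bit_depth = 8) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  lev <- 2^bit_depth - 1
  nf <- dim(stack$frames)[1]
  paths <- character(nf)
  for (f in seq_len(nf)) {
    img <- round(stack$frames[f, , ] * lev)
    path <- file.path(dir, sprintf("frame_%04d.pgm", f - 1))
    con <- file(path, "w")
    writeLines(c("P2", paste(ncol(img), nrow(img)), as.character(lev)), con)
    write(t(img), con, ncolumns = 16)
    close(con)
    paths[f] <- path
  }
  invisible(paths)
}

#' Read a single plain-text PGM (P2) image
#'
#' @param path PGM file path.
#' @return Matrix of intensities in \[0, 1\].
#' @export
read_pgm <- function(path) {
  txt <- scan(path, what = character(), comment.char = "#", quiet = TRUE)
  stopifnot(txt[1] == "P2")
  nc <- as.integer(txt[2]); nr <- as.integer(txt[3]); lev <- as.numeric(txt[4])
  vals <- as.numeric(txt[-(1:4)])
  matrix(vals, nr, nc, byrow = TRUE) / lev
}
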