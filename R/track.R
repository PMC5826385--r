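#' Preprocess grayscale frames
#'
#' Batch contrast/brightness adjustment before segmentation: an optional
#' per-frame background normalization (dividing by the frame median, which
#' suppresses illumination flicker), a monotone linear contrast stretch
#' mapping `[low, high]` to `[0, 1]` with clipping, and an optional box
#' smoothing.  With identity parameters the input is returned unchanged.
#'
#' @param x A `frame_stack`, a 3D array (frame, row, col), or a single
#'   matrix.
#' @param low,high Intensity window mapped to `[0, 1]` (defaults 0 and 1 =
#'   identity stretch).
#' @param normalize_background If `TRUE`, divide each frame by its median
#'   intensity (then rescale by the stack-wide median) before stretching.
#' @param smooth_radius Half-width (px) of a box smoothing kernel; 0
#'   disables smoothing.
#' @return Same shape as the input, intensities in \[0, 1\].
#' @export
preprocess_frames <- function(x, low = 0, high = 1,
                              normalize_background = FALSE,
                              smooth_radius = 0) {
  stopifnot(high > low)
  if (inherits(x, "frame_stack")) {
    out <- x
    out$frames <- preprocess_frames(x$frames, low, high,
                                    normalize_background, smooth_radius)
    return(out)
  }
  single <- is.matrix(x)
  a <- if (single) array(x, dim = c(1, nrow(x), ncol(x))) else x
  if (normalize_background) {
    meds <- apply(a, 1, median)
    ref <- median(meds)
    for (f in seq_len(dim(a)[1])) a[f, , ] <- a[f, , ] / meds[f] * ref
  }
  a <- (a - low) / (high - low)
  a <- pmin(pmax(a, 0), 1)
  if (smooth_radius > 0) {
    for (f in seq_len(dim(a)[1])) a[f, , ] <- box_smooth(a[f, , ], smooth_radius)
  }
  if (single) a[1, , ] else a
}

# Separable box filter with replicated edges.
box_smooth <- function(img, radius) {
  k <- 2 * radius + 1
  n <- nrow(img); m <- ncol(img)
  cs <- apply(rbind(matrix(img[1, ], radius, m, byrow = TRUE), img,
                    matrix(img[n, ], radius, m, byrow = TRUE)), 2, cumsum)
  out <- (cs[k:(n + k - 1), ] - rbind(0, cs[1:(n - 1), ])) / k
  cs2 <- t(apply(cbind(matrix(out[, 1], n, radius), out,
                       matrix(out[, m], n, radius)), 1, cumsum))
  (cs2[, k:(m + k - 1)] - cbind(0, cs2[, 1:(m - 1)])) / k
}

#' Otsu threshold of a grayscale image
#'
#' Maximizes between-class variance on a 256-bin histogram of \[0, 1\]
#' intensities.
#' @param img Matrix or array of intensities in \[0, 1\].
#' @return Threshold intensity.
#' @export
otsu_threshold <- function(img) {
  v <- as.vector(img)
  h <- tabulate(pmin(pmax(floor(v * 256) + 1L, 1L), 256L), nbins = 256)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * (seq_len(256) - 0.5) / 256)
  mu_t <- mu[256]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  (which.max(sigma_b)) / 256
}

#' Segment marker dots in one frame
#'
#' Thresholds dark connected components (8-connectivity) against a lighter
#' background, applies an area filter, and returns intensity-weighted
#' (sub-pixel) centroids.  The threshold defaults to Otsu's method on the
#' frame; components touching the border are kept.
#'
#' @param frame Grayscale matrix (intensities in \[0, 1\]).
#' @param min_area,max_area Component area bounds (px^2).
#' @param threshold Intensity threshold; pixels strictly below it are
#'   foreground.  `NULL` uses [otsu_threshold()].
#' @return Tibble with sub-pixel `x_px`, `y_px` (0-based pixel-centre
#'   coordinates) and `area` (px^2); zero rows when nothing is detected.
#' @export
segment_dots <- function(frame, min_area = 4, max_area = 400,
                         threshold = NULL) {
  stopifnot(is.matrix(frame))
  thr <- threshold %||% otsu_threshold(frame)
  mask <- frame < thr
  if (!any(mask)) {
    return(tibble(x_px = numeric(), y_px = numeric(), area = numeric()))
  }
  lab <- label_components(mask)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_area & sizes <= max_area)
  if (length(keep) == 0) {
    return(tibble(x_px = numeric(), y_px = numeric(), area = numeric()))
  }
  idx <- which(lab > 0 & lab %in% keep)
  comp <- lab[idx]
  rows <- (idx - 1) %% nrow(frame)      # 0-based row
  cols <- (idx - 1) %/% nrow(frame)     # 0-based col
  w <- pmax(thr - frame[idx], 1e-12)    # darker pixels weigh more
  sw <- tapply(w, comp, sum)
  x <- tapply(w * cols, comp, sum) / sw
  y <- tapply(w * rows, comp, sum) / sw
  a <- tapply(rep(1, length(comp)), comp, sum)
  ord <- order(as.integer(names(sw)))
  tibble(x_px = as.numeric(x[ord]), y_px = as.numeric(y[ord]),
         area = as.numeric(a[ord]))
}

# 8-connected component labelling by breadth-first flood fill.
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  todo <- which(mask)
  nbr <- c(-1L, 1L, -nr, nr, -nr - 1L, -nr + 1L, nr - 1L, nr + 1L)
  current <- 0L
  for (s in todo) {
    if (lab[s] != 0L) next
    current <- current + 1L
    lab[s] <- current
    frontier <- s
    while (length(frontier) > 0) {
      cand <- rep(frontier, each = 8L) + nbr
      rows <- (rep(frontier, each = 8L) - 1L) %% nr + 1L
      # drop candidates that wrap across matrix columns or exit bounds
      dr <- rep(c(-1L, 1L, 0L, 0L, -1L, 1L, -1L, 1L), times = length(frontier))
      ok <- cand >= 1L & cand <= nr * nc
      rr <- rows + dr
      ok <- ok & rr >= 1L & rr <= nr
      cand <- unique(cand[ok])
      cand <- cand[mask[cand] & lab[cand] == 0L]
      lab[cand] <- current
      frontier <- cand
    }
  }
  lab
}

#' Segment every frame of a stack
#'
#' @param stack A `frame_stack` or 3D array (frame, row, col).
#' @inheritParams segment_dots
#' @return Tibble with `frame` (0-based), `x_px`, `y_px`, `area`.
#' @export
segment_stack <- function(stack, min_area = 4, max_area = 400,
                          threshold = NULL) {
  a <- if (inherits(stack, "frame_stack")) stack$frames else stack
  purrr::map_dfr(seq_len(dim(a)[1]), function(f) {
    segment_dots(a[f, , ], min_area, max_area, threshold) %>%
      mutate(frame = f - 1L, .before = 1)
  })
}

#' Link centroids across frames into marker tracks
#'
#' Frame-to-frame greedy mutual-nearest linking: detections in consecutive
#' frames are paired in order of increasing distance, and only pairs
#' closer than `radius` pixels (default 10, the linking rule used for the
#' transection videos) are ever joined.  Unmatched detections start new
#' tracks; a track that misses a frame terminates (no re-identification).
#' Exact distance ties resolve to the lowest centroid index and emit a
#' message.
#'
#' @param detections Tibble from [segment_stack()] (`frame`, `x_px`,
#'   `y_px`, optionally `area`).
#' @param radius Maximum linking distance (px).
#' @return Tibble with `track_id`, `frame`, `x_px`, `y_px` (and `area` if
#'   supplied), ordered by track then frame.
#' @export
link_tracks <- function(detections, radius = 10) {
  stopifnot(all(c("frame", "x_px", "y_px") %in% names(detections)))
  if (nrow(detections) == 0) {
    return(tibble(track_id = integer(), frame = integer(),
                  x_px = numeric(), y_px = numeric()))
  }
  detections <- arrange(detections, .data$frame)
  frames <- sort(unique(detections$frame))
  by_f <- split(detections, factor(detections$frame, levels = frames))

  next_id <- 0L
  assign_new <- function(d) {
    ids <- next_id + seq_len(nrow(d))
    next_id <<- next_id + nrow(d)
    d$track_id <- ids
    d
  }
  prev <- assign_new(by_f[[1]])
  out <- list(prev)
  for (fi in seq_along(frames)[-1]) {
    cur <- by_f[[fi]]
    cur$track_id <- NA_integer_
    if (frames[fi] == frames[fi - 1] + 1L && nrow(prev) > 0 && nrow(cur) > 0) {
      D <- outer(prev$x_px, cur$x_px, "-")^2 + outer(prev$y_px, cur$y_px, "-")^2
      lim <- radius^2
      repeat {
        m <- min(D)
        if (!is.finite(m) || m > lim) break
        hits <- which(D == m)
        if (length(hits) > 1) {
          inform(sprintf("link_tracks: distance tie at frame %d resolved by lowest index.",
                         frames[fi]))
        }
        k <- hits[1]
        i <- (k - 1) %% nrow(D) + 1
        j <- (k - 1) %/% nrow(D) + 1
        cur$track_id[j] <- prev$track_id[i]
        D[i, ] <- Inf
        D[, j] <- Inf
      }
    }
    new <- is.na(cur$track_id)
    if (any(new)) {
      ids <- next_id + seq_len(sum(new))
      next_id <- next_id + sum(new)
      cur$track_id[new] <- ids
    }
    out[[fi]] <- cur
    prev <- cur
  }
  bind_rows(out) %>%
    select("track_id", "frame", dplyr::everything()) %>%
    arrange(.data$track_id, .data$frame)
}

#' Keep only tracks covering most of the recording
#'
#' Mirrors the "successfully segmented" criterion: tracks shorter than
#' `min_frac` of the distinct frames present are dropped.
#'
#' @param tracks Tibble from [link_tracks()].
#' @param min_frac Minimum fraction of frames a track must span.
#' @return Filtered tracks tibble.
#' @export
filter_tracks <- function(tracks, min_frac = 0.9) {
  n_frames <- dplyr::n_distinct(tracks$frame)
  tracks %>%
    group_by(.data$track_id) %>%
    filter(n() >= min_frac * n_frames) %>%
    ungroup()
}

#' Label tracks as brain or rigid by initial radial position
#'
#' Markers whose first-frame distance from `center` exceeds
#' `rigid_radius` are labelled `"rigid"`, the rest `"brain"` — the rigid
#' dots sit on the skull/potting annulus outside the brain section.
#'
#' @param tracks Tracks tibble (`track_id`, `frame`, `x_px`, `y_px`).
#' @param center `c(x, y)` of the section centre, in track units.
#' @param rigid_radius Radius separating brain from rigid markers.
#' @return Tracks tibble with a `label` column added.
#' @export
label_tracks <- function(tracks, center, rigid_radius) {
  lab <- tracks %>%
    group_by(.data$track_id) %>%
    slice(1) %>%
    ungroup() %>%
    mutate(label = ifelse(sqrt((.data$x_px - center[1])^2 +
                               (.data$y_px - center[2])^2) > rigid_radius,
                          "rigid", "brain")) %>%
    select("track_id", "label")
  left_join(tracks, lab, by = "track_id")
}
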