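#' Pair brain markers with their nearest rigid marker
#'
#' Each brain track is matched to the rigid track nearest in the first
#' analysis frame (many brain dots may share a rigid dot).  Pairs are
#' flagged `superior` when the brain marker's first-frame y-coordinate
#' lies in the top tercile of the brain-marker bounding box — the region
#' whose displacement governs bridging-vein elongation.  Distance ties
#' resolve to the lowest rigid label and emit a message.
#'
#' @param tracks Labelled tracks tibble (`track_id`, `frame`, `x_px`,
#'   `y_px`, `label` in `"brain"`/`"rigid"`).  Coordinates may be pixels
#'   or mm; pairing only uses first-frame geometry.
#' @param superior_frac Top fraction of the first-frame brain bounding box
#'   (in image y, i.e. smallest y values when `y_down = TRUE`) flagged
#'   superior.
#' @param y_down `TRUE` when the y axis points downward (image pixel
#'   convention); `FALSE` for ground-frame y-up coordinates.
#' @return Tibble with `brain_id`, `rigid_id`, `superior`,
#'   `first_distance` (same units as the coordinates).
#' @export
pair_markers <- function(tracks, superior_frac = 1 / 3, y_down = TRUE) {
  first <- tracks %>%
    group_by(.data$track_id) %>%
    arrange(.data$frame, .by_group = TRUE) %>%
    slice(1) %>%
    ungroup()
  brain <- filter(first, .data$label == "brain")
  rigid <- filter(first, .data$label == "rigid") %>% arrange(.data$track_id)
  if (nrow(rigid) == 0) abort("No rigid tracks: cannot pair brain markers.")
  if (nrow(brain) == 0) {
    return(tibble(brain_id = integer(), rigid_id = integer(),
                  superior = logical(), first_distance = numeric()))
  }
  D <- sqrt(outer(brain$x_px, rigid$x_px, "-")^2 +
            outer(brain$y_px, rigid$y_px, "-")^2)
  nearest <- apply(D, 1, function(r) {
    hits <- which(r == min(r))
    if (length(hits) > 1) {
      inform("pair_markers: equidistant rigid markers; lowest label chosen.")
    }
    hits[1]
  })
  ylim <- range(brain$y_px)
  cut <- if (y_down) ylim[1] + superior_frac * diff(ylim)
         else ylim[2] - superior_frac * diff(ylim)
  superior <- if (y_down) brain$y_px <= cut else brain$y_px >= cut
  tibble(brain_id = brain$track_id,
         rigid_id = rigid$track_id[nearest],
         superior = superior,
         first_distance = D[cbind(seq_len(nrow(brain)), nearest)])
}

#' Relative brain-rigid displacement series
#'
#' For every pair, computes the per-frame Euclidean distance between the
#' brain and rigid centroids, averages the `n_baseline` frames before
#' `motion_start_frame` into a baseline distance, and subtracts it to give
#' the signed relative displacement.  Coordinates are converted to mm once
#' via `mm_per_unit`.
#'
#' @param tracks Labelled tracks tibble.
#' @param pairs Tibble from [pair_markers()].
#' @param motion_start_frame Frame index (same 0/1 base as `tracks$frame`)
#'   of the first motion sample.
#' @param n_baseline Number of pre-motion frames averaged into the
#'   baseline (default 50).
#' @param mm_per_unit Scale from track units to mm (e.g. 0.41 mm/px;
#'   default 1 for tracks already in mm).
#' @return Tibble of class `displacement_series`: `brain_id`, `rigid_id`,
#'   `superior`, `frame`, `rel_disp_mm`, plus a `baseline_mm` attribute
#'   table.
#' @export
relative_displacement <- function(tracks, pairs, motion_start_frame,
                                  n_baseline = 50, mm_per_unit = 1) {
  base_frames <- motion_start_frame - seq_len(n_baseline)
  missing_base <- setdiff(base_frames, unique(tracks$frame))
  if (length(missing_base) > 0) {
    abort(sprintf(
      "Insufficient pre-motion frames: %d of the %d baseline frames are absent (need frames %d..%d).",
      length(missing_base), n_baseline, min(base_frames), max(base_frames)))
  }
  pos <- tracks %>% select("track_id", "frame", "x_px", "y_px")
  series <- pairs %>%
    mutate(pair = row_number()) %>%
    left_join(pos, by = c(brain_id = "track_id"), relationship = "many-to-many") %>%
    rename(bx = "x_px", by = "y_px") %>%
    dplyr::inner_join(pos, by = c(rigid_id = "track_id", frame = "frame")) %>%
    rename(rx = "x_px", ry = "y_px") %>%
    mutate(dist_mm = sqrt((.data$bx - .data$rx)^2 +
                          (.data$by - .data$ry)^2) * mm_per_unit)
  baseline <- series %>%
    filter(.data$frame %in% base_frames) %>%
    group_by(.data$pair) %>%
    summarise(baseline_mm = mean(.data$dist_mm), .groups = "drop")
  out <- series %>%
    left_join(baseline, by = "pair") %>%
    mutate(rel_disp_mm = .data$dist_mm - .data$baseline_mm) %>%
    select("brain_id", "rigid_id", "superior", "frame", "rel_disp_mm") %>%
    arrange(.data$brain_id, .data$frame)
  structure(out,
            baseline_mm = baseline,
            motion_start_frame = motion_start_frame,
            n_baseline = n_baseline,
            class = c("displacement_series", class(out)))
}

#' Per-pair displacement maxima and pre-motion error
#'
#' Extracts, for each brain-rigid pair, the maximum relative displacement
#' over the motion window (`max_disp_mm`) and over the pre-motion window
#' (`error_mm`, the digitization-error measure).
#'
#' @param disp A `displacement_series`.
#' @param motion_window Frames of the motion window; defaults to all
#'   frames at or after the series' motion start.
#' @param premotion_window Frames of the error window; defaults to the
#'   `n_baseline` frames before motion start.
#' @return Tibble with `brain_id`, `rigid_id`, `superior`, `max_disp_mm`,
#'   `error_mm`.
#' @export
extract_maxima <- function(disp, motion_window = NULL, premotion_window = NULL) {
  m0 <- attr(disp, "motion_start_frame")
  nb <- attr(disp, "n_baseline")
  motion_window <- motion_window %||% unique(disp$frame[disp$frame >= m0])
  premotion_window <- premotion_window %||% (m0 - seq_len(nb))
  if (length(motion_window) == 0 || length(premotion_window) == 0) {
    abort("Motion and pre-motion windows must be non-empty.")
  }
  if (length(intersect(motion_window, premotion_window)) > 0) {
    abort("Motion and pre-motion windows must be disjoint.")
  }
  disp %>%
    group_by(.data$brain_id, .data$rigid_id, .data$superior) %>%
    summarise(
      max_disp_mm = max(.data$rel_disp_mm[.data$frame %in% motion_window]),
      error_mm = max(.data$rel_disp_mm[.data$frame %in% premotion_window]),
      .groups = "drop")
}

#' Motion-start frame from a rotation pulse
#'
#' First frame whose time reaches the instant when the angular velocity
#' magnitude exceeds `frac` of its peak.
#'
#' @param pulse A `rotation_pulse`.
#' @param frame_rate Video frame rate (Hz).
#' @param lead_in Static time preceding the pulse in the recording (s).
#' @param frac Velocity threshold as a fraction of the peak.
#' @return 0-based frame index.
#' @export
motion_start_frame <- function(pulse, frame_rate, lead_in = 0, frac = 0.01) {
  t_on <- pulse$time[which(pulse$omega > frac * max(pulse$omega))[1]]
  as.integer(ceiling((lead_in + t_on) * frame_rate))
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided signed-rank test on paired samples.  Zero differences are
#' dropped; the statistic is min(V+, V-).  The exact distribution is used
#' for n <= 25 when the rank sum is integral, otherwise a normal
#' approximation with tie correction and continuity correction.  All-zero
#' differences give p = 1 with a warning.
#'
#' @param a,b Equal-length paired samples.
#' @return List with `statistic`, `p_value`, `n` (non-zero pairs),
#'   `method`.
#' @export
wilcoxon_paired <- function(a, b) {
  stopifnot(length(a) == length(b))
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    warn("All paired differences are zero; p = 1.")
    return(list(statistic = 0, p_value = 1, n = 0, method = "degenerate"))
  }
  r <- rank(abs(d))
  v_pos <- sum(r[d > 0])
  v_neg <- sum(r[d < 0])
  stat <- min(v_pos, v_neg)
  if (n <= 25 && abs(v_pos - round(v_pos)) < 1e-9) {
    # exact: two-sided p from the null signed-rank distribution
    v <- round(v_pos)
    p_low <- psignrank(v, n)
    p_high <- 1 - psignrank(v - 1, n)
    p <- min(1, 2 * min(p_low, p_high))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (v_pos - mu - sign(v_pos - mu) * 0.5) / sqrt(sig2)
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal approximation"
  }
  list(statistic = stat, p_value = p, n = n, method = method)
}

#' Summarise experiments into rotation-level and pooled rows
#'
#' Builds the per-experiment summary table of the transection analysis:
#' per-experiment mean +/- SD of pair maxima and errors (n-1 denominator)
#' and per-experiment kinematic peaks, plus pooled rows in which pair
#' values are pooled over the union of pairs (count-weighted, not a mean
#' of means) and kinematic peaks are averaged per experiment.
#'
#' @param pair_maxima Tibble of pair-level results with columns `animal`,
#'   `rotation`, `max_disp_mm`, `error_mm` (one row per brain-rigid pair).
#' @param kinematics Optional tibble with one row per experiment:
#'   `animal`, `rotation`, `peak_velocity`, `peak_accel`, `peak_decel`.
#' @return Tibble with one row per experiment plus pooled rows
#'   (`group` = `"rotation 1"`, `"rotation 2"`, `"overall"`): `n_pairs`,
#'   `mean_disp_mm`, `sd_disp_mm`, `mean_error_mm`, `sd_error_mm`, and
#'   averaged kinematic peaks when supplied.
#' @export
summarize_rotations <- function(pair_maxima, kinematics = NULL) {
  if (nrow(pair_maxima) == 0) abort("No pairs to summarise.")
  per <- pair_maxima %>%
    group_by(.data$animal, .data$rotation) %>%
    summarise(n_pairs = n(),
              mean_disp_mm = mean(.data$max_disp_mm),
              sd_disp_mm = sd(.data$max_disp_mm),
              mean_error_mm = mean(.data$error_mm),
              sd_error_mm = sd(.data$error_mm),
              .groups = "drop") %>%
    mutate(group = sprintf("animal %s rotation %s", .data$animal, .data$rotation))
  pool <- function(rows, label) {
    tibble(animal = NA, rotation = NA,
           n_pairs = nrow(rows),
           mean_disp_mm = mean(rows$max_disp_mm),
           sd_disp_mm = sd(rows$max_disp_mm),
           mean_error_mm = mean(rows$error_mm),
           sd_error_mm = sd(rows$error_mm),
           group = label)
  }
  pooled <- bind_rows(
    pool(filter(pair_maxima, .data$rotation == 1), "rotation 1"),
    pool(filter(pair_maxima, .data$rotation == 2), "rotation 2"),
    pool(pair_maxima, "overall"))
  pooled <- filter(pooled, .data$n_pairs > 0)
  out <- bind_rows(per, pooled)
  if (!is.null(kinematics)) {
    kin <- kinematics %>%
      mutate(group = sprintf("animal %s rotation %s", .data$animal, .data$rotation)) %>%
      select(-"animal", -"rotation")
    kin_pool <- bind_rows(
      kinematics %>% filter(.data$rotation == 1) %>%
        summarise(dplyr::across(c("peak_velocity", "peak_accel", "peak_decel"), mean)) %>%
        mutate(group = "rotation 1"),
      kinematics %>% filter(.data$rotation == 2) %>%
        summarise(dplyr::across(c("peak_velocity", "peak_accel", "peak_decel"), mean)) %>%
        mutate(group = "rotation 2"),
      kinematics %>%
        summarise(dplyr::across(c("peak_velocity", "peak_accel", "peak_decel"), mean)) %>%
        mutate(group = "overall"))
    out <- left_join(out, bind_rows(kin, kin_pool), by = "group")
  }
  select(out, "group", dplyr::everything())
}

#' Count-weighted pooling of printed summary rows
#'
#' Recomputes pooled summary values from per-experiment means and pair
#' counts: pooled mean = sum(n_i * m_i) / sum(n_i).  Used to reproduce the
#' pooled rows of published summary tables, where only rounded
#' per-experiment rows are available (pooled SDs are not recoverable from
#' rounded summaries and are not attempted).
#'
#' @param means Per-experiment means.
#' @param counts Per-experiment pair counts (same length).
#' @return The pooled mean.
#' @export
pooled_mean <- function(means, counts) {
  stopifnot(length(means) == length(counts), length(means) > 0)
  sum(means * counts) / sum(counts)
}

#' @export
autoplot.displacement_series <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$frame, .data$rel_disp_mm,
                                       group = .data$brain_id)) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::geom_vline(xintercept = attr(object, "motion_start_frame"),
                        linetype = 2, colour = "grey40") +
    ggplot2::labs(x = "frame", y = "relative displacement (mm)")
}
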