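#' Published sagittal transection experiment summaries
#'
#' Per-experiment summary rows from the published series of six sagittal
#' transection rotations of neonatal piglet heads (three animals, two
#' consecutive rotations each): peak angular kinematics, the mean +/- SD
#' of the per-pair maximum brain-skull displacements, the mean +/- SD of
#' the per-pair pre-motion error measures, and the number of brain-rigid
#' dot pairs contributing to each experiment (13, 14 and 14 for the three
#' animals).  These printed rows are the experimental inputs used to
#' verify the pooled-summary arithmetic.
#'
#' @return Tibble with columns `animal`, `rotation`, `peak_velocity`
#'   (rad/s), `peak_accel`, `peak_decel` (krad/s^2), `mean_disp_mm`,
#'   `sd_disp_mm`, `mean_error_mm`, `sd_error_mm`, `n_pairs`.
#' @export
sagittal_experiment_table <- function() {
  tibble::tribble(
    ~animal, ~rotation, ~peak_velocity, ~peak_accel, ~peak_decel,
      ~mean_disp_mm, ~sd_disp_mm, ~mean_error_mm, ~sd_error_mm, ~n_pairs,
    1L, 1L, 52, 9.6, 6.8,  1.00, 0.41, 0.32, 0.16, 13L,
    1L, 2L, 51, 10.3, 7.4, 1.07, 0.40, 0.28, 0.17, 13L,
    2L, 1L, 50, 8.4, 8.6,  0.63, 0.36, 0.28, 0.19, 14L,
    2L, 2L, 51, 9.5, 8.1,  0.68, 0.29, 0.31, 0.37, 14L,
    3L, 1L, 52, 6.2, 9.0,  0.58, 0.27, 0.33, 0.29, 14L,
    3L, 2L, 54, 7.7, 11.2, 0.66, 0.26, 0.31, 0.21, 14L)
}

#' Published axial transection experiment summaries
#'
#' Summary rows of the earlier axial-plane transection experiments used
#' for the directional comparison: peak kinematics and mean +/- SD of the
#' per-pair maximum brain-skull displacements around the axially
#' transected cortex periphery.
#'
#' @return Tibble with `animal`, `peak_velocity` (rad/s), `peak_accel`,
#'   `peak_decel` (krad/s^2), `mean_disp_mm`, `sd_disp_mm`.
#' @export
axial_experiment_table <- function() {
  tibble::tribble(
    ~animal, ~peak_velocity, ~peak_accel, ~peak_decel, ~mean_disp_mm, ~sd_disp_mm,
    "Axial-1", 52, 6.2, 6.9, 1.71, 0.40,
    "Axial-2", 53, 6.7, 6.3, 1.50, 0.56,
    "Axial-3", 54, 5.5, 6.6, 1.31, 0.56)
}

#' Published connector-stiffness sweep (regression slopes and CIs)
#'
#' The printed stiffness sweep of the sagittally transected finite element
#' model: for each general connector stiffness, the
#' regression-through-origin slope between simulated and measured maximum
#' brain-skull displacements over all dot pairs (`a_all`) and over
#' superior-only pairs (`a_sup`), with 95% confidence intervals.  One
#' stiffness (46.133 N/m) appears twice: once with post-cyclic and once
#' with high-rate bridging-vein behaviour.
#'
#' @return Tibble of class `calibration_sweep` with `stiffness` (N/m),
#'   `a_all`, `ci_all_low`, `ci_all_high`, `a_sup`, `ci_sup_low`,
#'   `ci_sup_high`, `vein_variant`.
#' @export
published_connector_sweep <- function() {
  out <- tibble::tribble(
    ~stiffness, ~a_all, ~ci_all_low, ~ci_all_high, ~a_sup, ~ci_sup_low, ~ci_sup_high, ~vein_variant,
    4000,   0.769, 0.684, 0.854, 0.665, 0.582, 0.749, "post_cyclic",
    3750,   0.769, 0.684, 0.855, 0.666, 0.582, 0.749, "post_cyclic",
    3460,   0.770, 0.685, 0.855, 0.666, 0.582, 0.750, "post_cyclic",
    3250,   0.770, 0.685, 0.855, 0.666, 0.583, 0.750, "post_cyclic",
    3000,   0.771, 0.686, 0.856, 0.667, 0.583, 0.750, "post_cyclic",
    2595,   0.772, 0.687, 0.857, 0.668, 0.584, 0.751, "post_cyclic",
    2000,   0.774, 0.700, 0.859, 0.669, 0.586, 0.753, "post_cyclic",
    1730,   0.775, 0.690, 0.861, 0.670, 0.587, 0.754, "post_cyclic",
    692,    0.789, 0.703, 0.875, 0.678, 0.596, 0.761, "post_cyclic",
    346,    0.812, 0.724, 0.899, 0.687, 0.608, 0.766, "post_cyclic",
    138.4,  0.930, 0.826, 1.034, 0.784, 0.695, 0.874, "post_cyclic",
    69.2,   1.002, 0.879, 1.125, 0.883, 0.753, 1.014, "post_cyclic",
    46.133, 1.082, 0.939, 1.226, 0.984, 0.8230, 1.144, "post_cyclic",
    46.133, 1.081, 0.938, 1.225, 0.981, 0.821, 1.142, "high_rate",
    34.6,   1.149, 0.990, 1.308, 1.056, 0.874, 1.239, "post_cyclic")
  class(out) <- c("calibration_sweep", class(out))
  out
}

#' Recompute pooled rows of published summary tables
#'
#' Reproduces the pooled summary rows from per-experiment printed rows:
#' displacement and error means pooled with pair-count weights
#' ([pooled_mean()]), kinematic peaks averaged per experiment.
#'
#' @param rows Per-experiment tibble in the shape of
#'   [sagittal_experiment_table()] (an `n_pairs` column is required for
#'   displacement pooling; kinematic columns are averaged unweighted).
#' @param group Optional subset: `"rotation1"`, `"rotation2"`, or
#'   `"overall"` (default).
#' @return One-row tibble with `n_pairs`, `mean_disp_mm`,
#'   `mean_error_mm` (when present) and averaged kinematic peaks.
#' @export
recompute_summary_rows <- function(rows, group = c("overall", "rotation1", "rotation2")) {
  group <- match.arg(group)
  if (group != "overall") {
    stopifnot("rotation" %in% names(rows))
    rows <- filter(rows, .data$rotation == as.integer(sub("rotation", "", group)))
  }
  if (nrow(rows) == 0) abort("Empty group.")
  out <- tibble(
    group = group,
    n_experiments = nrow(rows),
    peak_velocity = mean(rows$peak_velocity),
    peak_accel = mean(rows$peak_accel),
    peak_decel = mean(rows$peak_decel))
  if ("n_pairs" %in% names(rows)) {
    out$n_pairs <- sum(rows$n_pairs)
    out$mean_disp_mm <- pooled_mean(rows$mean_disp_mm, rows$n_pairs)
    if ("mean_error_mm" %in% names(rows)) {
      out$mean_error_mm <- pooled_mean(rows$mean_error_mm, rows$n_pairs)
    }
  } else {
    out$mean_disp_mm <- mean(rows$mean_disp_mm)
  }
  out
}
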