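# tracks for two markers with a prescribed distance series
tracks_with_distance <- function(dist_series, n_baseline = 50) {
  n <- length(dist_series)
  dplyr::bind_rows(
    tibble::tibble(track_id = 1L, frame = 0:(n - 1), x_px = 0,
                   y_px = dist_series, label = "brain"),
    tibble::tibble(track_id = 2L, frame = 0:(n - 1), x_px = 0, y_px = 0,
                   label = "rigid"))
}

test_that("baseline subtraction reproduces the hand-computed oracle", {
  # 50 frames at distance 10, then 10.5, 11, 10.2
  d <- c(rep(10, 50), 10.5, 11, 10.2)
  tracks <- tracks_with_distance(d)
  pairs <- pair_markers(tracks)
  disp <- relative_displacement(tracks, pairs, motion_start_frame = 50)
  motion <- disp$rel_disp_mm[disp$frame >= 50]
  expect_equal(motion, c(0.5, 1.0, 0.2))
  mx <- extract_maxima(disp)
  expect_equal(mx$max_disp_mm, 1.0)
  # baseline window has mean rel_disp exactly 0
  expect_equal(mean(disp$rel_disp_mm[disp$frame < 50]), 0)
  # constant distance -> identically zero, and errors when pre-motion short
  tracks0 <- tracks_with_distance(rep(7, 60))
  disp0 <- relative_displacement(tracks0, pair_markers(tracks0), 50)
  expect_true(all(disp0$rel_disp_mm == 0))
  expect_error(relative_displacement(tracks0, pair_markers(tracks0), 20),
               "Insufficient pre-motion frames")
})

test_that("scale equivariance and rotation invariance of displacement", {
  set.seed(11)
  n <- 80
  tracks <- dplyr::bind_rows(purrr::map(1:4, function(k) {
    tibble::tibble(track_id = k, frame = 0:(n - 1),
                   x_px = 20 * k + cumsum(rnorm(n, sd = 0.1)),
                   y_px = 10 + cumsum(rnorm(n, sd = 0.1)),
                   label = ifelse(k <= 2, "brain", "rigid"))
  }))
  pairs <- pair_markers(tracks)
  d1 <- relative_displacement(tracks, pairs, 50)
  # multiplying coordinates by c multiplies every displacement by c
  sc <- tracks %>% dplyr::mutate(x_px = 3 * x_px, y_px = 3 * y_px)
  d3 <- relative_displacement(sc, pair_markers(sc), 50)
  expect_equal(d3$rel_disp_mm, 3 * d1$rel_disp_mm, tolerance = 1e-12)
  # a global rigid rotation leaves displacements unchanged to 1e-9
  a <- 0.7
  rot <- tracks %>% dplyr::mutate(
    x2 = cos(a) * x_px - sin(a) * y_px,
    y2 = sin(a) * x_px + cos(a) * y_px,
    x_px = x2, y_px = y2)
  dr <- relative_displacement(rot, pair_markers(rot), 50)
  expect_lt(max(abs(dr$rel_disp_mm - d1$rel_disp_mm)), 1e-9)
})

test_that("pairing matches each brain marker to the nearest rigid marker", {
  mk <- function(id, x, y, label) {
    tibble::tibble(track_id = id, frame = 0L, x_px = x, y_px = y, label = label)
  }
  tracks <- dplyr::bind_rows(
    mk(1, 0, 0, "brain"), mk(2, 10, 0, "brain"),
    mk(3, 2, 0, "rigid"), mk(4, 9, 0, "rigid"))
  pr <- pair_markers(tracks)
  expect_equal(pr$rigid_id, c(3L, 4L))
  # equidistant -> lowest rigid label, with a message
  tracks2 <- dplyr::bind_rows(mk(1, 5, 0, "brain"),
                              mk(3, 2, 0, "rigid"), mk(4, 8, 0, "rigid"))
  expect_message(pr2 <- pair_markers(tracks2), "equidistant")
  expect_equal(pr2$rigid_id, 3L)
  # many-to-one pairing and the 13-pair count
  ex <- fix_tracked_experiment()
  pr3 <- pair_markers(ex$tracks)
  expect_equal(nrow(pr3), sum(ex$layout$label == "brain"))
  expect_error(pair_markers(dplyr::filter(tracks, label == "brain")),
               "No rigid tracks")
})

test_that("superior flags select the top tercile of brain markers", {
  mk <- tibble::tibble(track_id = 1:4, frame = 0L, x_px = 0,
                       y_px = c(0, 40, 80, 120),
                       label = c(rep("brain", 3), "rigid"))
  pr <- pair_markers(mk, y_down = FALSE)
  expect_equal(pr$superior, c(FALSE, FALSE, TRUE))
  pr_img <- pair_markers(mk, y_down = TRUE)   # image y points down
  expect_equal(pr_img$superior, c(TRUE, FALSE, FALSE))
})

test_that("full measurement pipeline recovers the configured lag amplitude", {
  ex <- fix_tracked_experiment(peak_rel_disp = 1.0, noise_sd = 0)
  pairs <- pair_markers(ex$tracks)
  m0 <- motion_start_frame(ex$pulse, ex$stack$frame_rate,
                           lead_in = attr(ex$traj, "motion_start_time"))
  disp <- relative_displacement(ex$tracks, pairs, m0,
                                mm_per_unit = 1 / ex$stack$px_per_mm)
  mx <- extract_maxima(disp)
  expect_equal(max(mx$max_disp_mm), 1.0, tolerance = 0.05)
})

test_that("with lag and noise disabled the measured displacement is below one pixel", {
  ex <- fix_tracked_experiment(peak_rel_disp = 0, noise_sd = 0)
  pairs <- pair_markers(ex$tracks)
  m0 <- motion_start_frame(ex$pulse, ex$stack$frame_rate,
                           lead_in = attr(ex$traj, "motion_start_time"))
  disp <- relative_displacement(ex$tracks, pairs, m0,
                                mm_per_unit = 1 / ex$stack$px_per_mm)
  mx <- extract_maxima(disp)
  expect_lt(max(abs(mx$max_disp_mm)), 0.41)   # one pixel in mm
})

test_that("jitter at the physical noise scale reproduces the ~0.3 mm error level", {
  # direct (unrasterized) trajectories of 24 brain dots with 0.13 mm
  # coordinate jitter, analysed at the sensor rate
  p <- fix_pulse()
  lay <- generate_layout(24, 8, "sagittal", seed = 9)
  traj <- synthesize_trajectories(lay, p, lag_model(1.0), noise_sd = 0.13,
                                  seed = 10, lead_in = 0.01, hold = 0.01)
  ids <- unique(traj$marker_id)
  tracks <- traj %>%
    dplyr::mutate(track_id = match(marker_id, ids),
                  frame = match(time, sort(unique(time))) - 1L,
                  x_px = x_mm, y_px = -y_mm) %>%
    dplyr::select(track_id, frame, x_px, y_px, label)
  pairs <- pair_markers(tracks)
  m0 <- motion_start_frame(p, 1 / (p$time[2] - p$time[1]), lead_in = 0.01)
  disp <- relative_displacement(tracks, pairs, m0, n_baseline = 50)
  mx <- extract_maxima(disp)
  # pre-motion error measure on the 0.31 mm scale
  expect_gt(mean(mx$error_mm), 0.15)
  expect_lt(mean(mx$error_mm), 0.6)
  # motion maxima clearly exceed their error measures
  wt <- wilcoxon_paired(mx$max_disp_mm, mx$error_mm)
  expect_lt(wt$p_value, 1e-5)
})

test_that("wilcoxon signed-rank matches exact enumeration and handles edge cases", {
  x <- rnorm(20)
  # paired +1 shift on 20 pairs: statistic 0, exact minimal p = 2/2^20
  wt <- wilcoxon_paired(x + 1, x)
  expect_equal(wt$statistic, 0)
  expect_equal(wt$p_value, 2 / 2^20)
  # identical samples -> p = 1 with warning
  expect_warning(w0 <- wilcoxon_paired(x, x), "zero")
  expect_equal(w0$p_value, 1)
  # agreement with the exact null distribution on a random no-tie sample
  set.seed(3)
  a <- rnorm(12); b <- rnorm(12)
  wt2 <- wilcoxon_paired(a, b)
  ref <- suppressWarnings(stats::wilcox.test(a, b, paired = TRUE,
                                             exact = TRUE))
  expect_equal(wt2$p_value, ref$p.value, tolerance = 1e-12)
})

test_that("pooled summaries use count-weighted means, not mean of means", {
  set.seed(5)
  pairs <- dplyr::bind_rows(
    tibble::tibble(animal = 1, rotation = 1, max_disp_mm = rnorm(13, 1.0, 0.1),
                   error_mm = abs(rnorm(13, 0.3, 0.05))),
    tibble::tibble(animal = 2, rotation = 1, max_disp_mm = rnorm(14, 0.6, 0.1),
                   error_mm = abs(rnorm(14, 0.3, 0.05))),
    tibble::tibble(animal = 2, rotation = 2, max_disp_mm = rnorm(14, 0.7, 0.1),
                   error_mm = abs(rnorm(14, 0.3, 0.05))))
  s <- summarize_rotations(pairs)
  r1 <- s[s$group == "rotation 1", ]
  per <- pairs %>% dplyr::filter(rotation == 1)
  expect_equal(r1$n_pairs, 27)
  expect_equal(r1$mean_disp_mm, mean(per$max_disp_mm))
  # pooled-mean identity: sum(n_i m_i) / sum(n_i) equals the union mean
  m_i <- tapply(per$max_disp_mm, per$animal, mean)
  n_i <- tapply(per$max_disp_mm, per$animal, length)
  expect_equal(r1$mean_disp_mm, pooled_mean(m_i, n_i))
  # SDs use the n-1 denominator
  expect_equal(r1$sd_disp_mm, sd(per$max_disp_mm))
  # single experiment: pooled row equals its own row
  one <- summarize_rotations(dplyr::filter(pairs, animal == 1))
  expect_equal(one$mean_disp_mm[one$group == "rotation 1"],
               one$mean_disp_mm[one$group == "overall"])
})
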