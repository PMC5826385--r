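test_that("preprocessing is monotone and identity at identity parameters", {
  img <- matrix(runif(400), 20, 20)
  expect_equal(preprocess_frames(img), img)
  const <- matrix(0.5, 20, 20)
  expect_equal(preprocess_frames(const, low = 0.2, high = 0.8),
               matrix(0.5, 20, 20))
  # monotone mapping preserves intensity ordering
  out <- preprocess_frames(img, low = 0.25, high = 0.75)
  expect_true(all(diff(out[order(img)]) >= 0))
})

test_that("background normalization reduces flicker variance", {
  p <- generate_pulse(5, 2000, 2000, total_angle = 0.02, dt = 1e-4)
  lay <- generate_layout(4, 0, "circle", seed = 1, base_radius = 8)
  tr <- synthesize_trajectories(lay, p, lag_model(0), rotation_center = c(0, 0),
                                lead_in = 0.01, hold = 0.01)
  stack <- rasterize_frames(tr, shape = c(80, 80), flicker_amp = 0.1)
  bg_var <- function(a) var(a[, 2, 2])   # background pixel across frames
  norm <- preprocess_frames(stack, normalize_background = TRUE)
  expect_lt(bg_var(norm$frames), 0.05 * bg_var(stack$frames))
})

test_that("segmentation finds dots with sub-pixel centroids", {
  ex <- fix_tracked_experiment()
  det <- segment_dots(ex$stack$frames[1, , ])
  truth <- ex$stack$truth_px[ex$stack$truth_px$frame == 0, ]
  expect_equal(nrow(det), nrow(truth))
  # every truth centroid recovered within 0.25 px
  for (i in seq_len(nrow(truth))) {
    dd <- sqrt((det$x_px - truth$x_px[i])^2 + (det$y_px - truth$y_px[i])^2)
    expect_lt(min(dd), 0.25)
  }
  # blank frame: zero detections
  blank <- matrix(0.8, 50, 50)
  expect_equal(nrow(segment_dots(blank)), 0)
  # two disks separated by more than a diameter: exactly two detections
  img <- matrix(0.8, 40, 40)
  for (c0 in list(c(10, 10), c(30, 28))) {
    d <- sqrt(outer((0:39 - c0[2])^2, (0:39 - c0[1])^2, "+"))
    img <- pmin(img, ifelse(d < 3, 0.1, 0.8))
  }
  expect_equal(nrow(segment_dots(img)), 2)
})

test_that("area filtering is applied before centroid computation", {
  img <- matrix(0.8, 40, 40)
  d <- sqrt(outer((0:39 - 20)^2, (0:39 - 20)^2, "+"))
  img[d < 3] <- 0.1       # area ~28 px
  img[5, 5] <- 0.1        # single-pixel speck
  det <- segment_dots(img, min_area = 4, max_area = 400)
  expect_equal(nrow(det), 1)
  expect_equal(det$x_px, 20, tolerance = 0.05)
})

test_that("static and jumping dots link according to the 10-pixel rule", {
  # static dot over 100 frames -> one track of length 100
  det <- tibble::tibble(frame = 0:99, x_px = 50, y_px = 50)
  tr <- link_tracks(det, radius = 10)
  expect_equal(length(unique(tr$track_id)), 1)
  expect_equal(nrow(tr), 100)
  # a dot jumping 11 px with radius 10 -> two tracks
  det2 <- tibble::tibble(frame = 0:9, x_px = c(rep(20, 5), rep(31, 5)), y_px = 10)
  expect_equal(length(unique(link_tracks(det2, radius = 10)$track_id)), 2)
  # exactly 10 px is still linked (within the radius)
  det3 <- tibble::tibble(frame = 0:1, x_px = c(20, 30), y_px = 10)
  expect_equal(length(unique(link_tracks(det3, radius = 10)$track_id)), 1)
})

# exhaustive minimum-total-distance assignment (oracle)
oracle_assign <- function(prev, cur, radius) {
  n <- nrow(prev); m <- nrow(cur)
  D <- sqrt(outer(prev$x_px, cur$x_px, "-")^2 + outer(prev$y_px, cur$y_px, "-")^2)
  best <- NULL; best_cost <- Inf; best_n <- -1
  recurse <- function(i, used, links, cost) {
    if (i > n) {
      nl <- if (is.null(links)) 0L else nrow(links)
      if (nl > best_n || (nl == best_n && cost < best_cost)) {
        best <<- links; best_cost <<- cost; best_n <<- nl
      }
      return(invisible())
    }
    recurse(i + 1, used, links, cost)  # leave i unmatched
    for (j in setdiff(seq_len(m), used)) {
      if (D[i, j] <= radius) {
        recurse(i + 1, c(used, j), rbind(links, data.frame(i = i, j = j)),
                cost + D[i, j])
      }
    }
  }
  recurse(1, integer(0), NULL, 0)
  best
}

test_that("greedy mutual-nearest linking matches the exhaustive assignment oracle", {
  set.seed(42)
  radius <- 10
  for (rep in 1:20) {
    n <- sample(3:6, 1)
    # dots spaced > 2*radius apart, moving less than the radius per frame
    base <- cbind(runif(n, 0, 300), runif(n, 0, 300))
    while (min(dist(base)) <= 2 * radius) {
      base <- cbind(runif(n, 0, 300), runif(n, 0, 300))
    }
    step <- base + matrix(runif(2 * n, -6, 6), n, 2)
    prev <- tibble::tibble(frame = 0L, x_px = base[, 1], y_px = base[, 2])
    cur <- tibble::tibble(frame = 1L, x_px = step[, 1], y_px = step[, 2])
    tracks <- link_tracks(dplyr::bind_rows(prev, cur), radius = radius)
    got <- tracks %>% dplyr::group_by(track_id) %>%
      dplyr::filter(dplyr::n() == 2) %>% dplyr::ungroup()
    oracle <- oracle_assign(prev, cur, radius)
    expect_equal(nrow(got) / 2, nrow(oracle))
    # same pairings: each linked track joins prev row i to cur row oracle$j[i]
    for (tid in unique(got$track_id)) {
      seg <- got[got$track_id == tid, ]
      i <- which(prev$x_px == seg$x_px[1])
      j <- which(cur$x_px == seg$x_px[2])
      expect_true(any(oracle$i == i & oracle$j == j))
    }
  }
})

test_that("no link ever exceeds the radius and memberships are conserved", {
  set.seed(7)
  det <- purrr::map_dfr(0:30, function(f) {
    tibble::tibble(frame = f,
                   x_px = 30 + 1:5 * 40 + rnorm(5, sd = 2.5),
                   y_px = 50 + rnorm(5, sd = 2.5))
  })
  tracks <- link_tracks(det, radius = 10)
  jumps <- tracks %>% dplyr::group_by(track_id) %>%
    dplyr::mutate(d = sqrt((x_px - dplyr::lag(x_px))^2 +
                           (y_px - dplyr::lag(y_px))^2)) %>%
    dplyr::filter(!is.na(d))
  expect_true(all(jumps$d <= 10))
  by_frame <- tracks %>% dplyr::count(frame)
  det_n <- det %>% dplyr::count(frame)
  expect_true(all(by_frame$n <= det_n$n))
})

test_that("the full tracking pipeline recovers noise-free ground truth", {
  ex <- fix_tracked_experiment(peak_rel_disp = 0, noise_sd = 0)
  truth <- ex$stack$truth_px
  n_frames <- length(unique(truth$frame))
  long <- ex$tracks %>% dplyr::group_by(track_id) %>%
    dplyr::filter(dplyr::n() == n_frames) %>% dplyr::ungroup()
  expect_equal(length(unique(long$track_id)), length(unique(truth$marker_id)))
  # match tracks to truth markers at frame 0, then check every frame
  t0 <- truth[truth$frame == 0, ]
  l0 <- long[long$frame == 0, ]
  for (i in seq_len(nrow(l0))) {
    k <- which.min((t0$x_px - l0$x_px[i])^2 + (t0$y_px - l0$y_px[i])^2)
    tt <- truth[truth$marker_id == t0$marker_id[k], ]
    ll <- long[long$track_id == l0$track_id[i], ]
    err <- sqrt((tt$x_px - ll$x_px)^2 + (tt$y_px - ll$y_px)^2)
    expect_lt(max(err), 0.5)
  }
})
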