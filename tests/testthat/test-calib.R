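test_that("regression through origin matches closed forms and the brute-force oracle", {
  fit <- regress_through_origin(c(1, 2, 3), c(1.1, 1.9, 3.2))
  expect_equal(fit$slope, 14.5 / 14)
  # identity data: slope exactly 1 with a zero-width CI
  fit1 <- regress_through_origin(c(0.5, 1, 2), c(0.5, 1, 2))
  expect_equal(fit1$slope, 1)
  expect_equal(fit1$ci_low, 1)
  expect_equal(fit1$ci_high, 1)
  # linearity: scaling d_fem by c scales slope and CI endpoints by c
  f2 <- regress_through_origin(c(1, 2, 3), 2.5 * c(1.1, 1.9, 3.2))
  expect_equal(f2$slope, 2.5 * fit$slope)
  expect_equal(f2$ci_low, 2.5 * fit$ci_low)
  # brute-force oracle: grid minimization of the residual sum of squares
  set.seed(21)
  for (r in 1:10) {
    x <- runif(8, 0.2, 2); y <- 1.3 * x + rnorm(8, sd = 0.2)
    fit <- regress_through_origin(x, y)
    a_grid <- seq(0, 4, by = 1e-5)
    rss <- vapply(a_grid, function(a) sum((y - a * x)^2), numeric(1))
    expect_equal(fit$slope, a_grid[which.min(rss)], tolerance = 1e-4)
    expect_equal(fit$slope, sum(x * y) / sum(x^2), tolerance = 1e-10)
  }
  expect_error(regress_through_origin(c(0, 0, 0), c(1, 2, 3)), "zero")
})

test_that("tidy and glance expose the fit in broom style", {
  fit <- regress_through_origin(c(1, 2, 3), c(1.1, 1.9, 3.2))
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$estimate, fit$slope)
  expect_equal(glance(fit)$nobs, 3)
})

test_that("the no-intercept CI covers the true slope at the nominal rate", {
  set.seed(99)
  n <- 10; a_true <- 1.4; sigma <- 0.3; reps <- 10000
  x <- runif(n, 0.5, 2)
  Y <- a_true * matrix(x, n, reps) + matrix(rnorm(n * reps, sd = sigma), n)
  sxx <- sum(x^2)
  slopes <- colSums(x * Y) / sxx
  rss <- colSums((Y - outer(x, slopes))^2)
  se <- sqrt(rss / ((n - 1) * sxx))
  tq <- qt(0.975, n - 1)
  covered <- abs(slopes - a_true) <= tq * se
  expect_equal(mean(covered), 0.95, tolerance = 0.02)
  # spot-check the vectorized replication against regress_through_origin
  f <- regress_through_origin(x, Y[, 1])
  expect_equal(f$slope, slopes[1])
  expect_equal(f$ci_high - f$slope, tq * se[1])
})

test_that("selection on the published sweep returns 46.133 N/m", {
  sweep <- published_connector_sweep()
  sel <- select_optimal(sweep)
  expect_equal(as.numeric(sel), 46.133)
  # candidates are exactly the rows whose both CIs contain 1
  cand <- attr(sel, "candidates")
  expect_setequal(unique(cand$stiffness), c(69.2, 46.133, 34.6))
  # the sum-of-deviations metric selects the same stiffness
  expect_equal(as.numeric(select_optimal(sweep, metric = "sum")), 46.133)
  # single candidate is selected trivially
  one <- sweep[sweep$stiffness == 69.2, ]
  expect_equal(as.numeric(select_optimal(one)), 69.2)
  # no candidate -> error recommending grid extension
  none <- sweep[sweep$stiffness > 1000, ]
  expect_error(select_optimal(none), "extend the sweep grid")
})

test_that("simulated displacements decrease with stiffness and slopes follow", {
  d_fem <- fix_sweep_dfem()
  pooled <- d_fem %>% dplyr::group_by(stiffness) %>%
    dplyr::summarise(m = mean(d_fem_mm)) %>% dplyr::arrange(stiffness)
  expect_true(all(diff(pooled$m) < 0))
  # slopes against a fixed synthetic d_exp are non-increasing in k
  ex <- fix_experiments()
  truth <- d_fem %>% dplyr::filter(stiffness == 346)
  ex <- purrr::map(ex, function(e) {
    mine <- truth[truth$experiment == e$id, ]
    e$d_exp <- tibble::tibble(pair = mine$pair, superior = mine$superior,
                              max_disp_mm = mine$d_fem_mm)
    e
  })
  sw <- sweep_stiffness(fix_recovery_grid(), ex, fix_mesh(), fix_material(),
                        d_fem = d_fem)
  expect_true(all(diff(sw$a_all) < 0))
  expect_true(all(diff(sw$a_sup) < 0))
})

test_that("noiseless stiffness recovery is exact and noisy recovery degrades gracefully", {
  d_fem <- fix_sweep_dfem()
  grid <- fix_recovery_grid()
  args <- list(grid = grid, experiments = fix_experiments(),
               mesh = fix_mesh(), material = fix_material(), d_fem = d_fem)
  # noiseless: exact recovery at every grid point
  for (k in grid) {
    got <- do.call(recover_stiffness,
                   c(list(true_k = k, noise_sd = 0, seed = 1), args))
    expect_equal(got, k)
  }
  # 0.1 mm noise: selected k within one grid step in >= 80% of 20 replicates
  true_k <- 346
  mc <- do.call(recover_stiffness_mc,
                c(list(true_k = true_k, noise_sd = 0.1, seed = 100), args))
  step_of <- function(k) match(k, grid)
  hits <- abs(vapply(mc$selected_k, step_of, numeric(1)) - step_of(true_k)) <= 1
  expect_gte(mean(hits), 0.8)
  # selection never leaves the grid
  expect_true(all(mc$selected_k %in% grid))
  # heavier noise cannot beat light noise on average (graceful degradation)
  mc_heavy <- do.call(recover_stiffness_mc,
                      c(list(true_k = true_k, noise_sd = 1.5, seed = 100),
                        args))
  err <- function(m) mean(abs(vapply(m$selected_k, step_of, numeric(1)) -
                              step_of(true_k)))
  expect_lte(err(mc), err(mc_heavy) + 1e-9)
})

test_that("vein behaviour has little influence on the calibrated slopes", {
  d_fem <- fix_sweep_dfem()
  ex <- fix_experiments()[1:2]
  truth <- d_fem %>% dplyr::filter(stiffness == 346, experiment <= 2)
  ex <- purrr::map(ex, function(e) {
    mine <- truth[truth$experiment == e$id, ]
    e$d_exp <- tibble::tibble(pair = mine$pair, superior = mine$superior,
                              max_disp_mm = mine$d_fem_mm)
    e
  })
  sens <- vein_sensitivity(346, ex, fix_mesh(), fix_material(), sim_config(),
                           ultimate_stretch = 2.0)
  expect_equal(nrow(sens), 2)
  expect_setequal(sens$vein_variant, c("post_cyclic", "high_rate"))
  delta <- attr(sens, "delta")
  expect_lt(delta[["d_a_all"]], 0.15)
  expect_true(all(sens$max_stretch >= 1))
  expect_false(any(sens$exceeds_ultimate))
})
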