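test_that("traveled distance accumulates Euclidean segment lengths", {
  expect_equal(traveled_distance(rbind(c(0, 0, 0))), 0)
  expect_equal(traveled_distance(rbind(c(0, 0, 0), c(3, 4, 0), c(3, 4, 12))),
               17) # 3-4-5 triangle plus 12
  expect_error(traveled_distance(matrix(0, 0, 3)), "empty")
  # direction symmetry
  set.seed(41)
  P <- matrix(stats::rnorm(30), 10, 3)
  expect_equal(traveled_distance(P), traveled_distance(P[10:1, ]))
})

test_that("traveled distance is monotone under appends and bounded below by the chord", {
  set.seed(42)
  P <- matrix(stats::rnorm(24), 8, 3)
  for (i in 2:8) {
    expect_gte(traveled_distance(P[1:i, , drop = FALSE]),
               traveled_distance(P[1:(i - 1), , drop = FALSE]))
    expect_gte(traveled_distance(P[1:i, , drop = FALSE]),
               sqrt(sum((P[i, ] - P[1, ])^2)))
  }
})

test_that("relative distance error follows its definition", {
  expect_equal(relative_distance_error(487.5, 487.5), 0)
  expect_equal(relative_distance_error(512.0, 487.5), 100 * 24.5 / 487.5)
  expect_equal(relative_distance_error(512.0, 487.5), 5.026, tolerance = 1e-4)
  expect_equal(relative_distance_error(0, 487.5), 100)
  expect_error(relative_distance_error(100, 0), "positive")
})

test_that("orientation error respects the axis and signed conventions", {
  v <- c(0, 0, 1)
  expect_equal(orientation_error(v, v), 0)
  expect_equal(orientation_error(v, c(1, 0, 0)), 90)
  expect_equal(orientation_error(v, -v, mode = "axis"), 0)
  expect_equal(orientation_error(v, -v, mode = "signed"), 180)
  expect_equal(orientation_error(c(1, 1, 0), c(1, 0, 0)), 45)
  expect_error(orientation_error(c(0, 0, 0), v), "zero")
  # row-wise matrix form
  E <- rbind(c(1, 0, 0), c(0, 1, 0))
  R <- rbind(c(1, 0, 0), c(0, 0, 1))
  expect_equal(orientation_error(E, R), c(0, 90))
})

test_that("noiseless tracking recovers the trajectory almost exactly", {
  arr <- sensor_array()
  mag <- magnet()
  truth <- generate_trajectory(n_samples = 30)
  ds <- simulate_dataset(truth, arr, mag, noiseless_model())
  tr <- track_dataset(ds, arr, mag, truth = truth)
  expect_equal(tr$n_converged, 30L)
  expect_lt(tr$rel_dist_err_pct, 0.1)
  expect_lt(tr$mean_orient_err_deg, 0.1)
  expect_lt(max(abs(tr$estimates$x - truth$x)), 1e-6)
})

test_that("tracking results are identical with and without a homogeneous background", {
  arr <- sensor_array()
  mag <- magnet()
  truth <- generate_trajectory(n_samples = 8)
  lsb2 <- 2^-25
  base <- simulate_dataset(truth, arr, mag,
                           sensor_model(noise_sigma = 0, lsb = lsb2))
  g <- round(geomagnetic_field() / lsb2) * lsb2
  shifted <- base
  cols <- grep("^s[0-9]{2}[xyz]$", names(base), value = TRUE)
  for (i in seq_along(cols)) {
    shifted[[cols[i]]] <- base[[cols[i]]] + g[((i - 1L) %% 3L) + 1L]
  }
  t1 <- track_dataset(base, arr, mag, truth = truth)
  t2 <- track_dataset(shifted, arr, mag, truth = truth)
  expect_identical(t1$estimates, t2$estimates)
  expect_identical(t1$dist_est, t2$dist_est)
})

test_that("reversed frame order preserves the traveled distance", {
  arr <- sensor_array()
  mag <- magnet()
  truth <- generate_trajectory(n_samples = 10)
  ds <- simulate_dataset(truth, arr, mag, noiseless_model())
  fwd <- track_dataset(ds, arr, mag)
  rev_ds <- ds[10:1, ]
  rev_ds$t <- ds$t
  bwd <- track_dataset(rev_ds, arr, mag)
  expect_equal(bwd$dist_est, fwd$dist_est, tolerance = 1e-9)
})

test_that("position noise inflates the estimated distance one-sidedly", {
  arr <- sensor_array()
  mag <- magnet()
  truth <- generate_trajectory(n_samples = 40)
  dist_true <- traveled_distance(truth)
  infl <- vapply(1:5, function(s) {
    ds <- simulate_dataset(truth, arr, mag, sensor_model(),
                           geomagnetic_field(), seed = 500 + s)
    track_dataset(ds, arr, mag, truth = truth)$dist_est - dist_true
  }, numeric(1))
  expect_gt(mean(infl), 0)
})

test_that("a small experiment runs end to end, deterministically", {
  cfg <- mini_config()
  e1 <- run_experiment(cfg)
  expect_equal(nrow(e1$runs), 1L)
  expect_lt(e1$runs$rel_dist_err_pct, 5)
  expect_lt(e1$runs$mean_orient_err_deg, 5)
  expect_equal(e1$runs$n_converged, 12L)
  e2 <- run_experiment(mini_config())
  expect_identical(e1$runs, e2$runs)
  expect_identical(glance(e1), e1$summary)
  # zero-noise, zero-background config: errors collapse to ~0
  e0 <- run_experiment(mini_config(model = noiseless_model(),
                                   geomagnetic = c(0, 0, 0),
                                   speed_jitter = 0))
  expect_lt(e0$runs$rel_dist_err_pct, 0.1)
  expect_lt(e0$runs$mean_orient_err_deg, 0.1)
})

test_that("parallel magnetisation is restricted to the 10 mm magnet", {
  cfg <- mini_config(magnets = "3x10", orientation_mode = "parallel")
  expect_error(run_experiment(cfg), "parallel")
  cfg_ok <- mini_config(magnets = "3x10", orientation_mode = "parallel",
                        allow_parallel = TRUE, n_samples = 4L)
  expect_s3_class(run_experiment(cfg_ok), "magtrack_experiment")
})

test_that("autoplot methods return ggplot objects", {
  tr <- generate_trajectory(n_samples = 20)
  expect_s3_class(autoplot(tr), "ggplot")
  arr <- sensor_array()
  mag <- magnet()
  ds <- simulate_dataset(tr, arr, mag, noiseless_model())
  tk <- track_dataset(ds, arr, mag, truth = tr)
  expect_s3_class(autoplot(tk), "ggplot")
  e <- run_experiment(mini_config(n_samples = 6L))
  expect_s3_class(autoplot(e), "ggplot")
  expect_equal(nrow(tidy(e)), 1L)
})
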