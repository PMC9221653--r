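test_that("pair residuals vanish at the true pose and encode pairwise deltas", {
  arr <- sensor_array()
  mag <- magnet()
  truth <- pose(c(0.03, -0.02, 0.05), c(0.3, -0.1, 0.95))
  fr <- simulate_measurement(arr, mag, truth, noiseless_model())
  res <- pair_residuals(fr, arr, mag, truth)
  expect_equal(dim(res), c(66L, 3L))
  expect_equal(max(abs(res)), 0, tolerance = 1e-20)

  # per-sensor deltas d_i propagate to pair residuals d_i - d_j
  readings <- measurement_matrix(fr)
  d <- matrix(0, 12, 3)
  d[1, 1] <- 3e-6 # sensor 1: +3 uT on x
  d[2, 1] <- 1e-6 # sensor 2: +1 uT on x
  res_d <- pair_residuals(readings + d, arr, mag, truth)
  k12 <- which(arr$pairs[, 1] == 1L & arr$pairs[, 2] == 2L)
  expect_equal(unname(res_d[k12, ]), c(2e-6, 0, 0), tolerance = 1e-12)
})

test_that("the differential cost is the sum of squared pair-residual norms", {
  expect_equal(residual_cost(matrix(0, 66, 3)), 0)
  expect_equal(residual_cost(rbind(c(3, 4, 0))), 25)
  r <- matrix(rep(c(3, 4, 0), each = 7), 7, 3) # K pairs, each norm 5
  expect_equal(residual_cost(r), 7 * 25)
})

test_that("a homogeneous field cancels bit-for-bit in residuals and estimates", {
  arr <- sensor_array()
  mag <- magnet()
  truth <- pose(c(0.03, 0.04, -0.02), c(0.2, -0.4, 0.89))
  fx <- exact_grid_frames(arr, mag, truth)
  r0 <- pair_residuals(fx$base, arr, mag, truth)
  rg <- pair_residuals(fx$shifted, arr, mag, truth)
  expect_identical(r0, rg)
  # the whole LM iterate path is identical, hence bit-identical estimates
  f0 <- locate_pose(fx$base, arr, mag)
  fg <- locate_pose(fx$shifted, arr, mag)
  expect_identical(f0$pose, fg$pose)
  expect_identical(f0$cost, fg$cost)
  expect_identical(f0$n_iterations, fg$n_iterations)
})

test_that("warm-started solve recovers a noiseless pose from a perturbed init", {
  arr <- sensor_array()
  mag <- magnet()
  truth <- pose(c(0.030, 0.040, -0.020), c(0, 0, 1))
  fr <- simulate_measurement(arr, mag, truth, noiseless_model())

  exact <- locate_pose(fr, arr, mag, init = truth)
  expect_lt(exact$cost, 1e-20)
  expect_true(exact$converged)

  # init off by 20 mm and ~20 degrees
  init <- pose(truth$position + c(0.02, 0, 0) / sqrt(2) + c(0, 0.02, 0) / sqrt(2),
               c(sin(20 * pi / 180), 0, cos(20 * pi / 180)))
  fit <- locate_pose(fr, arr, mag, init = init)
  expect_lt(position_error_mm(fit, truth$position), 1e-3)
  expect_lt(orientation_error(fit$pose$orientation, truth$orientation), 1e-3)
})

test_that("under-determined pairings are rejected", {
  arr1 <- sensor_array(pairing = cbind(1L, 2L)) # K = 1 -> 3 residuals < 6
  mag <- magnet()
  fr <- simulate_measurement(arr1, mag, pose(c(0.02, 0, 0)), noiseless_model())
  expect_error(locate_pose(fr, arr1, mag), "under-determined")
})

test_that("grid-search oracle agrees with and never beats the LM solve", {
  arr <- sensor_array()
  mag <- magnet()
  truth <- pose(c(0.02, -0.01, 0.03), c(0, 1, 0))
  fr <- simulate_measurement(arr, mag, truth, noiseless_model())

  # grid containing the true pose -> exact argmin
  grid_hit <- rbind(c(0, 0, 0), truth$position, c(0.05, 0.05, 0.05))
  oracle <- grid_search_pose(fr, arr, mag, grid_hit,
                             orientations = rbind(c(0, 1, 0), c(0, 0, 1)))
  expect_equal(oracle$pose$position, truth$position)
  expect_lt(oracle$cost, 1e-25)

  # 11^3 grid around the truth: argmin within one grid cell
  step <- 0.004
  g1 <- seq(-5, 5) * step
  off <- as.matrix(expand.grid(g1, g1, g1))
  grid11 <- off + rep(truth$position + c(0.0013, -0.0011, 0.0009),
                      each = nrow(off))
  oracle11 <- grid_search_pose(fr, arr, mag, grid11,
                               orientations = rbind(c(0, 1, 0)))
  expect_lt(sqrt(sum((oracle11$pose$position - truth$position)^2)),
            sqrt(3) * step)

  # LM warm-started at the oracle argmin can only descend
  refined <- locate_pose(fr, arr, mag, init = oracle11$pose)
  expect_lte(refined$cost, oracle11$cost)
  # cold-start LM beats the coarse oracle too
  cold <- locate_pose(fr, arr, mag)
  expect_lte(cold$cost, oracle11$cost)
  expect_error(grid_search_pose(fr, arr, mag, matrix(0, 0, 3)), "empty")
})

test_that("the standard method is biased by a wrong geomagnetic assumption, the differential is not", {
  arr <- sensor_array()
  mag <- magnet()
  g <- geomagnetic_field()
  truth <- pose(c(0.03, 0.04, -0.02), c(0.3, 0.2, 0.93))
  fr <- simulate_measurement(arr, mag, truth, noiseless_model(),
                             geomagnetic = g)

  # correct assumption: both methods recover the truth
  std_ok <- locate_pose_standard(fr, arr, mag, geomagnetic_assumed = g,
                                 init = truth)
  expect_lt(position_error_mm(std_ok, truth$position), 1e-6)

  # zero assumption while the true background is 48 uT: standard is biased
  std_wrong <- locate_pose_standard(fr, arr, mag,
                                    geomagnetic_assumed = c(0, 0, 0),
                                    init = truth)
  diff_fit <- locate_pose(fr, arr, mag, init = truth)
  expect_gt(position_error_mm(std_wrong, truth$position),
            position_error_mm(diff_fit, truth$position))
  expect_gt(position_error_mm(std_wrong, truth$position), 1) # > 1 mm off

  # no background at all: the two methods coincide
  fr0 <- simulate_measurement(arr, mag, truth, noiseless_model())
  std0 <- locate_pose_standard(fr0, arr, mag, init = truth)
  dif0 <- locate_pose(fr0, arr, mag, init = truth)
  expect_equal(std0$pose$position, dif0$pose$position, tolerance = 1e-9)
})

test_that("median position error grows with the sensor noise level", {
  arr <- sensor_array()
  mag <- magnet()
  truth <- pose(c(0.02, 0.03, -0.01), c(0, 0, 1))
  med_err <- vapply(c(0.1e-6, 0.3e-6, 1.0e-6), function(sigma) {
    set.seed(7000 + round(sigma * 1e7))
    errs <- replicate(25, {
      fr <- simulate_measurement(arr, mag, truth,
                                 sensor_model(noise_sigma = sigma))
      position_error_mm(locate_pose(fr, arr, mag, init = truth),
                        truth$position)
    })
    stats::median(errs)
  }, numeric(1))
  expect_true(all(diff(med_err) > 0))
})

test_that("tidy and glance expose the fit parameters and diagnostics", {
  arr <- sensor_array()
  mag <- magnet()
  truth <- pose(c(0.01, 0.02, 0.03), c(1, 0, 0))
  fr <- simulate_measurement(arr, mag, truth, noiseless_model())
  fit <- locate_pose(fr, arr, mag, init = truth)
  td <- tidy(fit)
  expect_equal(td$term, c("x", "y", "z", "ox", "oy", "oz"))
  expect_equal(td$estimate[1:3], truth$position, tolerance = 1e-9)
  gl <- glance(fit)
  expect_true(gl$converged)
  expect_equal(gl$method, "differential")
})
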