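test_that("magnet moment equals magnetisation times cylinder volume", {
  for (spec in list(c(10, 10), c(5, 10), c(3, 10))) {
    m <- magnet(diameter = spec[2] * 1e-3, length = spec[1] * 1e-3)
    expect_equal(m$moment, 1150e3 * pi * (spec[2] * 1e-3 / 2)^2 * spec[1] * 1e-3,
                 tolerance = 1e-15)
  }
  expect_error(magnet(diameter = 0), "diameter")
  expect_error(magnet(magnetisation = -1))
})

test_that("catalog magnets resolve and unknown ids fail", {
  m <- magnet_from_catalog("10x10")
  expect_equal(m$moment, 0.9032079, tolerance = 1e-6)
  expect_equal(magnet_from_catalog("3x10")$length, 3e-3)
  expect_error(magnet_from_catalog("7x7"), "unknown magnet id")
})

test_that("dipole field matches the closed-form axial and equatorial values", {
  m <- magnet() # 10 x 10 mm, moment ~0.9032 A m^2
  p <- pose(orientation = c(0, 0, 1))
  # on-axis: B = mu0 m / (2 pi R^3), parallel to the axis
  B_ax <- dipole_field(m, p, c(0, 0, 0.1))
  expect_equal(B_ax[1:2], c(0, 0))
  expect_equal(B_ax[3], 2e-7 * m$moment / 0.1^3, tolerance = 1e-12)
  expect_equal(B_ax[3], 180.6e-6, tolerance = 1e-3) # ~180.6 uT
  # equatorial: antiparallel, half the axial magnitude at equal distance
  B_eq <- dipole_field(m, p, c(0.1, 0, 0))
  expect_equal(B_eq[3], -B_ax[3] / 2, tolerance = 1e-12)
  expect_equal(B_eq[1:2], c(0, 0))
})

test_that("dipole field scales as 1/R^3 and linearly in magnetisation", {
  m <- magnet()
  p <- pose(position = c(0.01, -0.02, 0.005), orientation = c(1, 2, -1))
  ray <- c(0.6, 0.64, 0.48) / sqrt(sum(c(0.6, 0.64, 0.48)^2))
  B1 <- dipole_field(m, p, p$position + 0.08 * ray)
  B2 <- dipole_field(m, p, p$position + 0.16 * ray)
  expect_equal(sqrt(sum(B1^2)) / sqrt(sum(B2^2)), 8, tolerance = 1e-12)

  m3 <- magnet(magnetisation = 3 * 1150e3)
  expect_equal(dipole_field(m3, p, c(0.1, 0.05, 0)),
               3 * dipole_field(m, p, c(0.1, 0.05, 0)), tolerance = 1e-15)
})

test_that("dipole field is equivariant under rigid rotations", {
  set.seed(11)
  m <- magnet()
  for (i in 1:10) {
    R <- random_rotation()
    pos <- stats::rnorm(3, sd = 0.02)
    o <- random_unit_vector()
    pt <- pos + 0.1 * random_unit_vector()
    B <- dipole_field(m, pose(pos, o), pt)
    B_rot <- dipole_field(m, pose(drop(R %*% pos), drop(R %*% o)),
                          drop(R %*% pt))
    expect_equal(B_rot, drop(R %*% B), tolerance = 1e-12)
  }
})

test_that("zero-distance observation point signals a singular evaluation", {
  m <- magnet()
  p <- pose(position = c(0.01, 0.02, 0.03))
  expect_error(dipole_field(m, p, c(0.01, 0.02, 0.03)), "singular")
})

test_that("finite-volume oracle collapses to the dipole at n = 1 and agrees in the far field", {
  p <- pose(orientation = c(0, 0, 1))
  pt <- c(0.03, 0.02, 0.09)
  m <- magnet()
  expect_identical(finite_volume_field(m, p, pt, 1), dipole_field(m, p, pt))

  rel_dev <- function(mag, pt, n = 1e4) {
    Bd <- dipole_field(mag, p, pt)
    Bf <- finite_volume_field(mag, p, pt, n)
    sqrt(sum((Bf - Bd)^2)) / sqrt(sum(Bd^2))
  }
  # R = 5 x magnet length -> < 1% deviation
  dir50 <- 0.05 * c(0.6, 0.53, 0.6) / sqrt(sum(c(0.6, 0.53, 0.6)^2))
  expect_lt(rel_dev(magnet(), dir50 / 0.05 * 0.05), 0.01)
  # 3 x 10 mm magnet at 150 mm -> < 0.1%
  dir150 <- 0.15 * c(0.2, 0.5, 0.84) / sqrt(sum(c(0.2, 0.5, 0.84)^2))
  expect_lt(rel_dev(magnet(length = 3e-3), dir150), 0.001)
})

test_that("dipole deviation decreases monotonically with distance along a ray", {
  m <- magnet()
  p <- pose(orientation = c(0, 0, 1))
  ray <- c(0.3, 0.4, 0.87) / sqrt(sum(c(0.3, 0.4, 0.87)^2))
  devs <- vapply(c(0.03, 0.05, 0.08, 0.12, 0.2), function(r) {
    Bd <- dipole_field(m, p, r * ray)
    Bf <- finite_volume_field(m, p, r * ray, 1e4)
    sqrt(sum((Bf - Bd)^2)) / sqrt(sum(Bd^2))
  }, numeric(1))
  expect_true(all(diff(devs) < 0))
})

test_that("total field superposes a homogeneous background", {
  m <- magnet()
  p <- pose(position = c(0.02, 0, -0.01), orientation = c(0, 1, 0))
  pts <- rbind(c(0.1, 0.1, 0), c(-0.15, 0.02, 0.08), c(0, -0.12, -0.05))
  expect_identical(total_field(m, p, pts, geomagnetic = NULL),
                   dipole_field(m, p, pts))
  g <- geomagnetic_field()
  diffs <- total_field(m, p, pts, geomagnetic = g) - dipole_field(m, p, pts)
  for (i in 1:3) expect_equal(diffs[i, ], g, tolerance = 1e-15,
                              ignore_attr = TRUE)
  # vanishing magnetisation limit: background only
  weak <- magnet(magnetisation = 1e-12)
  expect_equal(total_field(weak, p, c(0.1, 0, 0), geomagnetic = g), g,
               tolerance = 1e-12)
})

test_that("geomagnetic_field builds unit-direction scaled vectors", {
  g <- geomagnetic_field()
  expect_equal(sqrt(sum(g^2)), 48e-6, tolerance = 1e-15)
  expect_identical(geomagnetic_field(vector = c(1e-6, 0, 0)), c(1e-6, 0, 0))
})
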