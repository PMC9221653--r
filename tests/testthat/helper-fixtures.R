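# shared fixtures: all synthetic, built in code at test time

noiseless_model <- function() sensor_model(noise_sigma = 0, lsb = 0)

# uniform points on a sphere (uses the current RNG stream)
sphere_points <- function(n, radius = 48e-6) {
  th <- acos(stats::runif(n, -1, 1))
  ph <- stats::runif(n, 0, 2 * pi)
  radius * cbind(x = sin(th) * cos(ph), y = sin(th) * sin(ph), z = cos(th))
}

random_unit_vector <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

# random rotation matrix via QR of a Gaussian matrix
random_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

position_error_mm <- function(fit, truth_position) {
  sqrt(sum((fit$pose$position - truth_position)^2)) * 1e3
}

# noiseless frame plus the same frame with a homogeneous field added, both
# quantised to a power-of-two LSB so every addition is exact in binary64 and
# the differential cancellation is bit-for-bit
exact_grid_frames <- function(array, magnet, truth_pose,
                              g = geomagnetic_field(), lsb = 2^-25) {
  base <- simulate_measurement(array, magnet, truth_pose,
                               sensor_model(noise_sigma = 0, lsb = lsb))
  g <- round(g / lsb) * lsb
  shifted <- base
  cols <- grep("^s[0-9]{2}[xyz]$", names(base), value = TRUE)
  for (i in seq_along(cols)) {
    shifted[[cols[i]]] <- base[[cols[i]]] + g[((i - 1L) %% 3L) + 1L]
  }
  list(base = base, shifted = shifted, g = g)
}

# cache shared across test files (e.g. the expensive 30-run batch)
.test_cache <- new.env(parent = emptyenv())

# tiny but complete experiment config for protocol smoke tests
mini_config <- function(...) {
  defaults <- list(magnets = "10x10", z_planes = 0, layouts = "x",
                   repeats = 1L, n_samples = 12L, seed = 99L)
  do.call(experiment_config, utils::modifyList(defaults, list(...)))
}
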