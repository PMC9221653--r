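#' Elliptical-ring magnetometer array
#'
#' Builds the sensor-array geometry: three-axis magnetometers placed on
#' stacked elliptical rings around the abdomen, all sharing one global
#' orientation frame so every sensor pair is "equally oriented" and qualifies
#' for the differential method. The default reproduces the reference setup:
#' 12 sensors, 4 per ring at parametric ellipse angles 0/90/180/270 degrees,
#' ellipse semi-axes 200 x 165 mm (400 x 330 mm diameters), ring planes at
#' z = -100, 0, +100 mm.
#'
#' @param semi_axes Ellipse semi-axes `c(a, b)` in metres (x and y).
#' @param ring_z Ring plane offsets in metres.
#' @param angles_deg Parametric ellipse angles of the sensors on each ring.
#' @param pairing `"all"` for every unordered sensor pair (C(12,2) = 66 pairs,
#'   the default: maximises the equation count), `"disjoint"` for a partition
#'   into 6 pairs of diametrally opposite sensors on the same ring (ablation
#'   mode), or an explicit 2-column matrix of sensor indices (1-based, i < j).
#' @param orientations Optional list of per-sensor 3x3 rotation matrices
#'   mapping the array frame to the sensor frame; default: identity for all
#'   (readings reported in the array frame).
#'
#' @return An object of class `sensor_array`: list with `positions`
#'   (n x 3 matrix, metres), `orientations`, `pairs` (K x 2 matrix) and the
#'   pair differencing matrix `pair_diff` (K x n of +1/-1).
#' @examples
#' arr <- sensor_array()
#' nrow(arr$pairs) # 66
#' @export
sensor_array <- function(semi_axes = c(0.200, 0.165),
                         ring_z = c(-0.100, 0, 0.100),
                         angles_deg = c(0, 90, 180, 270),
                         pairing = c("all", "disjoint"),
                         orientations = NULL) {
  stopifnot(length(semi_axes) == 2L, all(semi_axes > 0),
            length(ring_z) >= 1L, length(angles_deg) >= 1L)
  th <- angles_deg * pi / 180
  pos <- do.call(rbind, lapply(ring_z, function(z) {
    cbind(semi_axes[1] * cos(th), semi_axes[2] * sin(th), z)
  }))
  # snap exact zeros lost to cos(pi/2) etc.
  pos[abs(pos) < 1e-15] <- 0
  n <- nrow(pos)
  rownames(pos) <- sprintf("s%02d", seq_len(n) - 1L)
  colnames(pos) <- c("x", "y", "z")

  if (is.null(orientations)) {
    orientations <- rep(list(diag(3)), n)
  }
  stopifnot(length(orientations) == n)

  pairs <- if (is.matrix(pairing)) {
    storage.mode(pairing) <- "integer"
    pairing
  } else {
    mode <- match.arg(pairing)
    if (mode == "all") {
      t(utils::combn(n, 2L))
    } else {
      per_ring <- length(angles_deg)
      if (per_ring < 2L) stop("disjoint pairing needs >= 2 sensors per ring",
                              call. = FALSE)
      half <- per_ring %/% 2L
      do.call(rbind, lapply(seq_along(ring_z), function(r) {
        base <- (r - 1L) * per_ring
        cbind(base + seq_len(half), base + seq_len(half) + half)
      }))
    }
  }
  stopifnot(ncol(pairs) == 2L, all(pairs >= 1L), all(pairs <= n),
            all(pairs[, 1] < pairs[, 2]))

  # the differential method requires equally oriented sensors in each pair
  same <- vapply(seq_len(nrow(pairs)), function(i) {
    isTRUE(all.equal(orientations[[pairs[i, 1]]], orientations[[pairs[i, 2]]],
                     tolerance = 1e-12))
  }, logical(1))
  if (!all(same)) {
    stop("pairing references sensors with different orientation frames; ",
         "the differential method requires equally oriented pairs",
         call. = FALSE)
  }
  if (nrow(pairs) == 0L) {
    stop("no equally oriented sensor pairs available", call. = FALSE)
  }

  D <- matrix(0, nrow(pairs), n)
  D[cbind(seq_len(nrow(pairs)), pairs[, 1])] <- 1
  D[cbind(seq_len(nrow(pairs)), pairs[, 2])] <- -1

  structure(list(positions = pos, orientations = orientations, pairs = pairs,
                 pair_diff = D, semi_axes = semi_axes, ring_z = ring_z,
                 angles_deg = angles_deg),
            class = "sensor_array")
}

#' @export
print.sensor_array <- function(x, ...) {
  cat(sprintf("<sensor_array> %d sensors on %d ring(s), %d equally oriented pair(s)\n",
              nrow(x$positions), length(x$ring_z), nrow(x$pairs)))
  invisible(x)
}

#' Sensor measurement-chain model
#'
#' Parameters of the magnetometer acquisition chain: full-scale clipping,
#' per-axis Gaussian noise, ADC quantisation and multi-sample averaging.
#' Defaults follow the reference device settings: +/-800 uT full scale,
#' 32 nT/LSB resolution, 3-sample averaging. The noise figure is a
#' representative magnetometer value (0.3 uT per axis before averaging) and
#' is freely configurable.
#'
#' @param full_scale Clipping range in tesla (readings clipped to
#'   `c(-full_scale, full_scale)`).
#' @param lsb Quantisation step in tesla; `0` disables quantisation.
#' @param noise_sigma Per-axis Gaussian noise standard deviation in tesla,
#'   applied to each raw sample before averaging.
#' @param n_average Number of raw samples averaged per reported reading.
#' @return An object of class `sensor_model`.
#' @export
sensor_model <- function(full_scale = 800e-6, lsb = 32e-9,
                         noise_sigma = 0.3e-6, n_average = 3L) {
  stopifnot(full_scale > 0, lsb >= 0, noise_sigma >= 0, n_average >= 1)
  structure(list(full_scale = full_scale, lsb = lsb,
                 noise_sigma = noise_sigma,
                 n_average = as.integer(n_average)),
            class = "sensor_model")
}

#' Simulate one array measurement frame
#'
#' Applies the full measurement chain to the true field at each sensor:
#' add the homogeneous geomagnetic background, draw `n_average` independent
#' noisy raw samples per axis, clip each to the full-scale range, round each
#' to the nearest LSB, then average. The chain order mirrors a physical
#' sensor front end (field superposition -> noise -> ADC clip -> ADC
#' quantise -> digital averaging). Uses the current RNG stream; wrap in
#' `set.seed()` (or pass datasets through [simulate_dataset()], which seeds
#' per run) for reproducibility.
#'
#' @param array A [sensor_array()].
#' @param magnet A [magnet()].
#' @param magnet_pose A [pose()].
#' @param model A [sensor_model()].
#' @param geomagnetic Homogeneous background 3-vector in tesla, or `NULL`.
#' @param t Timestamp in seconds for the output row.
#' @return A one-row tibble: column `t` plus 3 reading columns per sensor
#'   (`s00x` ... in tesla, array frame). The number of clipped raw samples is
#'   attached as attribute `n_clipped`.
#' @export
simulate_measurement <- function(array, magnet, magnet_pose,
                                 model = sensor_model(), geomagnetic = NULL,
                                 t = 0) {
  stopifnot(inherits(array, "sensor_array"), inherits(model, "sensor_model"))
  B <- dipole_field(magnet, magnet_pose, array$positions)
  if (!is.null(geomagnetic)) {
    B <- B + rep(geomagnetic_field(vector = geomagnetic), each = nrow(B))
  }
  # rotate into each sensor's frame (identity by default)
  for (i in seq_len(nrow(B))) {
    Ri <- array$orientations[[i]]
    if (!identical(Ri, diag(3))) B[i, ] <- as.numeric(Ri %*% B[i, ])
  }

  n_clipped <- 0L
  chain <- function(x) {
    clip <- abs(x) > model$full_scale
    n_clipped <<- n_clipped + sum(clip)
    x[clip] <- sign(x[clip]) * model$full_scale
    if (model$lsb > 0) x <- round(x / model$lsb) * model$lsb
    x
  }
  if (model$noise_sigma == 0) {
    # all raw samples are identical: averaging is exact, apply the chain once
    readings <- chain(B)
    n_clipped <- n_clipped * model$n_average
  } else {
    acc <- matrix(0, nrow(B), 3L)
    for (a in seq_len(model$n_average)) {
      acc <- acc + chain(B + matrix(stats::rnorm(length(B),
                                                 sd = model$noise_sigma),
                                    nrow(B), 3L))
    }
    readings <- acc / model$n_average
  }

  out <- tibble::as_tibble(
    c(list(t = t),
      stats::setNames(as.list(as.numeric(t(readings))), .meas_cols(nrow(B)))))
  attr(out, "n_clipped") <- n_clipped
  out
}
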