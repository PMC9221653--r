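#' Generate a synthetic GIT-model trajectory
#'
#' Builds the ground-truth path used throughout the evaluation protocol: a
#' planar serpentine (sinusoid with `n_half_waves` half-lobes) embedded in a
#' plane tilted by `tilt_deg`, so that the run along the tilted direction
#' produces the stated endpoint vertical displacement, with the transverse
#' amplitude solved numerically so the true curve's arc length equals
#' `arc_length` exactly. The default preset (`serpentine-v1`) reproduces the
#' reference gastrointestinal-tract-model dimensions: 487.5 mm arc length,
#' 15 degree tilt, 49 mm vertical displacement, traversed in 40 s. The path
#' is centred at the origin; `z_plane` shifts it vertically and
#' `layout = "y"` rotates it 90 degrees about z.
#'
#' With `speed_jitter > 0` the arc-length increments between successive
#' samples are randomised (hand-moved magnet: the distance between
#' successive points is not uniform); timestamps stay uniform. Uses the
#' current RNG stream when jittered, or `seed` if given.
#'
#' @param n_samples Number of pose samples along the path (>= 2).
#' @param duration Traversal time in seconds.
#' @param z_plane Vertical offset of the path centre in metres
#'   (protocol values: -0.06, 0, 0.06).
#' @param layout `"x"` (run along x) or `"y"` (rotated 90 degrees about z).
#' @param orientation_mode Magnetisation relative to the moving direction:
#'   `"perpendicular"` (default; orientation = tangent x global z,
#'   renormalised) or `"parallel"` (orientation = tangent).
#' @param arc_length Total path arc length in metres.
#' @param tilt_deg Tilt angle of the path plane in degrees.
#' @param vertical_displacement Endpoint z displacement in metres.
#' @param transverse_limit Maximum transverse extent (2 x amplitude) in
#'   metres; the fit errors out if the requested arc length needs more.
#' @param n_half_waves Number of sinusoid half-lobes (shape parameter of the
#'   preset).
#' @param speed_jitter Relative standard deviation of the per-step arc-length
#'   increments (0 = uniform sampling).
#' @param seed Optional RNG seed for the jitter (caller's RNG state is
#'   restored).
#' @return A tibble of class `magtrack_trajectory` with columns `t` (s),
#'   `x`, `y`, `z` (m) and unit orientation `ox`, `oy`, `oz`; path metadata
#'   is stored in attributes (`preset`, `arc_length`, `amplitude`,
#'   `z_plane`, `layout`, `orientation_mode`, `tilt_deg`).
#' @examples
#' traj <- generate_trajectory(n_samples = 200)
#' traveled_distance(traj) # slightly below 0.4875 (polyline shortfall)
#' @export
generate_trajectory <- function(n_samples = 100L, duration = 40,
                                z_plane = 0, layout = c("x", "y"),
                                orientation_mode = c("perpendicular", "parallel"),
                                arc_length = 0.4875, tilt_deg = 15,
                                vertical_displacement = 0.049,
                                transverse_limit = 0.180, n_half_waves = 3L,
                                speed_jitter = 0, seed = NULL) {
  layout <- match.arg(layout)
  orientation_mode <- match.arg(orientation_mode)
  stopifnot(n_samples >= 2L, duration > 0, arc_length > 0,
            tilt_deg > 0, tilt_deg < 90, vertical_displacement > 0,
            transverse_limit > 0, n_half_waves >= 1L, speed_jitter >= 0)

  alpha <- tilt_deg * pi / 180
  U <- vertical_displacement / sin(alpha) # run along the tilted direction
  k <- n_half_waves * pi / U
  true_len <- function(A) {
    stats::integrate(function(u) sqrt(1 + (A * k * cos(k * u))^2), 0, U,
                     rel.tol = 1e-13, subdivisions = 2000L)$value
  }
  if (arc_length < U) {
    stop("requested arc length (", arc_length * 1e3,
         " mm) is shorter than the tilted straight run (", round(U * 1e3, 1),
         " mm) implied by tilt and vertical displacement", call. = FALSE)
  }
  A_max <- transverse_limit / 2
  if (true_len(A_max) < arc_length) {
    stop("requested footprint cannot accommodate the requested arc length: ",
         "amplitude needed exceeds transverse_limit/2", call. = FALSE)
  }
  A <- if (arc_length == U) 0 else
    stats::uniroot(function(A) true_len(A) - arc_length, c(0, A_max),
                   tol = 1e-14)$root

  # dense arc-length table for inverting s -> u
  n_dense <- max(20001L, 4L * n_samples + 1L)
  u_d <- seq(0, U, length.out = n_dense)
  p_d <- cbind(u_d * cos(alpha), A * sin(k * u_d), u_d * sin(alpha))
  s_d <- c(0, cumsum(sqrt(rowSums(diff(p_d)^2))))
  L <- s_d[n_dense]

  s_targets <- if (speed_jitter > 0) {
    incr <- .with_seed(seed,
                       pmax(1 + speed_jitter * stats::rnorm(n_samples - 1L),
                            0.05))
    c(0, cumsum(incr)) / sum(incr) * L
  } else {
    seq(0, L, length.out = n_samples)
  }
  u_s <- stats::approx(s_d, u_d, xout = s_targets, ties = "ordered")$y
  u_s[1] <- 0
  u_s[n_samples] <- U

  x <- u_s * cos(alpha) - U * cos(alpha) / 2
  y <- A * sin(k * u_s)
  z <- u_s * sin(alpha) - U * sin(alpha) / 2

  # analytic unit tangent along the path
  tan_raw <- cbind(cos(alpha), A * k * cos(k * u_s), sin(alpha))
  tan_u <- tan_raw / sqrt(rowSums(tan_raw^2))

  if (layout == "y") { # rotate +90 degrees about z
    tmp <- x; x <- -y; y <- tmp
    tan_u <- cbind(-tan_u[, 2], tan_u[, 1], tan_u[, 3])
  }
  z <- z + z_plane

  o <- if (orientation_mode == "parallel") {
    tan_u
  } else {
    # tangent x global z: horizontal, exactly perpendicular to the tangent;
    # never degenerate here because the tangent always has a horizontal part
    perp <- cbind(tan_u[, 2], -tan_u[, 1], 0)
    perp / sqrt(rowSums(perp^2))
  }

  out <- tibble::tibble(
    t = seq(0, duration, length.out = n_samples),
    x = x, y = y, z = z,
    ox = o[, 1], oy = o[, 2], oz = o[, 3])
  class(out) <- c("magtrack_trajectory", class(out))
  attr(out, "preset") <- "serpentine-v1"
  attr(out, "arc_length") <- arc_length
  attr(out, "amplitude") <- A
  attr(out, "z_plane") <- z_plane
  attr(out, "layout") <- layout
  attr(out, "orientation_mode") <- orientation_mode
  attr(out, "tilt_deg") <- tilt_deg
  out
}
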