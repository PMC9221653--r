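#' Traveled distance of an ordered position sequence
#'
#' Accumulates Euclidean segment lengths between successive positions,
#' \eqn{D = \sum_i \|P_{i+1} - P_i\|}. A single position gives 0. Units
#' follow the input.
#'
#' @param positions A data frame with columns `x`, `y`, `z` (e.g. a
#'   trajectory or pose-estimate tibble) or an n x 3 matrix.
#' @return Nonnegative scalar in the input's length unit.
#' @examples
#' traveled_distance(rbind(c(0, 0, 0), c(3, 4, 0), c(3, 4, 12))) # 17
#' @export
traveled_distance <- function(positions) {
  X <- .as_xyz_matrix(positions)
  if (nrow(X) == 0L) stop("empty position list", call. = FALSE)
  if (nrow(X) == 1L) return(0)
  sum(sqrt(rowSums(diff(X)^2)))
}

#' Relative traveled-distance error
#'
#' `100 * |estimated - reference| / reference`, in percent.
#'
#' @param est_length Estimated traveled distance.
#' @param true_length Reference length (> 0), same unit.
#' @return Percentage (>= 0).
#' @export
relative_distance_error <- function(est_length, true_length) {
  stopifnot(is.numeric(est_length), is.numeric(true_length))
  if (any(true_length <= 0)) {
    stop("reference length must be positive", call. = FALSE)
  }
  100 * abs(est_length - true_length) / true_length
}

#' Angle between estimated and reference orientations
#'
#' In `"axis"` mode (default) the sign of the orientation axis is ignored:
#' `acos(|<e, r>|)`, range 0--90 degrees. In `"signed"` mode the full angle
#' `acos(<e, r>)` is returned, range 0--180 degrees.
#'
#' @param estimated,reference Nonzero 3-vectors or n x 3 matrices
#'   (row-wise pairing; normalised internally).
#' @param mode `"axis"` or `"signed"`.
#' @return Angle(s) in degrees.
#' @export
orientation_error <- function(estimated, reference,
                              mode = c("axis", "signed")) {
  mode <- match.arg(mode)
  E <- rbind(estimated)
  R <- rbind(reference)
  if (nrow(E) == 1L && nrow(R) > 1L) E <- E[rep(1L, nrow(R)), , drop = FALSE]
  if (nrow(R) == 1L && nrow(E) > 1L) R <- R[rep(1L, nrow(E)), , drop = FALSE]
  stopifnot(ncol(E) == 3L, ncol(R) == 3L, nrow(E) == nrow(R))
  ne <- sqrt(rowSums(E^2)); nr <- sqrt(rowSums(R^2))
  if (any(ne == 0) || any(nr == 0)) {
    stop("zero orientation vector", call. = FALSE)
  }
  d <- rowSums(E * R) / (ne * nr)
  d <- pmin(1, pmax(-1, d))
  if (mode == "axis") d <- abs(d)
  ang <- acos(d) * 180 / pi
  if (length(ang) == 1L) ang[[1]] else ang
}

# secondary "tilt-angle" metric: per-sample angle between the estimated
# orientation and the horizontal (untilted layout) plane, minus the nominal
# path tilt; meaningful only under conventions where the magnet orientation
# leaves the horizontal plane
.tilt_angle_error <- function(o_est, tilt_deg) {
  o <- rbind(o_est)
  ang_plane <- asin(pmin(1, abs(o[, 3]) / sqrt(rowSums(o^2)))) * 180 / pi
  ang_plane - tilt_deg
}

#' Sequentially localise every frame of a dataset
#'
#' Runs the differential localizer over an ordered measurement table:
#' cold start (grid multi-start) on the first frame, then each subsequent
#' frame warm-started from the previous converged estimate — the previous
#' pose is an excellent initial guess at tracking frame rates.
#'
#' @param measurements Wide measurement tibble (`t` + `s00x` ... columns,
#'   tesla), one row per frame, ordered in time.
#' @param array A [sensor_array()].
#' @param magnet A [magnet()].
#' @param control A [localizer_control()].
#' @param init Optional [pose()] warm start for the first frame (skips the
#'   cold-start grid).
#' @return A tibble with one row per frame: `t`, `x`, `y`, `z` (m), `ox`,
#'   `oy`, `oz`, `cost`, `n_iterations`, `converged`.
#' @export
locate_poses <- function(measurements, array, magnet,
                         control = localizer_control(), init = NULL) {
  n <- nrow(measurements)
  stopifnot(n >= 1L)
  out <- vector("list", n)
  prev <- init
  for (i in seq_len(n)) {
    fit <- locate_pose(measurements[i, ], array, magnet, init = prev,
                       control = control)
    if (isTRUE(fit$converged)) prev <- fit$pose
    out[[i]] <- tibble::tibble(
      t = measurements$t[i],
      x = fit$pose$position[1], y = fit$pose$position[2],
      z = fit$pose$position[3],
      ox = fit$pose$orientation[1], oy = fit$pose$orientation[2],
      oz = fit$pose$orientation[3],
      cost = fit$cost, n_iterations = fit$n_iterations,
      converged = fit$converged)
  }
  dplyr::bind_rows(out)
}

#' Track a magnet over a dataset and evaluate against ground truth
#'
#' Sequential tracking ([locate_poses()]) followed by the evaluation
#' metrics: traveled distance of the estimated polyline, relative distance
#' error against the Eq.-length of the ground-truth sample polyline (and,
#' secondarily, against the nominal path arc length when the truth carries
#' one), and per-sample orientation errors. Non-converged frames are
#' excluded from the orientation mean and enter the distance through the
#' last converged position (carry-forward, contributing zero extra length).
#'
#' @inheritParams locate_poses
#' @param truth Optional ground-truth trajectory tibble (`t`, `x`, `y`, `z`,
#'   `ox`, `oy`, `oz`), same sampling as `measurements`; metrics requiring
#'   truth are `NA` without it.
#' @return An object of class `magtrack_tracking`: list with `estimates`
#'   (the [locate_poses()] tibble), `truth`, `dist_est`, `dist_true`,
#'   `dist_nominal` (m), `rel_dist_err_pct`, `rel_dist_err_nominal_pct`,
#'   `orient_err_deg` (per converged sample), `mean_orient_err_deg`,
#'   `tilt_orient_err_deg`, `n_converged`. `tidy()`, `glance()` and
#'   `autoplot()` methods are provided.
#' @export
track_dataset <- function(measurements, array, magnet, truth = NULL,
                          control = localizer_control(), init = NULL) {
  est <- locate_poses(measurements, array, magnet, control = control,
                      init = init)
  if (!any(est$converged)) {
    stop("tracking failed: no frame converged", call. = FALSE)
  }

  # carry the last converged position forward through failed frames
  P <- as.matrix(est[, c("x", "y", "z")])
  last_ok <- NA_integer_
  for (i in seq_len(nrow(P))) {
    if (est$converged[i]) last_ok <- i
    else if (!is.na(last_ok)) P[i, ] <- P[last_ok, ]
  }
  first_ok <- which(est$converged)[1]
  if (first_ok > 1L) P[seq_len(first_ok - 1L), ] <- P[rep(first_ok, first_ok - 1L), ]

  dist_est <- traveled_distance(P)
  res <- list(estimates = est, truth = truth, dist_est = dist_est,
              n_converged = sum(est$converged))

  if (!is.null(truth)) {
    stopifnot(nrow(truth) == nrow(est))
    dist_true <- traveled_distance(truth)
    nominal <- attr(truth, "arc_length")
    tilt <- attr(truth, "tilt_deg")
    ok <- est$converged
    oe <- orientation_error(as.matrix(est[ok, c("ox", "oy", "oz")]),
                            as.matrix(truth[ok, c("ox", "oy", "oz")]),
                            mode = "axis")
    res$dist_true <- dist_true
    res$dist_nominal <- nominal
    res$rel_dist_err_pct <- relative_distance_error(dist_est, dist_true)
    res$rel_dist_err_nominal_pct <-
      if (is.null(nominal)) NA_real_
      else relative_distance_error(dist_est, nominal)
    res$orient_err_deg <- oe
    res$mean_orient_err_deg <- mean(oe)
    res$tilt_orient_err_deg <-
      if (is.null(tilt)) NA_real_
      else mean(.tilt_angle_error(as.matrix(est[ok, c("ox", "oy", "oz")]),
                                  tilt))
  } else {
    res$dist_true <- NA_real_
    res$dist_nominal <- NA_real_
    res$rel_dist_err_pct <- NA_real_
    res$rel_dist_err_nominal_pct <- NA_real_
    res$orient_err_deg <- numeric(0)
    res$mean_orient_err_deg <- NA_real_
    res$tilt_orient_err_deg <- NA_real_
  }
  structure(res, class = "magtrack_tracking")
}

#' @export
print.magtrack_tracking <- function(x, ...) {
  cat(sprintf("<magtrack_tracking> %d frame(s), %d converged; traveled %.1f mm",
              nrow(x$estimates), x$n_converged, x$dist_est * 1e3))
  if (!is.na(x$rel_dist_err_pct)) {
    cat(sprintf(" (true %.1f mm, rel err %.2f%%, mean orient err %.2f deg)",
                x$dist_true * 1e3, x$rel_dist_err_pct,
                x$mean_orient_err_deg))
  }
  cat("\n")
  invisible(x)
}
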