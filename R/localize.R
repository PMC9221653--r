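#' Differential pair residuals
#'
#' The core of the differential method: for every equally oriented sensor
#' pair (i, j) the residual is
#' \deqn{\Delta B_{pair} = (B^{meas}_i - B^{model}_i) - (B^{meas}_j - B^{model}_j),}
#' where the model value is the dipole field of the trial pose at the sensor
#' position. Any spatially homogeneous additive field in the measurements —
#' in particular the geomagnetic background — cancels exactly in the
#' difference, so no assumption about the background enters the fit.
#'
#' @param measurements One measurement frame: a one-row wide tibble (from
#'   [simulate_measurement()] / [read_measurements()]) or an n_sensors x 3
#'   matrix in tesla.
#' @param array A [sensor_array()].
#' @param magnet A [magnet()].
#' @param trial_pose A [pose()] (a nonzero orientation vector is normalised
#'   by the `pose()` constructor).
#' @return A K x 3 matrix of residual flux densities (tesla), one row per
#'   sensor pair.
#' @export
pair_residuals <- function(measurements, array, magnet, trial_pose) {
  stopifnot(inherits(array, "sensor_array"), inherits(magnet, "magnet"),
            inherits(trial_pose, "pose"))
  readings <- if (is.matrix(measurements)) measurements
              else measurement_matrix(measurements)
  stopifnot(nrow(readings) == nrow(array$positions))
  meas_diff <- array$pair_diff %*% readings
  model <- .dipole_field_m(magnet$moment, trial_pose$position,
                           trial_pose$orientation, array$positions)
  meas_diff - array$pair_diff %*% model
}

#' Differential cost function
#'
#' Sum of squared pair-residual norms,
#' \eqn{\epsilon_{diff} = \sum_{i=1}^{K} \|\Delta B_{pair,i}\|^2}, the
#' quantity minimised by [locate_pose()].
#'
#' @param residuals A K x 3 residual matrix from [pair_residuals()] (any
#'   numeric array works).
#' @return Nonnegative scalar, tesla squared.
#' @export
residual_cost <- function(residuals) {
  sum(as.numeric(residuals)^2)
}

#' Localizer solver settings
#'
#' @param ftol,ptol Relative cost / parameter convergence tolerances passed
#'   to the Levenberg-Marquardt solver.
#' @param maxiter Maximum iterations per start.
#' @param grid_n Cold-start grid resolution per position axis (grid_n^3
#'   positions x 6 axis-aligned orientations are scored).
#' @param n_starts Number of best-scoring grid candidates refined by LM on a
#'   cold start.
#' @return A list of class `localizer_control`.
#' @export
localizer_control <- function(ftol = 1e-10, ptol = 1e-10, maxiter = 200L,
                              grid_n = 5L, n_starts = 6L) {
  structure(list(ftol = ftol, ptol = ptol, maxiter = as.integer(maxiter),
                 grid_n = as.integer(grid_n), n_starts = as.integer(n_starts)),
            class = "localizer_control")
}

# residual closure over precomputed measured pair differences;
# par = (px, py, pz, ox, oy, oz), orientation normalised inside the model
.make_resid_fun <- function(meas_diff, D, positions, moment) {
  function(par) {
    p <- par[1:3]
    o <- par[4:6]
    on2 <- sum(o * o)
    R <- positions - rep(p, each = nrow(positions))
    r2 <- rowSums(R * R)
    if (!is.finite(on2) || on2 < 1e-300 || any(!is.finite(r2)) ||
        any(r2 < 1e-12)) {
      return(rep(1, length(meas_diff))) # push LM away from singular poses
    }
    o <- o / sqrt(on2)
    odotR <- as.numeric(R %*% o)
    model <- 1e-7 * moment *
      (3 * odotR * r2^(-2.5) * R - tcrossprod(r2^(-1.5), o))
    as.numeric(meas_diff - D %*% model)
  }
}

# per-sensor residual closure for the non-differential baseline
.make_resid_fun_standard <- function(readings, positions, moment, g_assumed) {
  meas <- readings - rep(g_assumed, each = nrow(readings))
  function(par) {
    p <- par[1:3]
    o <- par[4:6]
    on2 <- sum(o * o)
    R <- positions - rep(p, each = nrow(positions))
    r2 <- rowSums(R * R)
    if (!is.finite(on2) || on2 < 1e-300 || any(!is.finite(r2)) ||
        any(r2 < 1e-12)) {
      return(rep(1, length(meas)))
    }
    o <- o / sqrt(on2)
    odotR <- as.numeric(R %*% o)
    model <- 1e-7 * moment *
      (3 * odotR * r2^(-2.5) * R - tcrossprod(r2^(-1.5), o))
    as.numeric(meas - model)
  }
}

.lm_refine <- function(par0, fn, control) {
  fit <- suppressWarnings(minpack.lm::nls.lm(
    par = par0, fn = fn,
    control = minpack.lm::nls.lm.control(
      ftol = control$ftol, ptol = control$ptol, gtol = 0,
      maxiter = control$maxiter, maxfev = 100L * (control$maxiter + 1L))))
  list(par = fit$par, cost = fit$deviance, n_iterations = fit$niter,
       converged = fit$info %in% c(1L, 2L, 3L, 4L))
}

# cold-start candidates: grid_n^3 positions spanning the array interior
# crossed with the 6 axis-aligned orientations
.cold_start_candidates <- function(array, control) {
  a <- array$semi_axes[1] * 0.75
  b <- array$semi_axes[2] * 0.75
  zr <- range(array$ring_z)
  gx <- seq(-a, a, length.out = control$grid_n)
  gy <- seq(-b, b, length.out = control$grid_n)
  gz <- seq(zr[1], zr[2], length.out = control$grid_n)
  pos <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
  ors <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
               c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  list(positions = pos, orientations = ors)
}

.solve_frame <- function(fn, array, init, control) {
  if (!is.null(init)) {
    starts <- list(c(init$position, init$orientation))
  } else {
    cand <- .cold_start_candidates(array, control)
    np <- nrow(cand$positions)
    no <- nrow(cand$orientations)
    costs <- matrix(Inf, np, no)
    for (j in seq_len(no)) {
      o <- cand$orientations[j, ]
      for (i in seq_len(np)) {
        r <- fn(c(cand$positions[i, ], o))
        costs[i, j] <- sum(r * r)
      }
    }
    ord <- order(costs)[seq_len(min(control$n_starts, length(costs)))]
    starts <- lapply(ord, function(k) {
      i <- (k - 1L) %% np + 1L
      j <- (k - 1L) %/% np + 1L
      c(cand$positions[i, ], cand$orientations[j, ])
    })
  }
  best <- NULL
  for (s in starts) {
    fit <- .lm_refine(s, fn, control)
    if (is.null(best) || fit$cost < best$cost) best <- fit
  }
  best
}

.as_pose_fit <- function(fit, method) {
  est <- pose(position = fit$par[1:3], orientation = fit$par[4:6])
  structure(list(pose = est, cost = fit$cost,
                 n_iterations = fit$n_iterations, converged = fit$converged,
                 method = method),
            class = "magtrack_pose_fit")
}

#' Estimate the magnet pose from one frame (differential method)
#'
#' Minimises the differential cost [residual_cost()] over the 6 unknowns
#' (3 position components + a free 3-vector orientation, normalised inside
#' the field model and on output) with the Levenberg-Marquardt algorithm.
#' With `init = NULL` (cold start) a coarse grid over the array interior
#' crossed with the 6 axis-aligned orientations is scored first and the best
#' candidates are refined; with an `init` pose (warm start, used during
#' tracking) LM starts there directly.
#'
#' @inheritParams pair_residuals
#' @param init Optional [pose()] warm start.
#' @param control A [localizer_control()].
#' @return An object of class `magtrack_pose_fit`: list with `pose`, `cost`
#'   (tesla^2), `n_iterations`, `converged`, `method`. `tidy()` and
#'   `glance()` methods are provided.
#' @examples
#' arr <- sensor_array(); mag <- magnet()
#' truth <- pose(c(0.03, 0.04, -0.02), c(0, 0, 1))
#' frame <- simulate_measurement(arr, mag, truth,
#'                               sensor_model(noise_sigma = 0, lsb = 0))
#' fit <- locate_pose(frame, arr, mag, init = truth)
#' fit$cost # ~0
#' @export
locate_pose <- function(measurements, array, magnet, init = NULL,
                        control = localizer_control()) {
  stopifnot(inherits(array, "sensor_array"), inherits(magnet, "magnet"))
  readings <- if (is.matrix(measurements)) measurements
              else measurement_matrix(measurements)
  if (3L * nrow(array$pairs) < 6L) {
    stop("under-determined system: need at least 2 sensor pairs (3K >= 6)",
         call. = FALSE)
  }
  meas_diff <- array$pair_diff %*% readings
  fn <- .make_resid_fun(meas_diff, array$pair_diff, array$positions,
                        magnet$moment)
  .as_pose_fit(.solve_frame(fn, array, init, control), "differential")
}

#' Estimate the magnet pose without geomagnetic compensation (baseline)
#'
#' The non-differential baseline: per-sensor residuals
#' `measured - model - geomagnetic_assumed`, minimised the same way as
#' [locate_pose()]. When the assumed background is wrong the estimate is
#' biased, whereas the differential method is unaffected by construction —
#' this function exists to demonstrate exactly that.
#'
#' @inheritParams locate_pose
#' @param geomagnetic_assumed Background 3-vector (tesla) subtracted from
#'   every sensor reading before fitting.
#' @return A `magtrack_pose_fit` (method `"standard"`).
#' @export
locate_pose_standard <- function(measurements, array, magnet,
                                 geomagnetic_assumed = c(0, 0, 0),
                                 init = NULL, control = localizer_control()) {
  stopifnot(inherits(array, "sensor_array"), inherits(magnet, "magnet"))
  readings <- if (is.matrix(measurements)) measurements
              else measurement_matrix(measurements)
  fn <- .make_resid_fun_standard(readings, array$positions, magnet$moment,
                                 geomagnetic_field(vector = geomagnetic_assumed))
  .as_pose_fit(.solve_frame(fn, array, init, control), "standard")
}

#' Brute-force grid-search pose estimate (verification oracle)
#'
#' Exhaustively evaluates the differential cost on a finite pose grid and
#' returns the argmin. Intended as an independent cross-check of
#' [locate_pose()] on coarse instances, not for production use.
#'
#' @inheritParams locate_pose
#' @param positions m x 3 matrix of candidate positions (metres).
#' @param orientations k x 3 matrix of candidate orientations (normalised
#'   internally).
#' @return A `magtrack_pose_fit` (method `"grid_search"`, `n_iterations` is
#'   the number of grid points evaluated).
#' @export
grid_search_pose <- function(measurements, array, magnet, positions,
                             orientations = rbind(c(1, 0, 0), c(-1, 0, 0),
                                                  c(0, 1, 0), c(0, -1, 0),
                                                  c(0, 0, 1), c(0, 0, -1))) {
  stopifnot(inherits(array, "sensor_array"), inherits(magnet, "magnet"))
  positions <- rbind(positions)
  orientations <- rbind(orientations)
  if (nrow(positions) == 0L || nrow(orientations) == 0L) {
    stop("empty search grid", call. = FALSE)
  }
  readings <- if (is.matrix(measurements)) measurements
              else measurement_matrix(measurements)
  meas_diff <- array$pair_diff %*% readings
  fn <- .make_resid_fun(meas_diff, array$pair_diff, array$positions,
                        magnet$moment)
  best <- list(cost = Inf)
  n_eval <- 0L
  for (j in seq_len(nrow(orientations))) {
    o <- .normalize(orientations[j, ])
    for (i in seq_len(nrow(positions))) {
      r <- fn(c(positions[i, ], o))
      cst <- sum(r * r)
      n_eval <- n_eval + 1L
      if (cst < best$cost) {
        best <- list(par = c(positions[i, ], o), cost = cst)
      }
    }
  }
  .as_pose_fit(list(par = best$par, cost = best$cost, n_iterations = n_eval,
                    converged = TRUE), "grid_search")
}

#' @export
print.magtrack_pose_fit <- function(x, ...) {
  cat(sprintf("<pose_fit:%s> position (%.2f, %.2f, %.2f) mm, cost %.3g T^2, %s in %d iter\n",
              x$method,
              x$pose$position[1] * 1e3, x$pose$position[2] * 1e3,
              x$pose$position[3] * 1e3, x$cost,
              if (isTRUE(x$converged)) "converged" else "NOT converged",
              x$n_iterations))
  invisible(x)
}
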