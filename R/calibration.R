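#' Hard-/soft-iron magnetometer calibration by ellipsoid fitting
#'
#' A magnetometer rotated through all orientations in a constant field traces
#' a sphere of radius equal to the field magnitude; hard-iron (additive
#' offset) and soft-iron (linear, ellipsoidal) distortions turn that sphere
#' into an offset ellipsoid. `fit_ellipsoid()` recovers the correction by a
#' constrained algebraic quadric least-squares fit: solve
#' \eqn{x^\top M x + 2 b^\top x = 1} for the 9 quadric parameters, extract
#' the centre \eqn{x_0 = -M^{-1} b} (hard-iron offset) and the ellipsoid
#' matrix, and take the unique symmetric positive-definite square root scaled
#' to the reference radius as the soft-iron correction matrix, so that
#' `soft_iron %*% (raw - hard_iron)` lies on the reference sphere.
#'
#' @param samples Raw readings: a data frame with columns `x`, `y`, `z` or an
#'   n x 3 matrix (tesla). At least 9 non-coplanar points spanning the
#'   ellipsoid are required.
#' @param reference_radius Radius of the target sphere in tesla; default the
#'   local geomagnetic magnitude, 48 uT.
#' @return An object of class `calibration_model`: list with `soft_iron`
#'   (symmetric positive-definite 3x3), `hard_iron` (3-vector, tesla),
#'   `reference_radius` and `rms_radius_error` (relative RMS radius residual
#'   of the calibrated samples).
#' @examples
#' th <- acos(stats::runif(200, -1, 1)); ph <- stats::runif(200, 0, 2 * pi)
#' u <- 48e-6 * cbind(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
#' fit <- fit_ellipsoid(u) # ~identity model on undistorted sphere data
#' @export
fit_ellipsoid <- function(samples, reference_radius = 48e-6) {
  X <- .as_xyz_matrix(samples)
  if (nrow(X) < 9L) {
    stop("ellipsoid fit needs at least 9 samples, got ", nrow(X), call. = FALSE)
  }
  stopifnot(reference_radius > 0)

  sc <- mean(sqrt(rowSums(X^2)))
  if (sc == 0) stop("degenerate samples: all at the origin", call. = FALSE)
  U <- X / sc
  D <- cbind(U[, 1]^2, U[, 2]^2, U[, 3]^2,
             2 * U[, 1] * U[, 2], 2 * U[, 1] * U[, 3], 2 * U[, 2] * U[, 3],
             2 * U[, 1], 2 * U[, 2], 2 * U[, 3])
  qrD <- qr(D)
  if (qrD$rank < 9L) {
    stop("degenerate samples (coplanar or otherwise rank-deficient): ",
         "cannot determine a unique quadric", call. = FALSE)
  }
  v <- qr.coef(qrD, rep(1, nrow(D)))
  M <- matrix(c(v[1], v[4], v[5],
                v[4], v[2], v[6],
                v[5], v[6], v[3]), 3L, 3L)
  b <- v[7:9]
  x0 <- drop(solve(M, -b))
  # (x - x0)' M (x - x0) = 1 + b' M^-1 b
  s <- 1 + drop(t(b) %*% solve(M, b))
  E <- M / s
  ev <- eigen(E, symmetric = TRUE)
  if (any(ev$values <= 0)) {
    stop("fitted quadric is not an ellipsoid (non-positive-definite)",
         call. = FALSE)
  }
  # unique symmetric positive-definite square root, scaled to the reference
  # sphere; the rotational ambiguity of ellipsoid fits is resolved by symmetry
  A_u <- ev$vectors %*% (sqrt(ev$values) * t(ev$vectors))
  soft_iron <- reference_radius * A_u / sc
  hard_iron <- x0 * sc

  cal <- (X - rep(hard_iron, each = nrow(X))) %*% t(soft_iron)
  rms <- sqrt(mean((sqrt(rowSums(cal^2)) / reference_radius - 1)^2))

  structure(list(soft_iron = soft_iron, hard_iron = hard_iron,
                 reference_radius = reference_radius, rms_radius_error = rms),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("<calibration_model> hard-iron offset (%.3f, %.3f, %.3f) uT, rms radius error %.3g\n",
              x$hard_iron[1] * 1e6, x$hard_iron[2] * 1e6, x$hard_iron[3] * 1e6,
              x$rms_radius_error))
  invisible(x)
}

#' Apply a calibration model to raw readings
#'
#' Returns `soft_iron %*% (raw - hard_iron)` for each reading.
#'
#' @param readings Data frame with `x`, `y`, `z` columns or n x 3 matrix
#'   (tesla); a single 3-vector is also accepted.
#' @param model A [fit_ellipsoid()] result.
#' @return Calibrated readings with the same shape convention as the input.
#' @export
apply_calibration <- function(readings, model) {
  stopifnot(inherits(model, "calibration_model"))
  vec_in <- is.null(dim(readings)) && !is.data.frame(readings)
  X <- .as_xyz_matrix(readings)
  out <- (X - rep(model$hard_iron, each = nrow(X))) %*% t(model$soft_iron)
  colnames(out) <- c("x", "y", "z")
  if (vec_in && nrow(out) == 1L) return(drop(out))
  if (is.data.frame(readings)) return(tibble::as_tibble(out))
  out
}

#' Simulate hard-/soft-iron distortion (forward model, for testing)
#'
#' Maps true field values `u` to distorted readings `S u + h`. This is the
#' forward counterpart of [fit_ellipsoid()]: fitting the distorted readings
#' of points on a sphere recovers a model that inverts the distortion.
#'
#' @param readings True readings: data frame with `x`, `y`, `z`, n x 3
#'   matrix, or 3-vector (tesla).
#' @param soft_iron 3x3 distortion matrix `S`.
#' @param hard_iron Additive offset 3-vector (tesla).
#' @return Distorted readings, same shape convention as the input.
#' @export
simulate_distortion <- function(readings, soft_iron = diag(3),
                                hard_iron = c(0, 0, 0)) {
  vec_in <- is.null(dim(readings)) && !is.data.frame(readings)
  X <- .as_xyz_matrix(readings)
  out <- X %*% t(soft_iron) + rep(hard_iron, each = nrow(X))
  colnames(out) <- c("x", "y", "z")
  if (vec_in && nrow(out) == 1L) return(drop(out))
  if (is.data.frame(readings)) return(tibble::as_tibble(out))
  out
}

.as_xyz_matrix <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("x", "y", "z") %in% names(x)))
    return(as.matrix(x[, c("x", "y", "z")]))
  }
  if (is.null(dim(x))) {
    stopifnot(length(x) %% 3L == 0L)
    return(matrix(as.numeric(x), ncol = 3L, byrow = TRUE))
  }
  stopifnot(ncol(x) == 3L)
  as.matrix(x)
}
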