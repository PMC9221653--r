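#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a single-frame pose fit
#'
#' @param x A `magtrack_pose_fit`.
#' @param ... Unused.
#' @return One row per parameter: `term`, `estimate` (position in metres,
#'   orientation unitless).
#' @export
tidy.magtrack_pose_fit <- function(x, ...) {
  tibble::tibble(term = c("x", "y", "z", "ox", "oy", "oz"),
                 estimate = c(x$pose$position, x$pose$orientation))
}

#' @rdname tidy.magtrack_pose_fit
#' @return `glance()`: one row with `cost` (T^2), `n_iterations`,
#'   `converged`, `method`.
#' @export
glance.magtrack_pose_fit <- function(x, ...) {
  tibble::tibble(cost = x$cost, n_iterations = x$n_iterations,
                 converged = x$converged, method = x$method)
}

#' Tidy a tracking result
#'
#' @param x A `magtrack_tracking`.
#' @param ... Unused.
#' @return `tidy()`: the per-frame estimate tibble, with per-sample
#'   orientation error (degrees) joined for converged frames when truth was
#'   supplied.
#' @export
tidy.magtrack_tracking <- function(x, ...) {
  out <- x$estimates
  out$orient_err_deg <- NA_real_
  if (length(x$orient_err_deg)) {
    out$orient_err_deg[out$converged] <- x$orient_err_deg
  }
  out
}

#' @rdname tidy.magtrack_tracking
#' @return `glance()`: one row with traveled distances (mm), relative
#'   distance errors (%), mean orientation error (degrees), the secondary
#'   tilt-plane orientation metric and the converged-frame count.
#' @export
glance.magtrack_tracking <- function(x, ...) {
  tibble::tibble(
    dist_est_mm = x$dist_est * 1e3,
    dist_true_mm = x$dist_true * 1e3,
    rel_dist_err_pct = x$rel_dist_err_pct,
    rel_dist_err_nominal_pct = x$rel_dist_err_nominal_pct,
    mean_orient_err_deg = x$mean_orient_err_deg,
    tilt_orient_err_deg = x$tilt_orient_err_deg,
    n_converged = x$n_converged,
    n_samples = nrow(x$estimates))
}

#' Tidy a batch experiment
#'
#' @param x A `magtrack_experiment`.
#' @param ... Unused.
#' @return `tidy()`: the per-run results tibble; `glance()`: the per-magnet
#'   summary (mean and STD of the error metrics).
#' @export
tidy.magtrack_experiment <- function(x, ...) x$runs

#' @rdname tidy.magtrack_experiment
#' @export
glance.magtrack_experiment <- function(x, ...) x$summary

#' Plot a trajectory
#'
#' Top view (x-y) of the path, coloured by height.
#'
#' @param object A `magtrack_trajectory`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.magtrack_trajectory <- function(object, ...) {
  df <- tibble::as_tibble(as.data.frame(object))
  ggplot2::ggplot(df, ggplot2::aes(.data$x * 1e3, .data$y * 1e3,
                                   colour = .data$z * 1e3)) +
    ggplot2::geom_path() +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x [mm]", y = "y [mm]", colour = "z [mm]",
                  title = "Ground-truth trajectory (top view)") +
    ggplot2::theme_minimal()
}

#' Plot tracked vs true path
#'
#' Top view of the estimated polyline over the ground truth (when present).
#'
#' @param object A `magtrack_tracking`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.magtrack_tracking <- function(object, ...) {
  est <- object$estimates
  p <- ggplot2::ggplot() +
    ggplot2::geom_path(
      data = est,
      ggplot2::aes(.data$x * 1e3, .data$y * 1e3, colour = "estimated")) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x [mm]", y = "y [mm]", colour = NULL,
                  title = "Tracked trajectory (top view)") +
    ggplot2::theme_minimal()
  if (!is.null(object$truth)) {
    p <- p + ggplot2::geom_path(
      data = tibble::as_tibble(as.data.frame(object$truth)),
      ggplot2::aes(.data$x * 1e3, .data$y * 1e3, colour = "truth"),
      linetype = "dashed")
  }
  p
}

#' Plot batch-experiment error summaries
#'
#' Mean with one-STD error bars per magnet, for the relative traveled
#' distance error and the mean orientation error (the two headline metrics
#' of the evaluation protocol).
#'
#' @param object A `magtrack_experiment`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.magtrack_experiment <- function(object, ...) {
  s <- object$summary
  long <- dplyr::bind_rows(
    tibble::tibble(magnet = s$magnet, metric = "relative distance error [%]",
                   mean = s$mean_rel_dist_err_pct,
                   sd = s$sd_rel_dist_err_pct),
    tibble::tibble(magnet = s$magnet, metric = "mean orientation error [deg]",
                   mean = s$mean_orient_err_deg,
                   sd = s$sd_orient_err_deg))
  ggplot2::ggplot(long, ggplot2::aes(.data$magnet, .data$mean)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = pmax(0, .data$mean - .data$sd),
                   ymax = .data$mean + .data$sd), width = 0.25) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Tracking errors by magnet (mean +/- STD)") +
    ggplot2::theme_minimal()
}
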