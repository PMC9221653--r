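#' Simulate a measurement dataset along a trajectory
#'
#' Produces one measurement frame per trajectory sample by running the full
#' sensor chain ([simulate_measurement()]) at each ground-truth pose.
#'
#' @param trajectory A [generate_trajectory()] tibble (or any tibble with
#'   `t`, `x`, `y`, `z`, `ox`, `oy`, `oz`).
#' @param array A [sensor_array()].
#' @param magnet A [magnet()].
#' @param model A [sensor_model()].
#' @param geomagnetic Homogeneous background 3-vector (tesla) or `NULL`.
#' @param seed Optional RNG seed (caller's RNG state is restored).
#' @return A wide measurement tibble: `t` plus `s00x` ... columns (tesla),
#'   one row per frame; total clipped raw samples in attribute `n_clipped`.
#' @export
simulate_dataset <- function(trajectory, array, magnet,
                             model = sensor_model(), geomagnetic = NULL,
                             seed = NULL) {
  stopifnot(all(c("t", "x", "y", "z", "ox", "oy", "oz") %in% names(trajectory)))
  .with_seed(seed, {
    n_clipped <- 0L
    rows <- vector("list", nrow(trajectory))
    for (i in seq_len(nrow(trajectory))) {
      p <- pose(position = c(trajectory$x[i], trajectory$y[i], trajectory$z[i]),
                orientation = c(trajectory$ox[i], trajectory$oy[i],
                                trajectory$oz[i]))
      fr <- simulate_measurement(array, magnet, p, model = model,
                                 geomagnetic = geomagnetic,
                                 t = trajectory$t[i])
      n_clipped <- n_clipped + attr(fr, "n_clipped")
      rows[[i]] <- fr
    }
    out <- dplyr::bind_rows(rows)
    attr(out, "n_clipped") <- n_clipped
    out
  })
}

#' Experiment configuration for the 30-run evaluation protocol
#'
#' Bundles every parameter of the batch evaluation: for each magnet, the
#' trajectory is traversed `repeats` times per z-plane and layout
#' orientation, giving `repeats * length(z_planes) * length(layouts)` runs
#' (5 x 3 x 2 = 30 by default). One master seed deterministically spawns a
#' child seed per run, so any individual run can be reproduced in isolation.
#'
#' @param magnets Character vector of magnet catalog ids.
#' @param z_planes Trajectory plane offsets in metres.
#' @param layouts Trajectory layout orientations, subset of `c("x", "y")`.
#' @param repeats Traversals per z-plane/layout combination.
#' @param n_samples Pose samples per traversal.
#' @param duration Traversal time in seconds.
#' @param orientation_mode `"perpendicular"` or `"parallel"` magnetisation
#'   (see [generate_trajectory()]). The 3 and 5 mm magnets support only
#'   perpendicular mode unless `allow_parallel = TRUE` (they cannot be moved
#'   precisely in parallel mode along the physical path).
#' @param speed_jitter Relative jitter of per-step arc-length increments.
#' @param model A [sensor_model()].
#' @param geomagnetic Background 3-vector in tesla.
#' @param array A [sensor_array()].
#' @param control A [localizer_control()].
#' @param seed Master seed (integer).
#' @param allow_parallel Override the parallel-mode restriction for short
#'   magnets.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(magnets = "10x10",
                              z_planes = c(-0.060, 0, 0.060),
                              layouts = c("x", "y"),
                              repeats = 5L,
                              n_samples = 100L,
                              duration = 40,
                              orientation_mode = "perpendicular",
                              speed_jitter = 0.2,
                              model = sensor_model(),
                              geomagnetic = geomagnetic_field(),
                              array = sensor_array(),
                              control = localizer_control(),
                              seed = 1L,
                              allow_parallel = FALSE) {
  stopifnot(length(magnets) >= 1L, repeats >= 1L, n_samples >= 2L,
            all(layouts %in% c("x", "y")),
            orientation_mode %in% c("perpendicular", "parallel"))
  structure(list(magnets = magnets, z_planes = z_planes, layouts = layouts,
                 repeats = as.integer(repeats),
                 n_samples = as.integer(n_samples), duration = duration,
                 orientation_mode = orientation_mode,
                 speed_jitter = speed_jitter, model = model,
                 geomagnetic = geomagnetic, array = array, control = control,
                 seed = as.integer(seed),
                 allow_parallel = isTRUE(allow_parallel)),
            class = "experiment_config")
}

# the run design table: one row per (magnet, z_plane, layout, repeat)
.run_design <- function(config) {
  d <- expand.grid(rep = seq_len(config$repeats),
                   layout = config$layouts,
                   z_plane = config$z_planes,
                   magnet = config$magnets,
                   stringsAsFactors = FALSE)
  d <- d[, c("magnet", "z_plane", "layout", "rep")]
  d$run_id <- seq_len(nrow(d))
  d$seed <- .child_seeds(config$seed, nrow(d))
  tibble::as_tibble(d)
}

#' Run the full batch evaluation protocol
#'
#' Executes the complete simulated protocol: per run, generate a jittered
#' ground-truth trajectory, simulate the measurement dataset through the
#' sensor chain, track the magnet with the differential localizer
#' ([track_dataset()]), and collect traveled-distance and orientation
#' errors. Per magnet, mean and standard deviation over the runs are
#' summarised.
#'
#' @param config An [experiment_config()].
#' @param progress Print one line per completed run.
#' @return An object of class `magtrack_experiment`: list with `runs` (one
#'   row per run: `run_id`, `magnet`, `z_plane`, `layout`, `rep`, `seed`,
#'   `dist_est_mm`, `dist_true_mm`, `rel_dist_err_pct`,
#'   `rel_dist_err_nominal_pct`, `mean_orient_err_deg`,
#'   `tilt_orient_err_deg`, `n_converged`, `n_samples`), `summary` (per
#'   magnet: n_runs, mean/sd of the error metrics) and `config`. `tidy()`,
#'   `glance()` and `autoplot()` methods are provided.
#' @export
run_experiment <- function(config, progress = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  design <- .run_design(config)
  res <- vector("list", nrow(design))
  for (i in seq_len(nrow(design))) {
    row <- design[i, ]
    mag <- magnet_from_catalog(row$magnet)
    if (config$orientation_mode == "parallel" && mag$length < 10e-3 &&
        !config$allow_parallel) {
      stop("parallel magnetisation mode is supported only for the 10 mm ",
           "magnet (set allow_parallel = TRUE to override)", call. = FALSE)
    }
    tr <- .with_seed(row$seed, {
      truth <- generate_trajectory(
        n_samples = config$n_samples, duration = config$duration,
        z_plane = row$z_plane, layout = row$layout,
        orientation_mode = config$orientation_mode,
        speed_jitter = config$speed_jitter)
      ds <- simulate_dataset(truth, config$array, mag, model = config$model,
                             geomagnetic = config$geomagnetic)
      track_dataset(ds, config$array, mag, truth = truth,
                    control = config$control)
    })
    g <- glance(tr)
    res[[i]] <- dplyr::bind_cols(row, g)
    if (progress) {
      message(sprintf("run %d/%d [%s z=%+.0f mm %s#%d]: dist err %.2f%%, orient err %.2f deg",
                      i, nrow(design), row$magnet, row$z_plane * 1e3,
                      row$layout, row$rep, g$rel_dist_err_pct,
                      g$mean_orient_err_deg))
    }
  }
  runs <- dplyr::bind_rows(res)
  summary <- runs |>
    dplyr::group_by(.data$magnet) |>
    dplyr::summarise(
      n_runs = dplyr::n(),
      mean_rel_dist_err_pct = mean(.data$rel_dist_err_pct),
      sd_rel_dist_err_pct = stats::sd(.data$rel_dist_err_pct),
      mean_rel_dist_err_nominal_pct = mean(.data$rel_dist_err_nominal_pct),
      sd_orient_err_deg = stats::sd(.data$mean_orient_err_deg),
      mean_orient_err_deg = mean(.data$mean_orient_err_deg),
      .groups = "drop") |>
    dplyr::relocate("mean_orient_err_deg", .before = "sd_orient_err_deg")
  structure(list(runs = runs, summary = summary, config = config),
            class = "magtrack_experiment")
}

#' @export
print.magtrack_experiment <- function(x, ...) {
  cat(sprintf("<magtrack_experiment> %d run(s), %d magnet(s)\n",
              nrow(x$runs), nrow(x$summary)))
  print(x$summary)
  invisible(x)
}
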