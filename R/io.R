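# CSV and JSON readers/writers. In-memory values are strictly SI (m, T);
# mm and uT appear only in these boundary functions, flagged by unit
# suffixes in the column names.

#' Write / read a measurement table (CSV, uT)
#'
#' Columns: `t` (s) and `s00x_uT` ... `s11z_uT`, one row per frame, header
#' mandatory. Values round-trip at full double precision.
#'
#' @param measurements Wide measurement tibble in tesla (see
#'   [simulate_measurement()]).
#' @param path File path.
#' @return `write_measurements()` returns the input invisibly;
#'   `read_measurements()` returns the measurement tibble in tesla.
#' @export
write_measurements <- function(measurements, path) {
  cols <- grep("^s[0-9]{2}[xyz]$", names(measurements), value = TRUE)
  if (length(cols) == 0L) stop("not a measurement table", call. = FALSE)
  out <- measurements[, c("t", cols)]
  out[cols] <- lapply(out[cols], function(v) v * 1e6)
  names(out) <- c("t", paste0(cols, "_uT"))
  readr::write_csv(out, path)
  invisible(measurements)
}

#' @rdname write_measurements
#' @export
read_measurements <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  cols <- grep("^s[0-9]{2}[xyz]_uT$", names(df), value = TRUE)
  if (!"t" %in% names(df) || length(cols) == 0L || length(cols) %% 3L != 0L) {
    stop("malformed measurement CSV '", path,
         "': need a 't' column and complete sNN{x,y,z}_uT triplets; found ",
         paste(utils::head(names(df), 8), collapse = ", "), call. = FALSE)
  }
  out <- df[, c("t", cols)]
  out[cols] <- lapply(out[cols], function(v) v * 1e-6)
  names(out) <- c("t", sub("_uT$", "", cols))
  tibble::as_tibble(out)
}

#' Write / read a trajectory or pose table (CSV, mm)
#'
#' Columns: `t` (s), `x_mm`, `y_mm`, `z_mm`, `ox`, `oy`, `oz`, plus any
#' extra columns present (e.g. `cost`, `n_iterations`, `converged` for pose
#' estimates), written as-is.
#'
#' @param trajectory Tibble with `t`, `x`, `y`, `z` (m), `ox`, `oy`, `oz`.
#' @param path File path.
#' @return `write_trajectory()` returns the input invisibly;
#'   `read_trajectory()` returns a tibble in metres.
#' @export
write_trajectory <- function(trajectory, path) {
  stopifnot(all(c("t", "x", "y", "z", "ox", "oy", "oz") %in% names(trajectory)))
  out <- tibble::as_tibble(as.data.frame(trajectory))
  out$x <- out$x * 1e3; out$y <- out$y * 1e3; out$z <- out$z * 1e3
  names(out)[match(c("x", "y", "z"), names(out))] <-
    c("x_mm", "y_mm", "z_mm")
  readr::write_csv(out, path)
  invisible(trajectory)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("t", "x_mm", "y_mm", "z_mm", "ox", "oy", "oz")
  if (!all(need %in% names(df))) {
    stop("malformed trajectory CSV '", path, "': missing column(s) ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  }
  df$x_mm <- df$x_mm * 1e-3; df$y_mm <- df$y_mm * 1e-3
  df$z_mm <- df$z_mm * 1e-3
  names(df)[match(c("x_mm", "y_mm", "z_mm"), names(df))] <- c("x", "y", "z")
  tibble::as_tibble(df)
}

#' Write / read a sensor-array geometry file (JSON, mm)
#'
#' Stores positions (mm), per-sensor orientation matrices, the pairing list
#' (1-based sensor indices) and the builder parameters needed to
#' reconstruct the array.
#'
#' @param array A [sensor_array()].
#' @param path File path.
#' @return `write_sensor_array()` returns the input invisibly;
#'   `read_sensor_array()` returns a `sensor_array`.
#' @export
write_sensor_array <- function(array, path) {
  stopifnot(inherits(array, "sensor_array"))
  jsonlite::write_json(
    list(positions_mm = unname(array$positions * 1e3),
         orientations = lapply(array$orientations, unname),
         pairs = unname(array$pairs),
         semi_axes_mm = array$semi_axes * 1e3,
         ring_z_mm = array$ring_z * 1e3,
         angles_deg = array$angles_deg),
    path, digits = NA, auto_unbox = FALSE)
  invisible(array)
}

#' @rdname write_sensor_array
#' @export
read_sensor_array <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("positions_mm", "pairs", "semi_axes_mm", "ring_z_mm")
  if (!all(need %in% names(j))) {
    stop("malformed array JSON '", path, "': missing ",
         paste(setdiff(need, names(j)), collapse = ", "), call. = FALSE)
  }
  orientations <- if (is.null(j$orientations)) NULL else
    lapply(seq_len(dim(j$orientations)[1]),
           function(i) matrix(j$orientations[i, , ], 3L, 3L))
  arr <- sensor_array(semi_axes = j$semi_axes_mm * 1e-3,
                      ring_z = j$ring_z_mm * 1e-3,
                      angles_deg = if (is.null(j$angles_deg))
                        c(0, 90, 180, 270) else j$angles_deg,
                      pairing = matrix(as.integer(j$pairs), ncol = 2L),
                      orientations = orientations)
  # trust the stored positions over the parametric rebuild
  pos <- matrix(as.numeric(j$positions_mm), ncol = 3L) * 1e-3
  dimnames(pos) <- dimnames(arr$positions)
  arr$positions <- pos
  arr
}

#' Write / read calibration models (JSON, uT)
#'
#' Stores one [fit_ellipsoid()] model per named sensor (use the name
#' `"global"` for a single array-wide model).
#'
#' @param models A named list of `calibration_model` objects.
#' @param path File path.
#' @return `write_calibration()` returns the input invisibly;
#'   `read_calibration()` returns the named list of models.
#' @export
write_calibration <- function(models, path) {
  if (inherits(models, "calibration_model")) models <- list(global = models)
  stopifnot(length(names(models)) == length(models))
  jsonlite::write_json(
    lapply(models, function(m) list(
      soft_iron = unname(m$soft_iron),
      hard_iron_uT = m$hard_iron * 1e6,
      reference_radius_uT = m$reference_radius * 1e6)),
    path, digits = NA, auto_unbox = FALSE)
  invisible(models)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(j, function(m) {
    structure(list(soft_iron = matrix(as.numeric(m$soft_iron), 3L, 3L),
                   hard_iron = as.numeric(m$hard_iron_uT) * 1e-6,
                   reference_radius = as.numeric(m$reference_radius_uT) * 1e-6,
                   rms_radius_error = NA_real_),
              class = "calibration_model")
  })
}

# apply stored calibration models to a wide measurement table; a single
# "global" model is applied to every sensor, otherwise models are matched
# to sensors by name (s00, s01, ...)
.calibrate_measurements <- function(measurements, models) {
  cols <- grep("^s[0-9]{2}[xyz]$", names(measurements), value = TRUE)
  sensors <- unique(substr(cols, 1L, 3L))
  out <- measurements
  for (s in sensors) {
    m <- if (length(models) == 1L && identical(names(models), "global"))
      models[["global"]] else models[[s]]
    if (is.null(m)) stop("no calibration model for sensor ", s, call. = FALSE)
    triplet <- paste0(s, c("x", "y", "z"))
    X <- as.matrix(measurements[, triplet])
    colnames(X) <- c("x", "y", "z")
    out[, triplet] <- apply_calibration(X, m)
  }
  out
}

#' Read an experiment configuration file (YAML or JSON)
#'
#' Boundary units: mm, uT, nT, seconds. Recognised fields: `magnets`,
#' `z_planes_mm`, `layouts`, `repeats`, `n_samples`, `duration_s`,
#' `orientation_mode`, `speed_jitter`, `noise_sigma_uT`, `lsb_nT`,
#' `n_average`, `full_scale_uT`, `geomagnetic_uT` (3-vector), `pairing`,
#' `seed`, `allow_parallel`. Missing fields fall back to the
#' [experiment_config()] defaults.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return An [experiment_config()].
#' @export
read_experiment_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  pick <- function(name, default) if (is.null(cfg[[name]])) default else cfg[[name]]
  dm <- sensor_model()
  model <- sensor_model(
    full_scale = pick("full_scale_uT", dm$full_scale * 1e6) * 1e-6,
    lsb = pick("lsb_nT", dm$lsb * 1e9) * 1e-9,
    noise_sigma = pick("noise_sigma_uT", dm$noise_sigma * 1e6) * 1e-6,
    n_average = pick("n_average", dm$n_average))
  geo <- pick("geomagnetic_uT", geomagnetic_field() * 1e6)
  arr <- sensor_array(pairing = pick("pairing", "all"))
  experiment_config(
    magnets = pick("magnets", "10x10"),
    z_planes = pick("z_planes_mm", c(-60, 0, 60)) * 1e-3,
    layouts = pick("layouts", c("x", "y")),
    repeats = pick("repeats", 5L),
    n_samples = pick("n_samples", 100L),
    duration = pick("duration_s", 40),
    orientation_mode = pick("orientation_mode", "perpendicular"),
    speed_jitter = pick("speed_jitter", 0.2),
    model = model,
    geomagnetic = as.numeric(geo) * 1e-6,
    array = arr,
    seed = pick("seed", 1L),
    allow_parallel = pick("allow_parallel", FALSE))
}

#' Write batch-experiment results to a directory
#'
#' Writes `runs.csv` (one row per run, mm/percent/degree units),
#' `summary.csv` (per-magnet mean and STD) and `manifest.json` (config
#' echo, seed, package version) under `dir`.
#'
#' @param experiment A [run_experiment()] result.
#' @param dir Output directory (created if missing).
#' @return The input, invisibly.
#' @export
write_experiment <- function(experiment, dir) {
  stopifnot(inherits(experiment, "magtrack_experiment"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  runs <- experiment$runs
  runs$z_plane_mm <- runs$z_plane * 1e3
  runs$z_plane <- NULL
  readr::write_csv(runs, file.path(dir, "runs.csv"))
  readr::write_csv(experiment$summary, file.path(dir, "summary.csv"))
  cfg <- experiment$config
  jsonlite::write_json(
    list(package = "magtrack",
         version = as.character(utils::packageVersion("magtrack")),
         seed = cfg$seed, magnets = cfg$magnets,
         z_planes_mm = cfg$z_planes * 1e3, layouts = cfg$layouts,
         repeats = cfg$repeats, n_samples = cfg$n_samples,
         duration_s = cfg$duration,
         orientation_mode = cfg$orientation_mode,
         speed_jitter = cfg$speed_jitter,
         noise_sigma_uT = cfg$model$noise_sigma * 1e6,
         lsb_nT = cfg$model$lsb * 1e9, n_average = cfg$model$n_average,
         full_scale_uT = cfg$model$full_scale * 1e6,
         geomagnetic_uT = cfg$geomagnetic * 1e6),
    file.path(dir, "manifest.json"), digits = NA, auto_unbox = TRUE)
  invisible(experiment)
}
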