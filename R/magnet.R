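#' Cylindrical permanent magnet
#'
#' Describes an axially magnetised cylindrical permanent magnet. The single
#' strength parameter of the dipole model is the magnetic moment
#' \eqn{m = M_0 \pi k^2 l} (magnetisation times cylinder volume), where `k` is
#' the cylinder radius and `l` its length. All quantities are SI: metres and
#' A/m in, A m^2 out.
#'
#' @param diameter Cylinder diameter in metres (must be > 0).
#' @param length Cylinder length in metres (must be > 0).
#' @param magnetisation Axial magnetisation in A/m (must be > 0). The default
#'   1150 kA/m is typical of sintered neodymium N52 material.
#' @param id Optional catalog identifier carried along for reporting.
#'
#' @return An object of class `magnet`: a list with fields `radius`, `length`,
#'   `magnetisation`, `moment` and `id`.
#' @examples
#' m <- magnet(diameter = 10e-3, length = 10e-3)
#' m$moment # ~0.903 A m^2
#' @export
magnet <- function(diameter = 10e-3, length = 10e-3, magnetisation = 1150e3,
                   id = NULL) {
  stopifnot(is.numeric(diameter), length(diameter) == 1L, diameter > 0,
            is.numeric(length), base::length(length) == 1L, length > 0,
            is.numeric(magnetisation), base::length(magnetisation) == 1L,
            magnetisation > 0)
  radius <- diameter / 2
  structure(
    list(radius = radius, length = length, magnetisation = magnetisation,
         moment = magnetisation * pi * radius^2 * length,
         id = if (is.null(id)) sprintf("%gx%g", length * 1e3, diameter * 1e3)
              else id),
    class = "magnet"
  )
}

#' @export
print.magnet <- function(x, ...) {
  cat(sprintf(
    "<magnet %s> cylinder %.1f mm (L) x %.1f mm (D), M0 = %.0f kA/m, moment = %.4f A m^2\n",
    x$id, x$length * 1e3, 2 * x$radius * 1e3, x$magnetisation / 1e3, x$moment))
  invisible(x)
}

#' Magnet catalog
#'
#' Reads the bundled catalog of cylindrical N52 magnets (`10x10`, `5x10`,
#' `3x10`: length x diameter in mm, 1150 kA/m axial magnetisation) or a
#' user-supplied JSON catalog of the same layout.
#'
#' @param path Path to a catalog JSON file; defaults to the bundled catalog.
#' @return A tibble with columns `id`, `diameter_mm`, `length_mm`,
#'   `magnetisation_kA_per_m`.
#' @seealso [magnet_from_catalog()]
#' @export
magnet_catalog <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "magnet_catalog.json", package = "magtrack",
                        mustWork = TRUE)
  }
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  tibble::tibble(
    id = names(raw),
    diameter_mm = unname(purrr::map_dbl(raw, "diameter_mm")),
    length_mm = unname(purrr::map_dbl(raw, "length_mm")),
    magnetisation_kA_per_m = unname(purrr::map_dbl(raw, "magnetisation_kA_per_m"))
  )
}

#' Build a magnet from a catalog entry
#'
#' @param id Catalog identifier such as `"10x10"`, `"5x10"` or `"3x10"`.
#' @inheritParams magnet_catalog
#' @return A [magnet()] object.
#' @export
magnet_from_catalog <- function(id, path = NULL) {
  cat_tbl <- magnet_catalog(path)
  row <- cat_tbl[cat_tbl$id == id, ]
  if (nrow(row) != 1L) {
    stop("unknown magnet id '", id, "'; catalog has: ",
         paste(cat_tbl$id, collapse = ", "), call. = FALSE)
  }
  magnet(diameter = row$diameter_mm * 1e-3, length = row$length_mm * 1e-3,
         magnetisation = row$magnetisation_kA_per_m * 1e3, id = id)
}

#' Magnet pose
#'
#' Position and orientation of the magnet at one instant. The orientation is
#' the unit vector along the magnetisation axis; a non-unit input vector is
#' normalised.
#'
#' @param position Numeric 3-vector, metres.
#' @param orientation Numeric 3-vector, any nonzero length; normalised.
#' @return An object of class `pose`: list with `position` and unit
#'   `orientation`.
#' @export
pose <- function(position = c(0, 0, 0), orientation = c(0, 0, 1)) {
  stopifnot(is.numeric(position), length(position) == 3L,
            all(is.finite(position)),
            is.numeric(orientation), length(orientation) == 3L,
            all(is.finite(orientation)))
  n <- sqrt(sum(orientation^2))
  if (n == 0) stop("orientation vector must be nonzero", call. = FALSE)
  structure(list(position = as.numeric(position),
                 orientation = as.numeric(orientation) / n),
            class = "pose")
}

#' @export
print.pose <- function(x, ...) {
  cat(sprintf("<pose> position (%.2f, %.2f, %.2f) mm, orientation (%.3f, %.3f, %.3f)\n",
              x$position[1] * 1e3, x$position[2] * 1e3, x$position[3] * 1e3,
              x$orientation[1], x$orientation[2], x$orientation[3]))
  invisible(x)
}

#' Homogeneous geomagnetic background field
#'
#' The geomagnetic flux density is modelled as spatially homogeneous over the
#' sensor-array workspace (a few hundred mm). The default is a 48 uT vector
#' with a mid-latitude-like downward inclination.
#'
#' @param vector Optional explicit 3-vector in tesla; overrides
#'   `magnitude`/`direction`.
#' @param magnitude Field magnitude in tesla (default 48e-6).
#' @param direction Direction 3-vector (normalised internally).
#' @return Numeric 3-vector in tesla.
#' @export
geomagnetic_field <- function(vector = NULL, magnitude = 48e-6,
                              direction = c(1, 1, -2)) {
  if (!is.null(vector)) {
    stopifnot(is.numeric(vector), length(vector) == 3L, all(is.finite(vector)))
    return(as.numeric(vector))
  }
  stopifnot(is.numeric(magnitude), length(magnitude) == 1L,
            is.finite(magnitude), magnitude >= 0)
  d <- as.numeric(direction)
  stopifnot(length(d) == 3L, all(is.finite(d)), any(d != 0))
  magnitude * d / sqrt(sum(d^2))
}
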