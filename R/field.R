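#' Magnetic flux density of a magnet under the point-dipole model
#'
#' Evaluates the standard magnetic dipole model at one or more observation
#' points: with \eqn{R} the vector from the magnet centre to the observation
#' point, \eqn{\hat R = R/\|R\|} and unit orientation \eqn{o},
#' \deqn{B = \frac{\mu_0 m}{4\pi}\left(\frac{3\langle o,\hat R\rangle \hat R - o}{\|R\|^3}\right),}
#' where \eqn{m = M_0 \pi k^2 l} is the magnet moment. The relative
#' permeability of human tissue is taken as 1 (not configurable), so only
#' \eqn{\mu_0 = 4\pi\times 10^{-7}} H/m enters. The approximation is valid
#' when the observation distance is much larger than the magnet's largest
#' dimension; [finite_volume_field()] quantifies the deviation.
#'
#' @param magnet A [magnet()].
#' @param magnet_pose A [pose()].
#' @param points Observation point(s), metres: a numeric 3-vector or an
#'   n x 3 matrix.
#' @return Flux density in tesla: an n x 3 matrix (or 3-vector when a single
#'   point was given as a vector).
#' @examples
#' m <- magnet() # 10 x 10 mm N52
#' dipole_field(m, pose(orientation = c(0, 0, 1)), c(0, 0, 0.1)) # ~180.6 uT axial
#' @export
dipole_field <- function(magnet, magnet_pose, points) {
  stopifnot(inherits(magnet, "magnet"), inherits(magnet_pose, "pose"))
  vec_in <- is.null(dim(points))
  pts <- if (vec_in) matrix(as.numeric(points), ncol = 3L) else
    matrix(as.numeric(points), ncol = 3L)
  B <- .dipole_field_m(magnet$moment, magnet_pose$position,
                       magnet_pose$orientation, pts)
  if (vec_in && nrow(B) == 1L) drop(B) else B
}

# core kernel: moment (A m^2), position, unit orientation, points n x 3
.dipole_field_m <- function(moment, position, orientation, pts) {
  R <- pts - rep(position, each = nrow(pts))
  r2 <- rowSums(R * R)
  if (any(r2 == 0)) {
    stop("singular dipole evaluation: observation point coincides with the magnet centre",
         call. = FALSE)
  }
  odotR <- as.numeric(R %*% orientation)
  inv_r5 <- r2^(-2.5)
  inv_r3 <- r2^(-1.5)
  pref <- 1e-7 * moment # mu0/(4 pi) = 1e-7
  pref * (3 * odotR * inv_r5 * R -
            tcrossprod(inv_r3, orientation))
}

#' Finite-volume field of a cylindrical magnet (validation oracle)
#'
#' Numerically integrates the dipole kernel over the magnet volume: the
#' cylinder is partitioned into equal-volume cells (equal-volume radial
#' shells x uniform angular sectors x uniform axial slabs), each carrying
#' moment \eqn{M_0\,dV} along the magnet axis, and the cell contributions are
#' summed. With `n_subdivisions = 1` this collapses to [dipole_field()]
#' exactly. Used to validate the point-dipole approximation in the far field;
#' it is not meant for production localisation.
#'
#' @inheritParams dipole_field
#' @param n_subdivisions Requested minimum number of cells (>= 1); the actual
#'   grid uses the smallest balanced factorisation at least this large.
#' @return Flux density in tesla, same shape convention as [dipole_field()].
#' @export
finite_volume_field <- function(magnet, magnet_pose, points, n_subdivisions = 1L) {
  stopifnot(inherits(magnet, "magnet"), inherits(magnet_pose, "pose"),
            is.numeric(n_subdivisions), length(n_subdivisions) == 1L,
            n_subdivisions >= 1)
  vec_in <- is.null(dim(points))
  pts <- matrix(as.numeric(points), ncol = 3L)
  n <- as.integer(ceiling(n_subdivisions))
  o <- magnet_pose$orientation
  if (n == 1L) {
    B <- .dipole_field_m(magnet$moment, magnet_pose$position, o, pts)
    return(if (vec_in && nrow(B) == 1L) drop(B) else B)
  }

  # balanced grid: aim for roughly cubic cells given aspect ratio l/(2k)
  aspect <- magnet$length / (2 * magnet$radius)
  n_z <- max(1L, as.integer(round((n * aspect^2)^(1 / 3))))
  n_r <- max(1L, as.integer(round(sqrt(n / n_z) / sqrt(pi))))
  n_phi <- max(1L, as.integer(ceiling(n / (n_z * n_r))))

  # equal-volume radial shells: boundaries r_i = k * sqrt(i / n_r);
  # area centroid radius of each annular sector
  rb <- magnet$radius * sqrt(seq(0L, n_r) / n_r)
  r_c <- (2 / 3) * (rb[-1]^3 - rb[-(n_r + 1)]^3) / (rb[-1]^2 - rb[-(n_r + 1)]^2)
  phi <- (seq_len(n_phi) - 0.5) * 2 * pi / n_phi
  z_c <- (seq_len(n_z) - 0.5) * magnet$length / n_z - magnet$length / 2
  dV <- pi * magnet$radius^2 * magnet$length / (n_r * n_phi * n_z)

  # local orthonormal frame with e3 along the magnet axis
  e3 <- o
  seed <- if (abs(e3[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- seed - sum(seed * e3) * e3
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(e3[2] * e1[3] - e3[3] * e1[2],
          e3[3] * e1[1] - e3[1] * e1[3],
          e3[1] * e1[2] - e3[2] * e1[1])

  grid <- expand.grid(r = r_c, phi = phi, z = z_c)
  centres <- outer(grid$r * cos(grid$phi), e1) +
    outer(grid$r * sin(grid$phi), e2) +
    outer(grid$z, e3)
  centres <- centres + rep(magnet_pose$position, each = nrow(centres))

  m_cell <- magnet$magnetisation * dV
  B <- matrix(0, nrow(pts), 3L)
  for (i in seq_len(nrow(centres))) {
    B <- B + .dipole_field_m(m_cell, centres[i, ], o, pts)
  }
  if (vec_in && nrow(B) == 1L) drop(B) else B
}

#' Total field: magnet dipole plus homogeneous geomagnetic background
#'
#' Superposition of [dipole_field()] and a homogeneous background vector.
#'
#' @inheritParams dipole_field
#' @param geomagnetic Background 3-vector in tesla (see [geomagnetic_field()]);
#'   `NULL` means zero background.
#' @return Flux density in tesla, same shape convention as [dipole_field()].
#' @export
total_field <- function(magnet, magnet_pose, points, geomagnetic = NULL) {
  B <- dipole_field(magnet, magnet_pose, points)
  if (is.null(geomagnetic)) return(B)
  g <- geomagnetic_field(vector = geomagnetic)
  if (is.null(dim(B))) B + g else B + rep(g, each = nrow(B))
}
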