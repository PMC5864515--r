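# Synthetic source-space geometry with exact left/right mirror symmetry.

#' Generate a synthetic bilateral source space
#'
#' Builds a two-hemisphere vertex grid standing in for a downsampled cortical
#' surface. Vertices `1..n` form the left hemisphere (`x < 0`); vertices
#' `n+1..2n` are their exact x-negated mirror twins, so the mirror map is an
#' involution with zero matching error by construction.
#'
#' Two geometries are available: `"two-lobe"` (default) places each
#' hemisphere on an ellipsoidal lobe offset from the midline, and
#' `"sphere-patch"` places each hemisphere on a spherical cap whose radius
#' shrinks smoothly towards the cap rim (so the rim is "deeper", giving the
#' leadfield a depth-sensitivity gradient). Registered-sphere coordinates (the unit-sphere positions the
#' lattice was drawn from, identical for mirror twins) are stored for
#' principal-axis splitting of parcels.
#'
#' @param n_vertices_per_hemisphere Number of vertices per hemisphere (>= 8).
#' @param geometry `"two-lobe"` or `"sphere-patch"`.
#' @param seed Integer seed; the same seed reproduces the space exactly.
#' @param jitter Fractional positional jitter applied (mirror-symmetrically)
#'   to the lattice, giving distinct spaces for distinct seeds.
#' @param normal_jitter Amplitude of the mirror-symmetric perturbation of
#'   the vertex normals, emulating cortical folding: orientation varies
#'   little between immediate neighbours (same gyral bank) but decorrelates
#'   across the surface, which is what lets orientation-sensitive leadfields
#'   distinguish nearby patches. Set to 0 for a smooth surface.
#' @param normal_corr Correlation length (mm) of the orientation field.
#' @param k_neighbors Neighbourhood size of the symmetric k-nearest-neighbour
#'   vertex adjacency (built within hemisphere).
#' @return An object of class `ctf_source_space` with fields `coords` (mm),
#'   `normals` (unit outward), `hemisphere` (`"lh"`/`"rh"`), `sphere_coords`,
#'   `mirror_map`, `adjacency`, `n_vertices`.
#' @export
make_source_space <- function(n_vertices_per_hemisphere,
                              geometry = c("two-lobe", "sphere-patch"),
                              seed = 1L, jitter = 0.02, normal_jitter = 1.2,
                              normal_corr = 10, k_neighbors = 6L) {
  n <- n_vertices_per_hemisphere
  if (!is.numeric(n) || length(n) != 1L || n < 8 || n != round(n)) {
    stop("n_vertices_per_hemisphere must be an integer >= 8")
  }
  n <- as.integer(n)
  geometry <- match.arg(geometry)

  with_seed(seed, {
    if (geometry == "sphere-patch") {
      cap <- pi / 3
      u <- fibonacci_sphere(n, cap = cap)              # unit cap around +z
      u <- u + matrix(stats::rnorm(3 * n, sd = jitter), n, 3)
      u <- u / sqrt(rowSums(u^2))
      u <- rotate_pole(u, c(-1, 0, 0))                 # cap faces -x (left)
      theta <- acos(pmin(1, pmax(-1, -u[, 1])))        # angle from cap centre
      radius <- 80 - 20 * (theta / cap)^2              # rim sits deeper
      lh <- u * radius
      lh_norm <- u
      sphere_lh <- u
    } else {
      u <- fibonacci_sphere(n)
      u <- u + matrix(stats::rnorm(3 * n, sd = jitter), n, 3)
      u <- u / sqrt(rowSums(u^2))
      axes <- c(45, 65, 55)
      centre <- c(-30, 0, 0)
      lh <- sweep(u %*% diag(axes), 2, centre, `+`)
      nrm <- u %*% diag(1 / axes)
      lh_norm <- nrm / sqrt(rowSums(nrm^2))
      sphere_lh <- u
    }
    if (normal_jitter > 0) {
      # smooth orientation field: neighbouring vertices share their local
      # fold, but orientation decorrelates across the surface
      d2 <- as.matrix(stats::dist(lh))^2
      K <- exp(-d2 / (2 * normal_corr^2))
      field <- K %*% matrix(stats::rnorm(3 * n), n, 3)
      field <- field / stats::sd(field)
      lh_norm <- lh_norm + normal_jitter * field
      lh_norm <- lh_norm / sqrt(rowSums(lh_norm^2))
      dimnames(lh_norm) <- NULL
    }
    # keep the left hemisphere clear of the midline: real source spaces
    # exclude the medial wall, so homologous sources are never closer than
    # about twice this margin
    lh[, 1] <- pmin(lh[, 1], -10)
    rh <- lh
    rh[, 1] <- -rh[, 1]
    rh_norm <- lh_norm
    rh_norm[, 1] <- -rh_norm[, 1]
    sphere_rh <- sphere_lh                              # registered sphere is shared

    coords <- rbind(lh, rh)
    normals <- rbind(lh_norm, rh_norm)
    hemisphere <- rep(c("lh", "rh"), each = n)
    mirror_map <- c(seq_len(n) + n, seq_len(n))
    adjacency <- knn_adjacency(coords, k = k_neighbors, group = hemisphere)

    structure(
      list(coords = coords, normals = normals, hemisphere = hemisphere,
           sphere_coords = rbind(sphere_lh, sphere_rh),
           mirror_map = as.integer(mirror_map), adjacency = adjacency,
           n_vertices = 2L * n, geometry = geometry, seed = seed),
      class = "ctf_source_space")
  })
}

#' @export
print.ctf_source_space <- function(x, ...) {
  cat("Synthetic source space (", x$geometry, "): ", x$n_vertices,
      " vertices (", x$n_vertices / 2L, " per hemisphere)\n", sep = "")
  invisible(x)
}

#' Generate a synthetic sensor array
#'
#' Sensors on a sphere of radius `radius` (mm) around the head origin,
#' strictly outside the source surface.
#'
#' @param n_sensors Number of sensors (>= 2).
#' @param radius Sensor shell radius in mm.
#' @param cap Half-angle (radians) of the spherical cap the sensors cover,
#'   measured from the +z pole. The default (2*pi/3) emulates a helmet that
#'   samples the upper head well but leaves inferior regions poorly seen —
#'   the geometry behind depth-dependent sensitivity loss.
#' @return An object of class `ctf_sensor_array` with `positions`, `kinds`,
#'   `n_sensors`.
#' @export
make_sensors <- function(n_sensors = 64L, radius = 110, cap = 2 * pi / 3) {
  if (n_sensors < 2) stop("n_sensors must be >= 2")
  n_sensors <- as.integer(n_sensors)
  if (n_sensors %% 2L != 0L) stop("n_sensors must be even (the array is built left/right symmetric)")
  # half the sensors from a cap lattice, mirrored across the midline so the
  # array has the same exact x-mirror symmetry as the source space
  half <- fibonacci_sphere(n_sensors %/% 2L, cap = cap)
  half[, 1] <- abs(half[, 1])
  mirror <- half
  mirror[, 1] <- -mirror[, 1]
  pos <- rbind(half, mirror) * radius
  structure(list(positions = pos, kinds = rep("meg", n_sensors),
                 n_sensors = n_sensors, radius = radius,
                 cap = cap),
            class = "ctf_sensor_array")
}

#' @export
print.ctf_sensor_array <- function(x, ...) {
  cat("Sensor array:", x$n_sensors, "sensors at radius", x$radius, "mm\n")
  invisible(x)
}
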