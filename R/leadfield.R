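# Synthetic leadfields and noise covariances.

#' Construct a leadfield object from an explicit gain matrix
#'
#' Wraps an `N_ch x N_s` gain matrix `G` together with its geometry. Used
#' both by the synthetic generators and to inject hand-built gain matrices
#' (e.g. a square invertible `G` for identity-limit checks).
#'
#' @param G Gain matrix, channels x sources.
#' @param space A `ctf_source_space` (optional for pure matrix work).
#' @param sensors A `ctf_sensor_array` (optional).
#' @return An object of class `ctf_leadfield`.
#' @export
leadfield <- function(G, space = NULL, sensors = NULL) {
  G <- as.matrix(G)
  if (!all(is.finite(G))) stop("leadfield entries must be finite")
  if (any(apply(abs(G), 1, max) == 0)) stop("leadfield has an all-zero sensor row")
  if (!is.null(space) && ncol(G) != space$n_vertices) {
    stop("ncol(G) must equal the number of source vertices")
  }
  structure(list(G = G, space = space, sensors = sensors,
                 n_channels = nrow(G), n_sources = ncol(G)),
            class = "ctf_leadfield")
}

#' @export
print.ctf_leadfield <- function(x, ...) {
  cat("Leadfield:", x$n_channels, "channels x", x$n_sources, "sources\n")
  invisible(x)
}

#' Generate a synthetic leadfield
#'
#' Each sensor sees a smooth spatial neighbourhood of the source surface.
#' `"dipole-in-sphere"` (default) uses the quasi-static potential of a
#' current dipole oriented along the vertex normal in a homogeneous medium,
#' so gains carry the orientation structure of the surface;
#' `"gaussian-spread"` uses a purely distance-based Gaussian sensitivity
#' profile of width `spread` mm. Both profiles decay with distance, so
#' deeper sources (larger distance from the sensor shell) produce smaller
#' gain-column norms — the sensitivity problem that makes some cortical
#' patches hard to see.
#'
#' @param space A `ctf_source_space`.
#' @param sensors A `ctf_sensor_array`; all sensors must lie outside the
#'   source surface.
#' @param model `"dipole-in-sphere"` (default) or `"gaussian-spread"`.
#' @param spread Gaussian profile width in mm (gaussian-spread model).
#' @param depth_profile Optional function of source depth (mm below the
#'   sensor shell) returning a per-source gain multiplier.
#' @return A `ctf_leadfield`.
#' @export
make_leadfield <- function(space, sensors,
                           model = c("dipole-in-sphere", "gaussian-spread"),
                           spread = 30, depth_profile = NULL) {
  stopifnot(inherits(space, "ctf_source_space"),
            inherits(sensors, "ctf_sensor_array"))
  model <- match.arg(model)
  src_r <- sqrt(rowSums(space$coords^2))
  sen_r <- sqrt(rowSums(sensors$positions^2))
  if (min(sen_r) <= max(src_r)) {
    stop("geometry error: sensors must lie outside the source surface")
  }
  nch <- sensors$n_sensors
  ns <- space$n_vertices
  G <- matrix(0, nch, ns)
  for (c_ in seq_len(nch)) {
    rel <- sweep(space$coords, 2, sensors$positions[c_, ], `-`)  # src -> sensor? sensor - src below
    rel <- -rel                                                  # vector source -> sensor
    d <- sqrt(rowSums(rel^2))
    if (model == "gaussian-spread") {
      G[c_, ] <- exp(-d^2 / (2 * spread^2))
    } else {
      # dipole potential ~ p . r_hat / |r|^2 with p = vertex normal
      G[c_, ] <- rowSums(space$normals * rel) / d^3 * 1e4
    }
  }
  if (!is.null(depth_profile)) {
    depth <- min(sen_r) - src_r
    G <- sweep(G, 2, vapply(depth, depth_profile, numeric(1)), `*`)
  }
  lf <- leadfield(G, space, sensors)
  lf$model <- model
  lf$spread <- spread
  lf
}

#' Generate a synthetic noise covariance
#'
#' Empirical covariance of white Gaussian baseline noise, symmetrized and
#' diagonally loaded by a fraction of its mean diagonal power.
#'
#' @param n_channels Number of channels (or a `ctf_sensor_array`).
#' @param n_samples Number of baseline noise samples for the empirical
#'   covariance.
#' @param loading Diagonal-loading fraction (default 0.05).
#' @param seed Integer seed.
#' @return An object of class `ctf_noisecov` with fields `C` and `loading`.
#' @export
make_noise_cov <- function(n_channels, n_samples = 500L, loading = 0.05,
                           seed = 1L) {
  if (inherits(n_channels, "ctf_sensor_array")) n_channels <- n_channels$n_sensors
  stopifnot(n_channels >= 2, n_samples > n_channels)
  with_seed(seed, {
    x <- matrix(stats::rnorm(n_samples * n_channels), n_samples, n_channels)
    C <- stats::cov(x)
    C <- (C + t(C)) / 2
    C <- C + diag(loading * mean(diag(C)), n_channels)
    structure(list(C = C, loading = loading), class = "ctf_noisecov")
  })
}

#' @export
print.ctf_noisecov <- function(x, ...) {
  cat("Noise covariance:", nrow(x$C), "channels, diagonal loading",
      x$loading, "\n")
  invisible(x)
}
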