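# Multi-subject synthetic forward models and subject->average vertex mappings.

#' Generate a multi-subject synthetic forward-model set
#'
#' Emulates a group study: every subject shares the average source space
#' topology but has a smoothly perturbed leadfield, an individually drawn
#' noise covariance and a subject-to-average vertex mapping. The mapping is a
#' mirror-consistent permutation (the mirror of a mapped vertex is the mapped
#' mirror), standing in for surface morphing between an individual brain and
#' the average brain. With `perturbation_scale = 0` all subjects are
#' identical copies of the base model and the mappings are the identity.
#'
#' The leadfield perturbation multiplies base gains by `1 + s * f` where `f`
#' is a spatially smoothed unit-variance Gaussian field over sources (plus an
#' independent per-channel gain factor), so perturbations are smooth in
#' source position rather than white.
#'
#' @param n_subjects Number of subjects (>= 1); group designs of around 17
#'   subjects are typical.
#' @param space Average `ctf_source_space` shared by the group.
#' @param sensors `ctf_sensor_array`.
#' @param perturbation_scale Fractional gain perturbation in `[0, 0.5]`.
#' @param seed Integer seed.
#' @param lf_args List of extra arguments for [make_leadfield()].
#' @param cov_samples Baseline samples per subject for [make_noise_cov()].
#' @return An object of class `ctf_subject_set`: list with `subjects` (each a
#'   list of `leadfield`, `cov`, `mapping`), `space`, `sensors`,
#'   `n_subjects`. `mapping[j]` is the average-space vertex corresponding to
#'   subject vertex `j`.
#' @export
make_subject_set <- function(n_subjects = 17L, space, sensors,
                             perturbation_scale = 0.1, seed = 1L,
                             lf_args = list(), cov_samples = 500L) {
  stopifnot(n_subjects >= 1)
  if (perturbation_scale < 0 || perturbation_scale > 0.5) {
    stop("perturbation_scale must be in [0, 0.5]")
  }
  base_lf <- do.call(make_leadfield, c(list(space = space, sensors = sensors),
                                       lf_args))
  n <- space$n_vertices
  nh <- n / 2L
  # smoothing kernel over source positions (for smooth gain fields)
  d2 <- as.matrix(stats::dist(space$coords))^2
  K <- exp(-d2 / (2 * 20^2))
  K <- K / rowSums(K)

  subjects <- with_seed(seed, lapply(seq_len(n_subjects), function(s) {
    if (perturbation_scale == 0) {
      mapping <- seq_len(n)
      G <- base_lf$G
    } else {
      perm_lh <- sample.int(nh)
      mapping <- c(perm_lh, space$mirror_map[perm_lh])  # mirror-consistent
      field <- as.numeric(K %*% stats::rnorm(n))
      field <- field / stats::sd(field)
      chan <- 1 + perturbation_scale * 0.5 * stats::rnorm(base_lf$n_channels)
      G <- (base_lf$G * outer(chan, rep(1, n))) *
        outer(rep(1, base_lf$n_channels), 1 + perturbation_scale * field)
      G <- G[, mapping, drop = FALSE]   # subject vertex j sits at average vertex mapping[j]
    }
    list(leadfield = leadfield(G, space, sensors),
         cov = make_noise_cov(base_lf$n_channels, n_samples = cov_samples,
                              seed = derive_seed(seed, s)),
         mapping = as.integer(mapping))
  }))
  structure(list(subjects = subjects, space = space, sensors = sensors,
                 n_subjects = as.integer(n_subjects),
                 perturbation_scale = perturbation_scale, seed = seed),
            class = "ctf_subject_set")
}

#' @export
print.ctf_subject_set <- function(x, ...) {
  cat("Subject set:", x$n_subjects, "subjects,",
      x$space$n_vertices, "vertices, perturbation",
      x$perturbation_scale, "\n")
  invisible(x)
}

# Map a subject-space vector (length N_v, indexed by subject vertices) into
# average space: average vertex mapping[j] receives subject entry j.
to_average <- function(v, mapping) {
  out <- v
  out[mapping] <- v
  out
}

# Map an average-space vertex index set into subject indices.
avg_vertices_to_subject <- function(verts, mapping) {
  match(verts, mapping)
}
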