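# Simulation of event-related source-space networks: basis functions,
# binary connectivity, active-node time courses, noise, leakage projection
# and null networks.

#' Epoch time base
#'
#' Sample times of one epoch: 725 ms at `sample_rate`, of which the first
#' 125 ms are pre-stimulus baseline (t < 0).
#'
#' @param sample_rate Sampling rate in Hz (default 250).
#' @return Numeric vector of sample times in seconds (t = 0 is stimulus
#'   onset; 182 samples at 250 Hz, 31 of them baseline).
#' @export
epoch_times <- function(sample_rate = 250) {
  n_base <- round(0.125 * sample_rate)
  n_post <- round(0.600 * sample_rate)
  seq(-n_base, n_post) / sample_rate
}

#' Generate sinusoidal basis functions
#'
#' `n_sources` sinusoids at frequencies equally spaced over `f_range`
#' (endpoints inclusive; a single basis function sits at the lower
#' endpoint). Each basis function's phase is redrawn uniformly on
#' `[0, 2pi)` for every epoch, which makes distinct basis functions
#' incoherent across epochs (expected squared coherence `1/N_e`).
#'
#' @param n_sources Number of basis functions (one per active node).
#' @param n_epochs Number of epochs (default 40).
#' @param sample_rate Sampling rate in Hz; must exceed 110 Hz so the 8-55 Hz
#'   analysis band is Nyquist-safe.
#' @param f_range Frequency interval in Hz (default `c(10, 40)`).
#' @param seed Integer seed.
#' @return An object of class `ctf_basis`: `frequencies`, `phases`
#'   (`n_epochs x n_sources`), `t`, `sample_rate`, `n_epochs`.
#' @export
make_basis <- function(n_sources, n_epochs = 40L, sample_rate = 250,
                       f_range = c(10, 40), seed = 1L) {
  stopifnot(n_sources >= 1, n_epochs >= 1)
  if (sample_rate <= 110) stop("sample_rate must exceed 110 Hz")
  freqs <- seq(f_range[1], f_range[2], length.out = n_sources)
  phases <- with_seed(seed, matrix(stats::runif(n_epochs * n_sources, 0, 2 * pi),
                                   n_epochs, n_sources))
  structure(list(frequencies = freqs, phases = phases,
                 t = epoch_times(sample_rate), sample_rate = sample_rate,
                 n_epochs = as.integer(n_epochs),
                 n_sources = as.integer(n_sources)),
            class = "ctf_basis")
}

# Basis signals of one epoch over sample times tt: n_sources x length(tt).
basis_signals <- function(basis, epoch, tt = basis$t, phase_shift = 0) {
  f <- basis$frequencies
  ph <- basis$phases[epoch, ]
  t(sapply(seq_along(f), function(i) {
    sin(2 * pi * f[i] * tt + ph[i] - if (length(phase_shift) > 1) phase_shift[i] else phase_shift)
  }))
}

# Effective (direct or common-source) connection pairs of a binary mixing
# matrix: pairs of rows sharing at least one basis function.
effective_pairs <- function(A) {
  n <- nrow(A)
  pr <- upper_tri_pairs(n)
  share <- apply(pr, 1, function(e) sum(A[e[1], ] * A[e[2], ]) > 0)
  pr[share, , drop = FALSE]
}

#' Sample a binary mixing matrix with a prescribed effective connectivity
#'
#' The mixing matrix `A` (rows = active nodes, columns = basis functions,
#' unit diagonal so every node is active) is rejection-sampled so that the
#' *effective* connection set — node pairs sharing at least one basis
#' function, which includes indirect connectivity through a common third
#' source — has exactly `round(pct/100 * n(n-1)/2)` members.
#'
#' @param n_sources Number of active nodes.
#' @param pct_connections Percentage of all possible node pairs that must be
#'   effectively connected (in `(0, 100]`).
#' @param seed Integer seed.
#' @param max_tries Sampling restarts before giving up.
#' @return List with `A` (binary matrix), `effective` (2-column matrix of
#'   connected node pairs), `target` (requested pair count).
#' @export
make_A <- function(n_sources, pct_connections, seed = 1L, max_tries = 200L) {
  stopifnot(n_sources >= 1)
  if (pct_connections <= 0 || pct_connections > 100) {
    stop("pct_connections must be in (0, 100]")
  }
  n_pairs <- n_possible_pairs(n_sources)
  target <- round(pct_connections / 100 * n_pairs)
  if (n_sources == 1L) {
    return(list(A = matrix(1, 1, 1), effective = matrix(0L, 0, 2),
                target = 0L))
  }
  off <- which(row(diag(n_sources)) != col(diag(n_sources)))
  best <- c(-Inf, Inf)
  with_seed(seed, {
    for (try in seq_len(max_tries)) {
      A <- diag(n_sources)
      count <- 0L
      for (pos in sample(off)) {
        A[pos] <- 1
        count_new <- nrow(effective_pairs(A))
        if (count_new > target) { A[pos] <- 0 } else { count <- count_new }
        if (count == target) break
      }
      if (count == target) {
        return(list(A = A, effective = effective_pairs(A), target = target))
      }
      best[1] <- max(best[1], count[count <= target], -Inf)
      best[2] <- min(best[2], count[count >= target], Inf)
    }
    stop(sprintf(paste0("could not realise %d effective connections for %d ",
                        "nodes (nearest attainable counts: %s, %s)"),
                 target, n_sources, format(best[1]), format(best[2])))
  })
}

#' Specify a simulated network
#'
#' Draws `n_seeds` active-node locations (parcels of a functional seed
#' atlas, independent of any parcellation under test), a binary mixing
#' matrix with the requested effective connection percentage, and one random
#' phase shift per active node (constant over epochs, so connected nodes are
#' non-zero-lag coupled).
#'
#' @param n_seeds Number of active nodes.
#' @param pct_connections Percentage of effectively connected node pairs.
#' @param snr Target signal-to-noise ratio (RMS of the post-stimulus signal
#'   over the noise standard deviation), e.g. 1 or 3; `Inf` for noiseless.
#' @param seed_atlas A functional-seed `ctf_parcellation` to draw node
#'   locations from.
#' @param seed Integer seed.
#' @return An object of class `ctf_network_spec`: `A`, `effective`, `phi`
#'   (node phase shifts), `an_parcels` (indices into `seed_atlas`),
#'   `an_vertices` (list of vertex sets), `snr`, `pct_connections`.
#' @export
make_network <- function(n_seeds, pct_connections, snr, seed_atlas,
                         seed = 1L) {
  stopifnot(inherits(seed_atlas, "ctf_parcellation"),
            n_seeds >= 1, n_seeds <= seed_atlas$n_parcels)
  mix <- make_A(n_seeds, pct_connections, seed = derive_seed(seed, 1L))
  with_seed(derive_seed(seed, 2L), {
    an <- sample.int(seed_atlas$n_parcels, n_seeds)
    phi <- stats::runif(n_seeds, 0, 2 * pi)
    structure(list(A = mix$A, effective = mix$effective, phi = phi,
                   an_parcels = an,
                   an_vertices = seed_atlas$vertices[an],
                   snr = snr, pct_connections = pct_connections,
                   n_seeds = as.integer(n_seeds)),
              class = "ctf_network_spec")
  })
}

# Active-node time courses of one epoch over post-stimulus times tt:
# g_j(t) = sum_i A[j, i] f_i(t - phi_j), the node's phase shift applied as a
# phase offset of every contributing sinusoid.
an_signals <- function(spec, basis, epoch, tt) {
  n <- spec$n_seeds
  out <- matrix(0, n, length(tt))
  for (j in seq_len(n)) {
    f <- basis$frequencies
    ph <- basis$phases[epoch, ]
    for (i in which(spec$A[j, ] > 0)) {
      out[j, ] <- out[j, ] + sin(2 * pi * f[i] * tt + ph[i] - spec$phi[j])
    }
  }
  out
}

#' Synthesize a multi-subject source-space dataset (no leakage)
#'
#' Every vertex of each active node carries that node's time course in the
#' post-stimulus window; all other vertices, and the pre-stimulus baseline
#' everywhere, carry white Gaussian noise. The noise standard deviation is
#' set per vertex so that `RMS(post-stimulus signal) / SD(noise)` equals the
#' requested SNR. The signal is identical across subjects; noise is drawn
#' independently per subject.
#'
#' @param spec A `ctf_network_spec`.
#' @param basis A `ctf_basis` with `n_sources == n_seeds`.
#' @param space The average `ctf_source_space`.
#' @param n_subjects Number of subject replicates.
#' @param seed Integer seed.
#' @param share_noise Share one noise realization across subjects (default
#'   `TRUE`, the morphed-from-average design)?
#' @return An object of class `ctf_simdata`: `subject_tc` (list of
#'   `n_epochs x N_v x N_t` arrays), `t`, `sample_rate`, `scenario`
#'   (`"no-leakage"`), `spec`, `noise_sd`.
#' @export
synthesize <- function(spec, basis, space, n_subjects = 1L, seed = 1L,
                       share_noise = TRUE) {
  stopifnot(inherits(spec, "ctf_network_spec"), inherits(basis, "ctf_basis"),
            basis$n_sources == spec$n_seeds)
  if (anyDuplicated(unlist(spec$an_vertices))) {
    stop("active-node parcels must be disjoint")
  }
  tt <- basis$t
  post <- tt >= 0
  nv <- space$n_vertices
  nt <- length(tt)
  ne <- basis$n_epochs

  sig <- lapply(seq_len(ne), function(e) an_signals(spec, basis, e, tt[post]))
  # signal RMS as realised in the data: each node's time course is copied to
  # every one of its vertices, so nodes weigh in by their vertex counts
  w <- lengths(spec$an_vertices)
  ms <- mean(vapply(sig, function(m) sum(w * rowMeans(m^2)) / sum(w),
                    numeric(1)))
  rms <- sqrt(ms)
  noise_sd <- if (is.finite(spec$snr)) rms / spec$snr else 0

  draw_one <- function() {
    arr <- array(stats::rnorm(ne * nv * nt, sd = noise_sd), dim = c(ne, nv, nt))
    for (e in seq_len(ne)) {
      for (j in seq_len(spec$n_seeds)) {
        vj <- spec$an_vertices[[j]]
        arr[e, vj, post] <- arr[e, vj, post] +
          matrix(sig[[e]][j, ], length(vj), sum(post), byrow = TRUE)
      }
    }
    arr
  }
  subject_tc <- with_seed(seed, {
    if (share_noise) rep(list(draw_one()), n_subjects)
    else lapply(seq_len(n_subjects), function(s) draw_one())
  })
  structure(list(subject_tc = subject_tc, t = tt,
                 sample_rate = basis$sample_rate, scenario = "no-leakage",
                 spec = spec, noise_sd = noise_sd),
            class = "ctf_simdata")
}

#' @export
print.ctf_simdata <- function(x, ...) {
  d <- dim(x$subject_tc[[1]])
  cat("Simulated dataset (", x$scenario, "): ", length(x$subject_tc),
      " subject(s), ", d[1], " epochs x ", d[2], " vertices x ", d[3],
      " samples\n", sep = "")
  invisible(x)
}

#' Project a dataset through per-subject forward and inverse operators
#'
#' Maps each subject's vertex time courses from average to subject space,
#' applies the subject's resolution matrix (equivalently, forward then
#' inverse operator; optionally adding sensor noise passed through the
#' inverse), and maps back to average space. This imposes the leakage of the
#' measurement process on the simulated sources.
#'
#' @param ds A `ctf_simdata` with one array per subject of `subjects`.
#' @param subjects A `ctf_subject_set`.
#' @param lambda2 Regularization of the inverse operators.
#' @param sensor_noise_sd Standard deviation of additive sensor noise passed
#'   through `W` (0 disables; the source-level noise already traverses `R`).
#' @param seed Seed for the sensor noise.
#' @return A `ctf_simdata` with scenario `"leakage"` (or `"null"` input kept
#'   as `"null"`).
#' @export
project_leakage <- function(ds, subjects, lambda2 = 1 / 9,
                            sensor_noise_sd = 0, seed = 1L) {
  stopifnot(inherits(ds, "ctf_simdata"), inherits(subjects, "ctf_subject_set"),
            length(ds$subject_tc) == subjects$n_subjects)
  nv <- subjects$space$n_vertices
  out <- ds
  out$subject_tc <- with_seed(seed, lapply(seq_len(subjects$n_subjects), function(si) {
    s <- subjects$subjects[[si]]
    W <- mne_operator(s$leadfield, s$cov, lambda2)
    R <- resolution_matrix(W)$R
    arr <- ds$subject_tc[[si]]
    d <- dim(arr)
    flat <- matrix(aperm(arr, c(2, 1, 3)), nv)      # v x (e*t), avg space
    flat <- flat[s$mapping, , drop = FALSE]          # subject space
    proj <- R %*% flat
    if (sensor_noise_sd > 0) {
      eps <- matrix(stats::rnorm(ncol(W$W) * ncol(flat), sd = sensor_noise_sd),
                    ncol(W$W), ncol(flat))
      proj <- proj + W$W %*% eps
    }
    back <- matrix(0, nv, ncol(flat))
    back[s$mapping, ] <- proj                        # back to average space
    aperm(array(back, dim = c(nv, d[1], d[3])), c(2, 1, 3))
  }))
  if (!identical(ds$scenario, "null")) out$scenario <- "leakage"
  out
}

#' Simulate a null network (leakage-induced connectivity only)
#'
#' White noise at every vertex of the average brain, shared across subjects
#' (each subject sees the same average-space realization through their own
#' forward and inverse operators; `share_noise = FALSE` draws per subject
#' instead). The ground-truth connection set is empty: any significant edge
#' found downstream is a leakage-induced false positive.
#'
#' @param subjects A `ctf_subject_set`.
#' @param n_epochs Number of epochs (default 40).
#' @param sample_rate Sampling rate in Hz (default 250).
#' @param noise_sd Noise standard deviation.
#' @param seed Integer seed.
#' @param lambda2 Regularization of the inverse operators.
#' @param share_noise Share one realization across subjects (default `TRUE`)?
#' @return A `ctf_simdata` with scenario `"null"` and `spec = NULL`.
#' @export
make_null <- function(subjects, n_epochs = 40L, sample_rate = 250,
                      noise_sd = 1, seed = 1L, lambda2 = 1 / 9,
                      share_noise = TRUE) {
  stopifnot(inherits(subjects, "ctf_subject_set"))
  tt <- epoch_times(sample_rate)
  nv <- subjects$space$n_vertices
  nt <- length(tt)
  raw <- with_seed(seed, {
    draw <- function() array(stats::rnorm(n_epochs * nv * nt, sd = noise_sd),
                             dim = c(n_epochs, nv, nt))
    if (share_noise) rep(list(draw()), subjects$n_subjects)
    else lapply(seq_len(subjects$n_subjects), function(s) draw())
  })
  ds <- structure(list(subject_tc = raw, t = tt, sample_rate = sample_rate,
                       scenario = "null", spec = NULL, noise_sd = noise_sd),
                  class = "ctf_simdata")
  project_leakage(ds, subjects, lambda2 = lambda2)
}
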