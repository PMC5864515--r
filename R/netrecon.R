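# Network reconstruction: parcel time-course extraction and multitaper
# spectral connectivity (coherence / imaginary coherency).

#' Extract parcel time courses by the mean-flip rule
#'
#' Each vertex signal is sign-flipped according to the orientation of its
#' source normal relative to the parcel's dominant normal direction (first
#' singular vector of the parcel's normals) and the flipped signals are
#' averaged, so opposing-wall vertices do not cancel.
#'
#' @param arr One subject's `n_epochs x N_v x N_t` array (or a
#'   `ctf_simdata`, in which case a list over subjects is returned).
#' @param parc A `ctf_parcellation`.
#' @param space Source space (defaults to `parc$space`).
#' @return `n_epochs x N_parcel x N_t` array (dimnames carry parcel labels),
#'   or a list of such arrays for a `ctf_simdata`.
#' @export
extract_timecourses <- function(arr, parc, space = parc$space) {
  stopifnot(inherits(parc, "ctf_parcellation"))
  if (parc$n_parcels == 0) stop("empty parcellation")
  if (inherits(arr, "ctf_simdata")) {
    return(lapply(arr$subject_tc, extract_timecourses, parc = parc,
                  space = space))
  }
  d <- dim(arr)
  nv <- d[2]
  Wm <- matrix(0, parc$n_parcels, nv)
  for (p in seq_len(parc$n_parcels)) {
    v <- parc$vertices[[p]]
    nrm <- space$normals[v, , drop = FALSE]
    u <- svd(nrm, nu = 0, nv = 1)$v[, 1]
    sgn <- sign(nrm %*% u)
    sgn[sgn == 0] <- 1
    if (sum(sgn) < 0) sgn <- -sgn
    Wm[p, v] <- sgn / length(v)
  }
  flat <- matrix(aperm(arr, c(2, 1, 3)), nv)
  tc <- Wm %*% flat
  out <- aperm(array(tc, dim = c(parc$n_parcels, d[1], d[3])), c(2, 1, 3))
  dimnames(out) <- list(NULL, parc$labels, NULL)
  out
}

#' Discrete prolate spheroidal sequence (Slepian) tapers
#'
#' Computed from the symmetric tridiagonal formulation; concentration
#' eigenvalues are evaluated against the ideal band-limiting kernel.
#'
#' @param n Taper length in samples.
#' @param nw Time-bandwidth product (default 4).
#' @param k Number of tapers (default `2 * nw - 1`).
#' @return List with `tapers` (`n x k`, unit energy) and `eigen`
#'   (concentration values, close to 1).
#' @export
dpss_tapers <- function(n, nw = 4, k = 2 * nw - 1) {
  stopifnot(n >= 2 * k, nw >= 1)
  W <- nw / n
  i <- seq_len(n) - 1
  Tm <- matrix(0, n, n)
  diag(Tm) <- ((n - 1 - 2 * i) / 2)^2 * cos(2 * pi * W)
  off <- (seq_len(n - 1) * (n - seq_len(n - 1))) / 2
  Tm[cbind(seq_len(n - 1), seq_len(n - 1) + 1)] <- off
  Tm[cbind(seq_len(n - 1) + 1, seq_len(n - 1))] <- off
  ev <- eigen(Tm, symmetric = TRUE)
  tapers <- ev$vectors[, seq_len(k), drop = FALSE]
  tapers <- sweep(tapers, 2, sqrt(colSums(tapers^2)), `/`)
  # polarity convention: positive mean for symmetric tapers, positive slope
  # for antisymmetric ones
  for (j in seq_len(k)) {
    s <- sum(tapers[, j])
    if (abs(s) > 1e-8) {
      if (s < 0) tapers[, j] <- -tapers[, j]
    } else if (tapers[2, j] - tapers[1, j] < 0) {
      tapers[, j] <- -tapers[, j]
    }
  }
  # concentration eigenvalues from the band-limiting kernel
  d_ <- outer(i, i, `-`)
  S <- sin(2 * pi * W * d_) / (pi * d_)
  diag(S) <- 2 * W
  lambda <- vapply(seq_len(k), function(j) {
    as.numeric(t(tapers[, j]) %*% S %*% tapers[, j])
  }, numeric(1))
  list(tapers = tapers, eigen = pmin(lambda, 1))
}

# Thomson adaptive weights for one series' eigencoefficients.
# Yk: nf x k complex matrix, lambda: length-k eigenvalues, var0: series
# variance. Returns nf x k non-negative weights d.
adaptive_weights <- function(Yk, lambda, var0, n_iter = 3L) {
  P <- abs(Yk)^2                                  # nf x k eigenspectra
  S <- rowMeans(P[, seq_len(min(2, ncol(P))), drop = FALSE])
  k <- length(lambda)
  d <- matrix(0, nrow(P), k)
  for (it in seq_len(n_iter)) {
    for (j in seq_len(k)) {
      d[, j] <- sqrt(lambda[j]) * S / (lambda[j] * S + (1 - lambda[j]) * var0)
    }
    num <- rowSums(d^2 * P)
    den <- rowSums(d^2)
    S <- ifelse(den > 0, num / den, S)
  }
  d
}

#' Multitaper spectral connectivity between parcel time courses
#'
#' Cross-spectra are estimated with DPSS multitapers (Thomson adaptive
#' weights by default), averaged across epochs, in the post-stimulus
#' analysis window. Magnitude-squared coherence
#' `COH = |S_xy|^2 / (S_xx S_yy)` or the imaginary part of coherency
#' `imCOH = Im(S_xy / sqrt(S_xx S_yy))` is aggregated over the frequency
#' band by the unweighted mean across bins (or the maximum).
#'
#' @param tc `n_epochs x N_parcel x N_t` array from
#'   [extract_timecourses()].
#' @param t Sample times matching the third dimension (seconds).
#' @param sample_rate Sampling rate in Hz.
#' @param metric `"coh"` or `"imcoh"`.
#' @param band Frequency band in Hz (default `c(8, 55)`).
#' @param window Analysis window in seconds (default post-stimulus
#'   `c(0, 0.6)`; the baseline is excluded).
#' @param nw Time-bandwidth product (default 4).
#' @param k Number of tapers (default `2 * nw - 1`).
#' @param adaptive Use Thomson adaptive weights (default `TRUE`)?
#' @param aggregate `"mean"` or `"max"` over band bins.
#' @return An object of class `ctf_connectivity`: `M_con`
#'   (`N_parcel x N_parcel`, symmetric; imCOH stored signed in the upper
#'   triangle and mirrored), `metric`, `band`, `freqs` (band bin
#'   frequencies), `per_bin` (p x p x nf array of the metric).
#' @export
spectral_connectivity <- function(tc, t, sample_rate,
                                  metric = c("coh", "imcoh"),
                                  band = c(8, 55), window = c(0, 0.6),
                                  nw = 4, k = 2 * nw - 1, adaptive = TRUE,
                                  aggregate = c("mean", "max")) {
  metric <- match.arg(metric)
  aggregate <- match.arg(aggregate)
  d <- dim(tc)
  if (d[1] < 2) stop("need at least 2 epochs")
  use <- t >= window[1] & t <= window[2]
  n <- sum(use)
  if (n < 2 * k) stop("analysis window shorter than 2 taper lengths")
  dp <- dpss_tapers(n, nw = nw, k = k)
  freqs <- (seq_len(n) - 1) * sample_rate / n
  bins <- which(freqs >= band[1] & freqs <= band[2] & freqs <= sample_rate / 2)
  if (!length(bins)) stop("no frequency bins inside the band")
  np <- d[2]
  nf <- length(bins)

  Sxy <- array(0 + 0i, dim = c(np, np, nf))
  Nxy <- array(0, dim = c(np, np, nf))
  for (e in seq_len(d[1])) {
    X <- matrix(aperm(tc[e, , use, drop = FALSE], c(3, 2, 1)), n, np)
    vars <- pmax(apply(X, 2, stats::var), .Machine$double.eps)
    # eigencoefficients: nf x k per parcel
    Yk <- array(0 + 0i, dim = c(nf, k, np))
    for (j in seq_len(k)) {
      F <- stats::mvfft(X * dp$tapers[, j])
      Yk[, j, ] <- F[bins, , drop = FALSE]
    }
    Dw <- array(0, dim = c(nf, k, np))
    for (p in seq_len(np)) {
      Dw[, , p] <- if (adaptive) {
        adaptive_weights(Yk[, , p, drop = FALSE][, , 1], dp$eigen, vars[p])
      } else {
        matrix(sqrt(dp$eigen), nf, k, byrow = TRUE)
      }
    }
    for (fi in seq_len(nf)) {
      V <- t(Yk[fi, , ]) * t(Dw[fi, , ])             # np x k weighted coeffs
      Wr <- t(Dw[fi, , ])                            # np x k real weights
      Sxy[, , fi] <- Sxy[, , fi] + V %*% Conj(t(V))
      Nxy[, , fi] <- Nxy[, , fi] + Wr %*% t(Wr)
    }
  }
  Sxy <- Sxy / ifelse(Nxy > 0, Nxy, 1)

  per_bin <- array(0, dim = c(np, np, nf))
  for (fi in seq_len(nf)) {
    S <- Sxy[, , fi]
    auto <- Re(diag(S))
    denom <- sqrt(outer(auto, auto))
    Cc <- S / ifelse(denom > 0, denom, 1)
    per_bin[, , fi] <- if (metric == "coh") abs(Cc)^2 else Im(Cc)
  }
  M <- if (aggregate == "mean") apply(per_bin, c(1, 2), mean) else {
    if (metric == "imcoh") {
      sel <- apply(abs(per_bin), c(1, 2), which.max)
      matrix(per_bin[cbind(as.vector(row(sel)), as.vector(col(sel)),
                           as.vector(sel))], np, np)
    } else apply(per_bin, c(1, 2), max)
  }
  diag(M) <- if (metric == "coh") 1 else 0
  dimnames(M) <- dimnames(tc)[c(2, 2)]
  structure(list(M_con = M, metric = metric, band = band,
                 freqs = freqs[bins], per_bin = per_bin,
                 window = window, nw = nw, k = k, adaptive = adaptive),
            class = "ctf_connectivity")
}

#' @export
print.ctf_connectivity <- function(x, ...) {
  cat("Connectivity matrix (", toupper(x$metric), ", ",
      x$band[1], "-", x$band[2], " Hz): ", nrow(x$M_con), " parcels\n",
      sep = "")
  invisible(x)
}

#' Per-subject connectivity stack for a simulated dataset
#'
#' Extracts parcel time courses for every subject and computes the spectral
#' connectivity matrix, returning the subject stack that the permutation
#' statistics consume.
#'
#' @param ds A `ctf_simdata`.
#' @param parc A `ctf_parcellation`.
#' @param metric,band,... Passed to [spectral_connectivity()].
#' @return `n_subjects x N_parcel x N_parcel` array.
#' @export
connectivity_stack <- function(ds, parc, metric = "coh", band = c(8, 55),
                               ...) {
  stopifnot(inherits(ds, "ctf_simdata"))
  tcs <- extract_timecourses(ds, parc)
  mats <- lapply(tcs, function(tc) {
    spectral_connectivity(tc, t = ds$t, sample_rate = ds$sample_rate,
                          metric = metric, band = band, ...)$M_con
  })
  out <- array(0, dim = c(length(mats), parc$n_parcels, parc$n_parcels),
               dimnames = list(NULL, parc$labels, parc$labels))
  for (s in seq_along(mats)) out[s, , ] <- mats[[s]]
  out
}
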