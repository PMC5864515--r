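# L2 minimum-norm inverse operators, resolution matrices and cross-talk
# functions.

#' Compute an L2 minimum-norm inverse operator
#'
#' `W = G' (G G' + lambda2 * C)^-1` with gain matrix `G`, noise covariance
#' `C` and regularization parameter `lambda2`. `C` is symmetrized and, under
#' the default `scale = "snr"`, rescaled so that `trace(C) = trace(G G')`;
#' `lambda2` is then dimensionless (the conventional `1/SNR^2`, default
#' `SNR = 3`) and the resulting resolution matrix is invariant to a global
#' rescaling of the gains. `scale = "none"` applies the formula literally.
#'
#' With `lambda2 = 0` and a square full-rank `G`, `W = G^-1`. A numerically
#' singular system without regularization is an error; with `lambda2 > 0` a
#' pseudo-inverse fallback is used and flagged.
#'
#' @param lf A `ctf_leadfield`.
#' @param cov A `ctf_noisecov`, a plain covariance matrix, or `NULL` for the
#'   identity.
#' @param lambda2 Non-negative regularization parameter (default `1/9`).
#' @param scale `"snr"` (trace-normalized covariance) or `"none"` (literal).
#' @return An object of class `ctf_inverse` with fields `W`, `lambda2`,
#'   `cov`, `pseudo_inverse` (flag).
#' @export
mne_operator <- function(lf, cov = NULL, lambda2 = 1 / 9,
                         scale = c("snr", "none")) {
  stopifnot(inherits(lf, "ctf_leadfield"), lambda2 >= 0)
  scale <- match.arg(scale)
  G <- lf$G
  C <- if (is.null(cov)) diag(nrow(G)) else if (inherits(cov, "ctf_noisecov")) cov$C else as.matrix(cov)
  if (!isTRUE(all.equal(dim(C), rep(nrow(G), 2L)))) {
    stop("covariance dimension must match the number of channels")
  }
  C <- (C + t(C)) / 2
  GGt <- G %*% t(G)
  if (scale == "snr" && lambda2 > 0) {
    C <- C * (sum(diag(GGt)) / sum(diag(C)))
  }
  K <- GGt + lambda2 * C
  pseudo <- FALSE
  Kinv <- tryCatch(solve(K), error = function(e) NULL)
  if (is.null(Kinv)) {
    if (lambda2 == 0) {
      stop("ill-posed without regularization: G G' is singular and lambda2 = 0")
    }
    Kinv <- MASS::ginv(K)
    pseudo <- TRUE
  }
  structure(list(W = t(G) %*% Kinv, lambda2 = lambda2, cov = C,
                 pseudo_inverse = pseudo, leadfield = lf),
            class = "ctf_inverse")
}

#' @export
print.ctf_inverse <- function(x, ...) {
  cat("MNE inverse operator:", nrow(x$W), "sources x", ncol(x$W),
      "channels, lambda2 =", format(x$lambda2), "\n")
  invisible(x)
}

#' Compute the resolution matrix R = W G
#'
#' Row `i` of `R` is the cross-talk function (CTF) of source `i`: how
#' activity at every source contaminates the estimate at source `i`. With a
#' square invertible `G` and no regularization, `R` is the identity; with an
#' identity noise covariance `R` is symmetric.
#'
#' @param inv A `ctf_inverse`.
#' @param lf A `ctf_leadfield` (defaults to the one the operator was built
#'   from).
#' @return An object of class `ctf_resolution` with field `R`
#'   (`N_s x N_s`), plus `lambda2` and a `space` reference.
#' @export
resolution_matrix <- function(inv, lf = inv$leadfield) {
  stopifnot(inherits(inv, "ctf_inverse"), inherits(lf, "ctf_leadfield"))
  if (ncol(inv$W) != nrow(lf$G)) stop("shape mismatch between W and G")
  structure(list(R = inv$W %*% lf$G, lambda2 = inv$lambda2,
                 space = lf$space),
            class = "ctf_resolution")
}

#' @export
print.ctf_resolution <- function(x, ...) {
  cat("Resolution matrix:", nrow(x$R), "x", ncol(x$R),
      "(rows are cross-talk functions)\n")
  invisible(x)
}

#' Extract a cross-talk function
#'
#' Row `i` of the resolution matrix, optionally as absolute values (the
#' parcellation machinery works on `|CTF|` since only the amount of leakage
#' matters, not its sign).
#'
#' @param res A `ctf_resolution`.
#' @param source_index Row index.
#' @param abs Return absolute values?
#' @return Numeric vector over all sources.
#' @export
ctf <- function(res, source_index, abs = FALSE) {
  stopifnot(inherits(res, "ctf_resolution"))
  n <- nrow(res$R)
  if (source_index < 1 || source_index > n || source_index != round(source_index)) {
    stop("source_index out of range")
  }
  v <- res$R[source_index, ]
  if (abs) base::abs(v) else v
}

# Average |R| across subjects in average space: entry (i, j) of the result is
# the mean over subjects of |R_s| at the subject vertices mapped to average
# vertices i, j.
average_abs_resolution <- function(subjects, lambda2 = 1 / 9, absR = NULL) {
  stopifnot(inherits(subjects, "ctf_subject_set"))
  if (is.null(absR)) absR <- subject_abs_resolutions(subjects, lambda2)
  n <- subjects$space$n_vertices
  acc <- matrix(0, n, n)
  for (si in seq_len(subjects$n_subjects)) {
    m <- subjects$subjects[[si]]$mapping
    acc[m, m] <- acc[m, m] + absR[[si]]
  }
  acc / subjects$n_subjects
}
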