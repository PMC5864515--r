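# Parcel CTFs and the parcel resolution matrix (PRmat) with its quality
# metrics.

#' Representative cross-talk function of a parcel
#'
#' Stacks the absolute CTFs of the parcel's vertices as rows of `M_p` (a
#' row-submatrix of `|R|`) and takes the first right-singular vector of the
#' (uncentered) SVD as the parcel's representative CTF. The sign is fixed so
#' the vector sums to a non-negative value and, since it is a combination of
#' non-negative rows, any residual negative entries are clipped at zero as a
#' numerical guard; the result has unit L2 norm.
#'
#' @param res A `ctf_resolution` (or a plain `|R|`-like matrix).
#' @param parcel Integer vector of vertex indices (non-empty).
#' @param center Center the rows of `M_p` before the SVD? Default `FALSE`
#'   (raw SVD, consistent with the representative-vector convention).
#' @return An object of class `ctf_parcel_ctf`: list with `ctf_p` (length
#'   `N_v`), `explained_variance` (squared-singular-value fractions), `M_p`.
#' @export
parcel_ctf <- function(res, parcel, center = FALSE) {
  R <- if (inherits(res, "ctf_resolution")) abs(res$R) else abs(as.matrix(res))
  parcel <- as.integer(parcel)
  if (!length(parcel)) stop("empty parcel")
  M <- R[parcel, , drop = FALSE]
  Ms <- if (center) sweep(M, 2, colMeans(M)) else M
  sv <- svd(Ms, nu = 0, nv = 1)
  v <- sv$v[, 1]
  if (sum(v) < 0) v <- -v
  v[v < 0] <- 0
  nrm <- sqrt(sum(v^2))
  if (nrm > 0) v <- v / nrm
  structure(list(ctf_p = v,
                 explained_variance = sv$d^2 / sum(sv$d^2),
                 M_p = M),
            class = "ctf_parcel_ctf")
}

# Number of principal components needed to explain more than `threshold` of
# the CTF variance of a parcel (from squared singular values of M_p).
n_components_needed <- function(res, parcel, threshold = 0.9, center = FALSE) {
  R <- if (inherits(res, "ctf_resolution")) abs(res$R) else abs(as.matrix(res))
  M <- R[as.integer(parcel), , drop = FALSE]
  if (center) M <- sweep(M, 2, colMeans(M))
  d2 <- svd(M, nu = 0, nv = 0)$d^2
  frac <- cumsum(d2) / sum(d2)
  which(frac > threshold)[1L]
}

#' Subject-averaged representative parcel CTFs
#'
#' Computes each parcel's representative CTF per subject (in that subject's
#' source space), maps it to average space through the subject-to-average
#' vertex mapping, and averages across subjects.
#'
#' @param parc A `ctf_parcellation` in average space.
#' @param subjects A `ctf_subject_set`.
#' @param lambda2 Regularization for the per-subject inverse operators.
#' @param center Passed to [parcel_ctf()].
#' @param absR Optional precomputed list of per-subject `|R|` matrices (from
#'   [subject_abs_resolutions()]) to avoid refitting inverse operators.
#' @return Matrix `N_parcel x N_v` of averaged representative CTFs (rows in
#'   parcellation order).
#' @export
group_parcel_ctfs <- function(parc, subjects, lambda2 = 1 / 9, center = FALSE,
                              absR = NULL) {
  stopifnot(inherits(parc, "ctf_parcellation"),
            inherits(subjects, "ctf_subject_set"))
  if (is.null(absR)) absR <- subject_abs_resolutions(subjects, lambda2)
  n <- subjects$space$n_vertices
  acc <- matrix(0, parc$n_parcels, n)
  for (si in seq_len(subjects$n_subjects)) {
    s <- subjects$subjects[[si]]
    R <- absR[[si]]
    for (p in seq_len(parc$n_parcels)) {
      sv <- avg_vertices_to_subject(parc$vertices[[p]], s$mapping)
      sv <- sv[!is.na(sv)]
      if (!length(sv)) next
      v <- parcel_ctf(R, sv, center = center)$ctf_p
      acc[p, s$mapping] <- acc[p, s$mapping] + v
    }
  }
  acc / subjects$n_subjects
}

#' Compute the parcel resolution matrix and its quality metrics
#'
#' `PRmat[i, j]` is the normalised leakage from parcel `i` received at parcel
#' `j`: under the default `"per-vertex-share"` normalization it is the mean,
#' over vertices `k` of parcel `j`, of parcel `i`'s share of the total
#' representative-CTF mass at `k`, `ctf_i(k) / sum_l ctf_l(k)`. This
#' guarantees entries in `[0, 1]`, columns that sum to 1 over parcels, and an
#' identity PRmat in the ideal fully-resolved case. The alternative
#' `"per-source-mass"` normalizes by parcel `i`'s own total CTF mass over all
#' parcel vertices.
#'
#' Vertices at which all representative CTFs are exactly zero carry no
#' leakage information and are excluded from the means (and counted in
#' `n_zero_vertices`).
#'
#' @param parcel_ctfs `N_parcel x N_v` matrix of representative CTFs (e.g.
#'   from [group_parcel_ctfs()]).
#' @param parc The matching `ctf_parcellation` (>= 2 parcels).
#' @param normalization `"per-vertex-share"` or `"per-source-mass"`.
#' @param rank_tol Heuristic singular-value tolerance for the PRmat rank
#'   (default 0.05, relative to the largest singular value).
#' @return An object of class `ctf_prmat`: `PRmat`, `S_ind` (mean diagonal),
#'   `D_ind` (Pearson correlation with the identity), `rank`, `cond`,
#'   `coverage`, `labels`, `n_zero_vertices`.
#' @export
compute_prmat <- function(parcel_ctfs, parc,
                          normalization = c("per-vertex-share", "per-source-mass"),
                          rank_tol = 0.05) {
  stopifnot(inherits(parc, "ctf_parcellation"))
  normalization <- match.arg(normalization)
  Cmat <- as.matrix(parcel_ctfs)
  np <- parc$n_parcels
  if (np < 2) stop("need at least 2 parcels")
  stopifnot(nrow(Cmat) == np)

  n_zero <- 0L
  P <- matrix(0, np, np, dimnames = list(parc$labels, parc$labels))
  if (normalization == "per-vertex-share") {
    tot <- colSums(Cmat)
    ok <- tot > 0
    share <- Cmat
    share[, ok] <- sweep(Cmat[, ok, drop = FALSE], 2, tot[ok], `/`)
    for (j in seq_len(np)) {
      kj <- parc$vertices[[j]]
      use <- kj[ok[kj]]
      n_zero <- n_zero + length(kj) - length(use)
      if (length(use)) P[, j] <- rowMeans(share[, use, drop = FALSE])
    }
  } else {
    # leakage from parcel i at parcel j, normalised by parcel i's total mass
    for (i in seq_len(np)) {
      mass <- sum(Cmat[i, unlist(parc$vertices)])
      if (mass <= 0) next
      for (j in seq_len(np)) {
        kj <- parc$vertices[[j]]
        P[i, j] <- sum(Cmat[i, kj]) / mass
      }
    }
  }

  rc <- prmat_rank_cond(P, tol = rank_tol)
  structure(list(PRmat = P,
                 S_ind = sensitivity_index(P),
                 D_ind = distinguishability_index(P),
                 rank = rc$rank, cond = rc$cond,
                 coverage = parc$coverage,
                 labels = parc$labels,
                 normalization = normalization,
                 n_zero_vertices = n_zero),
            class = "ctf_prmat")
}

#' @export
print.ctf_prmat <- function(x, ...) {
  cat("Parcel resolution matrix: ", nrow(x$PRmat), " parcels\n",
      "  S_ind = ", format(x$S_ind, digits = 3),
      ", D_ind = ", format(x$D_ind, digits = 3),
      ", rank = ", x$rank,
      ", cond = ", format(x$cond, digits = 4),
      ", coverage = ", x$coverage, "\n", sep = "")
  invisible(x)
}

#' Sensitivity index: mean diagonal of the PRmat
#'
#' Mean self-leakage of the parcels; 1 for an ideal (identity) PRmat.
#'
#' @param prmat Square PRmat matrix or a `ctf_prmat`.
#' @return Scalar in `[0, 1]`.
#' @export
sensitivity_index <- function(prmat) {
  P <- if (inherits(prmat, "ctf_prmat")) prmat$PRmat else as.matrix(prmat)
  stopifnot(nrow(P) == ncol(P))
  mean(diag(P))
}

#' Distinguishability index: correlation of the PRmat with the identity
#'
#' Pearson correlation between the flattened PRmat and the identity matrix of
#' the same size; 1 for an ideal PRmat. Undefined (returns `NA`) for a
#' constant matrix.
#'
#' @param prmat Square PRmat matrix or a `ctf_prmat`.
#' @return Scalar in `[-1, 1]`, or `NA` if the PRmat is constant.
#' @export
distinguishability_index <- function(prmat) {
  P <- if (inherits(prmat, "ctf_prmat")) prmat$PRmat else as.matrix(prmat)
  stopifnot(nrow(P) == ncol(P))
  if (stats::sd(as.numeric(P)) == 0) return(NA_real_)
  stats::cor(as.numeric(P), as.numeric(diag(nrow(P))))
}

#' Rank (with heuristic tolerance) and condition number of a PRmat
#'
#' The rank counts singular values above `tol` times the largest (the PRmat
#' is scaled in `[0, 1]`, so the default 0.05 asks whether a row is more than
#' 95% explained by the others); the condition number is the 2-norm ratio of
#' largest to smallest singular value of the full matrix.
#'
#' @param prmat Square matrix or `ctf_prmat`.
#' @param tol Relative singular-value tolerance (default 0.05).
#' @return List with `rank` (integer) and `cond` (Inf for a singular-to-
#'   working-precision matrix; rank 0 and `cond = Inf` for the zero matrix).
#' @export
prmat_rank_cond <- function(prmat, tol = 0.05) {
  P <- if (inherits(prmat, "ctf_prmat")) prmat$PRmat else as.matrix(prmat)
  stopifnot(nrow(P) == ncol(P))
  d <- svd(P, nu = 0, nv = 0)$d
  if (max(d) == 0) return(list(rank = 0L, cond = Inf))
  list(rank = sum(d > tol * max(d)),
       cond = if (min(d) == 0) Inf else max(d) / min(d))
}

#' PRmat of a parcellation under a subject set
#'
#' Convenience wrapper: subject-averaged representative CTFs followed by
#' [compute_prmat()].
#'
#' @inheritParams group_parcel_ctfs
#' @inheritParams compute_prmat
#' @return A `ctf_prmat`.
#' @export
parcellation_prmat <- function(parc, subjects, lambda2 = 1 / 9,
                               normalization = "per-vertex-share",
                               rank_tol = 0.05, absR = NULL) {
  compute_prmat(group_parcel_ctfs(parc, subjects, lambda2, absR = absR), parc,
                normalization = normalization, rank_tol = rank_tol)
}

#' Per-subject absolute resolution matrices
#'
#' Fits each subject's minimum-norm inverse operator and returns the list of
#' `|R|` matrices (subject-space indexing). Computing these once and passing
#' them to the parcellation stages avoids repeated inverse fits.
#'
#' @param subjects A `ctf_subject_set`.
#' @param lambda2 Regularization parameter.
#' @return List of `N_v x N_v` non-negative matrices, one per subject.
#' @export
subject_abs_resolutions <- function(subjects, lambda2 = 1 / 9) {
  stopifnot(inherits(subjects, "ctf_subject_set"))
  lapply(subjects$subjects, function(s) {
    abs(resolution_matrix(mne_operator(s$leadfield, s$cov, lambda2))$R)
  })
}
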