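# Region-growing adaptive parcellation from the vertex-level resolution
# matrix.

#' Find seed vertices from the vertex-level resolution matrix
#'
#' Treats every vertex as a single-vertex parcel, applying the parcel-level
#' sensitivity (half-max) and specificity (winner-takes-all, `z > z_thresh`,
#' margin) rules directly to the rows of the subject-averaged `|R|`: raw
#' rows, not unit-normalized ones, so that overall sensitivity differences
#' between vertices count — a strongly seen vertex can dominate its weakly
#' seen neighbours, which is what makes it a seed. A vertex that wins at
#' least one vertex other than itself is a seed. Seeds are ordered by their self z-score (descending; ties broken by
#' lower vertex index). Z-scoring is done in column blocks of fixed size so
#' memory stays bounded; results are independent of the block size.
#'
#' @param res_avg Subject-averaged `|R|` matrix in average space (e.g. from
#'   [average_abs_resolution()]), or a `ctf_resolution`.
#' @param space The `ctf_source_space`.
#' @param z_thresh,margin Specificity thresholds (defaults 3 and 1).
#' @param block_size Number of vertex columns scored per block.
#' @return An object of class `ctf_seed_list`: data frame with `seed`
#'   (vertex index), `self_z`, `n_won` (vertices won including self),
#'   ordered by `self_z` descending.
#' @export
find_seeds <- function(res_avg, space, z_thresh = 3, margin = 1,
                       block_size = 1024L) {
  R <- if (inherits(res_avg, "ctf_resolution")) abs(res_avg$R) else abs(as.matrix(res_avg))
  nv <- nrow(R)
  stopifnot(nv == space$n_vertices)
  Rn <- R
  rmax <- apply(Rn, 1, max)

  winner <- rep(NA_integer_, nv)
  self_z <- rep(NA_real_, nv)
  for (start in seq(1, nv, by = block_size)) {
    cols <- start:min(start + block_size - 1L, nv)
    M <- Rn[, cols, drop = FALSE]
    sens <- M >= 0.5 * rmax
    mu <- colMeans(M)
    sg <- sqrt(pmax(0, colMeans(M^2) - mu^2))
    Z <- sweep(M, 2, mu)
    Z <- sweep(Z, 2, ifelse(sg > 0, sg, NA_real_), `/`)
    tbl <- structure(list(Z = Z, sensitive = sens, sigma_zero = sg == 0),
                     class = "ctf_specificity")
    cats <- categorize_vertices(tbl, z_thresh, margin)
    winner[cols] <- cats$winner
    self_z[cols] <- Z[cbind(cols, seq_along(cols))]
  }

  won <- tabulate(winner[!is.na(winner)], nbins = nv)
  other <- won - as.integer(!is.na(winner) & winner == seq_len(nv))
  seeds <- which(other >= 1L)
  if (!length(seeds)) {
    stop("no seeds found: no vertex wins any vertex besides itself ",
         "(resolution matrix may be too close to identity or too blurred)")
  }
  ord <- order(-self_z[seeds], seeds)
  structure(data.frame(seed = seeds[ord], self_z = self_z[seeds][ord],
                       n_won = won[seeds][ord]),
            class = c("ctf_seed_list", "data.frame"))
}

#' Grow parcels around seed vertices
#'
#' Works on the hemisphere holding more winner seeds. In descending seed
#' strength, parcel `k` collects the still-unassigned vertices of that
#' hemisphere whose cross-talk value in seed `k`'s CTF reaches half of that
#' CTF's maximum anywhere in the brain. The grown parcels are then mirrored
#' to the opposite hemisphere through the mirror map.
#'
#' @param seeds A `ctf_seed_list`.
#' @param res_avg Subject-averaged `|R|` matrix (same one used for the
#'   seeds).
#' @param space The `ctf_source_space`.
#' @return A bilateral `ctf_parcellation` of grown parcels.
#' @export
grow_regions <- function(seeds, res_avg, space) {
  stopifnot(inherits(seeds, "ctf_seed_list"))
  R <- if (inherits(res_avg, "ctf_resolution")) abs(res_avg$R) else abs(as.matrix(res_avg))
  hemi_of <- space$hemisphere[seeds$seed]
  grow_hemi <- if (sum(hemi_of == "lh") >= sum(hemi_of == "rh")) "lh" else "rh"
  in_hemi <- space$hemisphere == grow_hemi

  unassigned <- in_hemi
  verts <- list(); base <- character(0)
  k <- 0L
  for (s in seeds$seed[hemi_of == grow_hemi]) {
    row <- R[s, ]
    supp <- which(unassigned & row >= 0.5 * max(row))
    if (!length(supp)) next
    k <- k + 1L
    verts <- c(verts, list(supp))
    base <- c(base, sprintf("rg%03d", k))
    unassigned[supp] <- FALSE
  }
  if (!k) stop("region growing produced no parcels")
  other <- lapply(verts, function(v) space$mirror_map[v])
  if (grow_hemi == "lh") {
    parcellation(c(verts, other), rep(base, 2),
                 rep(c("lh", "rh"), each = k), space, kind = "region-grown")
  } else {
    parcellation(c(other, verts), rep(base, 2),
                 rep(c("lh", "rh"), each = k), space, kind = "region-grown")
  }
}

#' Region-growing adaptive parcellation
#'
#' Atlas-free pipeline: seed detection on the subject-averaged vertex-level
#' resolution matrix, region growing around the seeds in strength order,
#' then the split-and-merge modification steps minus splitting (vertex
#' reassignment, merging, final homogeneity evaluation with minimum size,
#' PRmat diagonal dominance and bilateral mirror symmetry).
#'
#' @param subjects A `ctf_subject_set`.
#' @param z_thresh,margin Specificity thresholds (defaults 3 and 1).
#' @param min_vertices Minimum final parcel size (default 10).
#' @param lambda2 Inverse-operator regularization (default `1/9`).
#' @param normalization,rank_tol Passed to [compute_prmat()].
#' @return A `ctf_parc_fit` (method `"rg"`); `initial_prmat` holds the PRmat
#'   of the raw grown parcellation before modification.
#' @seealso [run_sam()]
#' @export
run_rg <- function(subjects, z_thresh = 3, margin = 1, min_vertices = 10L,
                   lambda2 = 1 / 9, normalization = "per-vertex-share",
                   rank_tol = 0.05) {
  cl <- match.call()
  absR <- subject_abs_resolutions(subjects, lambda2)
  res_avg <- average_abs_resolution(subjects, lambda2, absR = absR)
  seeds <- find_seeds(res_avg, subjects$space, z_thresh, margin)
  grown <- grow_regions(seeds, res_avg, subjects$space)
  initial_prmat <- parcellation_prmat(grown, subjects, lambda2,
                                      normalization = normalization,
                                      rank_tol = rank_tol, absR = absR)
  cm <- group_parcel_ctfs(grown, subjects, lambda2, absR = absR)
  cats <- categorize_vertices(score_specificity(cm), z_thresh, margin)
  merged <- merge_parcels(cats, grown)
  intermediate <- apply_categories(grown, cats, merged)
  fin <- finalize_parcellation(intermediate, subjects, min_vertices, lambda2,
                               z_thresh, margin, normalization, rank_tol,
                               absR = absR)
  structure(list(parcellation = fin$parcellation, prmat = fin$prmat,
                 initial_prmat = initial_prmat, seeds = seeds,
                 log = c(list(n_seeds = nrow(seeds),
                              n_grown = grown$n_parcels,
                              n_merged = length(merged),
                              n_intermediate = intermediate$n_parcels),
                         fin$log),
                 method = "rg",
                 config = list(z_thresh = z_thresh, margin = margin,
                               min_vertices = min_vertices, lambda2 = lambda2,
                               normalization = normalization,
                               rank_tol = rank_tol),
                 call = cl),
            class = "ctf_parc_fit")
}

#' @export
print.ctf_parc_fit <- function(x, ...) {
  cat("CTF-adaptive parcellation (",
      if (x$method == "sam") "split-and-merge" else "region growing",
      ")\n", sep = "")
  cat("  final parcels: ", x$parcellation$n_parcels,
      ", coverage ", x$parcellation$coverage, "/",
      x$parcellation$space$n_vertices, " vertices\n", sep = "")
  cat("  S_ind = ", format(x$prmat$S_ind, digits = 3),
      " (initial ", format(x$initial_prmat$S_ind, digits = 3), ")",
      ", D_ind = ", format(x$prmat$D_ind, digits = 3),
      " (initial ", format(x$initial_prmat$D_ind, digits = 3), ")\n", sep = "")
  invisible(x)
}

#' @export
summary.ctf_parc_fit <- function(object, ...) {
  out <- list(
    method = object$method,
    n_parcels = object$parcellation$n_parcels,
    sizes = summary(lengths(object$parcellation$vertices)),
    metrics = coef(object),
    initial = c(S_ind = object$initial_prmat$S_ind,
                D_ind = object$initial_prmat$D_ind),
    log = object$log)
  class(out) <- "summary.ctf_parc_fit"
  out
}

#' @export
print.summary.ctf_parc_fit <- function(x, ...) {
  cat("Method:", x$method, "\nParcels:", x$n_parcels, "\nSizes:\n")
  print(x$sizes)
  cat("Metrics:\n")
  print(x$metrics)
  cat("Initial indices: S_ind =", format(x$initial["S_ind"], digits = 3),
      ", D_ind =", format(x$initial["D_ind"], digits = 3), "\n")
  cat("Stage log:", paste(names(x$log), unlist(x$log), sep = "=",
                          collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.ctf_parc_fit <- function(object, ...) {
  c(S_ind = object$prmat$S_ind, D_ind = object$prmat$D_ind,
    rank = object$prmat$rank, cond = object$prmat$cond,
    coverage = object$prmat$coverage,
    n_parcels = object$parcellation$n_parcels)
}

#' @export
plot.ctf_parc_fit <- function(x, ...) {
  P <- x$prmat$PRmat
  n <- nrow(P)
  graphics::image(seq_len(n), seq_len(n), t(P[n:1, , drop = FALSE]),
                  xlab = "receiving parcel", ylab = "source parcel",
                  main = sprintf("PRmat (%s, %d parcels)", x$method, n),
                  ...)
  invisible(x)
}
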