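# Split-and-merge (SaM) adaptive parcellation driven by cross-talk functions.

# Mode of an integer vector; the minimum value among ties.
mode_min <- function(x) {
  tab <- table(x)
  min(as.integer(names(tab)[tab == max(tab)]))
}

#' Split CTF-heterogeneous parcels along their longest spatial axis
#'
#' For every parcel, the number of principal components `N_PC` needed to
#' explain more than `variance_threshold` of the variance of its vertex CTFs
#' is computed per subject (uncentered SVD of the `|CTF|` submatrix `M_p`).
#' `N_PC` is harmonized to the minimum over the contralateral pair within a
#' subject (under-splitting preferred over over-splitting) and to the mode
#' across subjects (minimum among tied modes). A parcel with `N_PC = k > 1`
#' is cut into `k` contiguous sub-parcels by projecting its vertices'
#' registered-sphere coordinates onto the parcel's principal eigen-axis and
#' slicing the projected coordinate into `k` equal-length intervals; the
#' right-hemisphere twin inherits the mirrored split. Empty slices collapse
#' (with a warning), as does a parcel smaller than its `N_PC`.
#'
#' @param atlas Initial `ctf_parcellation` (bilateral, mirror-paired bases).
#' @param subjects A `ctf_subject_set`.
#' @param variance_threshold CTF variance fraction that one component must
#'   exceed for the parcel to stay whole (default 0.90).
#' @param lambda2 Regularization of the per-subject inverse operators.
#' @param center Center `M_p` before the SVD (default `FALSE`).
#' @param absR Optional precomputed [subject_abs_resolutions()] list.
#' @return List with `parcellation` (the split-parcel `ctf_parcellation`) and
#'   `plan` (data frame: base label, harmonized `N_PC`, realized sub-parcel
#'   count).
#' @export
split_parcels <- function(atlas, subjects, variance_threshold = 0.9,
                          lambda2 = 1 / 9, center = FALSE, absR = NULL) {
  stopifnot(inherits(atlas, "ctf_parcellation"),
            inherits(subjects, "ctf_subject_set"))
  space <- atlas$space
  np <- atlas$n_parcels
  if (is.null(absR)) absR <- subject_abs_resolutions(subjects, lambda2)

  # per-subject N_PC per parcel
  npc <- matrix(NA_integer_, subjects$n_subjects, np)
  for (si in seq_len(subjects$n_subjects)) {
    s <- subjects$subjects[[si]]
    R <- absR[[si]]
    for (p in seq_len(np)) {
      sv <- avg_vertices_to_subject(atlas$vertices[[p]], s$mapping)
      sv <- sv[!is.na(sv)]
      if (!length(sv)) stop("parcel ", atlas$labels[p],
                            " has no vertices for subject ", si)
      npc[si, p] <- n_components_needed(R, sv, threshold = variance_threshold,
                                        center = center)
    }
    # hemisphere harmonization: min over each contralateral pair
    for (b in unique(atlas$base)) {
      idx <- which(atlas$base == b)
      npc[si, idx] <- min(npc[si, idx])
    }
  }
  # subject harmonization: mode (min of tied modes)
  npc_final <- vapply(seq_len(np), function(p) mode_min(npc[, p]), integer(1))

  verts <- list(); base <- character(0); hemi <- character(0)
  plan <- data.frame(base = character(0), n_pc = integer(0),
                     n_subparcels = integer(0))
  for (b in unique(atlas$base)) {
    il <- which(atlas$base == b & atlas$hemisphere == "lh")
    ir <- which(atlas$base == b & atlas$hemisphere == "rh")
    k <- npc_final[c(il, ir)][1L]
    vl <- if (length(il)) atlas$vertices[[il]] else integer(0)
    if (k > 1 && length(vl) >= k) {
      xyz <- space$sphere_coords[vl, , drop = FALSE]
      xyz <- sweep(xyz, 2, colMeans(xyz))
      ax <- svd(xyz, nu = 0, nv = 1)$v[, 1]
      proj <- as.numeric(xyz %*% ax)
      cuts <- cut(proj, breaks = seq(min(proj), max(proj), length.out = k + 1),
                  include.lowest = TRUE, labels = FALSE)
      groups <- split(vl, cuts)
      if (length(groups) < k) {
        warning("parcel ", b, ": ", k - length(groups),
                " empty sub-interval(s) collapsed")
      }
      for (gi in seq_along(groups)) {
        nb <- sprintf("%s.s%d", b, gi)
        verts <- c(verts, list(groups[[gi]]),
                   list(space$mirror_map[groups[[gi]]]))
        base <- c(base, nb, nb)
        hemi <- c(hemi, "lh", "rh")
      }
      plan <- rbind(plan, data.frame(base = b, n_pc = k,
                                     n_subparcels = length(groups)))
    } else {
      if (k > 1) warning("parcel ", b, " smaller than N_PC = ", k,
                         "; not split")
      if (length(il)) { verts <- c(verts, atlas$vertices[il]); base <- c(base, b); hemi <- c(hemi, "lh") }
      if (length(ir)) { verts <- c(verts, atlas$vertices[ir]); base <- c(base, b); hemi <- c(hemi, "rh") }
      plan <- rbind(plan, data.frame(base = b, n_pc = k, n_subparcels = 1L))
    }
  }
  list(parcellation = parcellation(verts, base, hemi, space, kind = "split"),
       plan = plan)
}

#' Sensitivity and specificity of parcels at every vertex
#'
#' From a matrix of representative parcel CTFs (rows = parcels, columns =
#' vertices): a vertex is *sensitive* to a parcel if the parcel's CTF there
#' is at least half of that CTF's maximum anywhere in the brain; the
#' *specificity* z-score of parcel `i` at vertex `v` is
#' `(ctf_i(v) - mean_i ctf_i(v)) / sd_i ctf_i(v)` with the population
#' standard deviation taken across parcels.
#'
#' @param ctf_mat `N_parcel x N_v` matrix of representative CTFs.
#' @return An object of class `ctf_specificity`: `Z` (z-scores, `NA` where
#'   the across-parcel sd is zero), `sensitive` (logical matrix),
#'   `sigma_zero` (per-vertex flag).
#' @export
score_specificity <- function(ctf_mat) {
  M <- as.matrix(ctf_mat)
  if (nrow(M) < 2) stop("need at least 2 parcels")
  rmax <- apply(M, 1, max)
  sensitive <- M >= 0.5 * rmax
  mu <- colMeans(M)
  sg <- sqrt(pmax(0, colMeans(M^2) - mu^2))
  Z <- sweep(M, 2, mu)
  Z <- sweep(Z, 2, ifelse(sg > 0, sg, NA_real_), `/`)
  structure(list(Z = Z, sensitive = sensitive, sigma_zero = sg == 0),
            class = "ctf_specificity")
}

#' Classify vertices as declined, assigned or merge candidates
#'
#' Winner-takes-all on the specificity z-scores: a vertex is *assigned* to
#' the top parcel if that parcel's z-score exceeds `z_thresh` (strict), leads
#' the runner-up by at least `margin`, and the vertex is sensitive to it. If
#' the top two z-scores both exceed `z_thresh` but differ by less than
#' `margin` (and no third parcel is equally close), the vertex is a *merge
#' candidate* for that pair, provided it is sensitive to both. Everything
#' else — including vertices sensitive to no parcel, vertices with zero
#' across-parcel variance, and three-way near-ties — is *declined*.
#'
#' @param table A `ctf_specificity`.
#' @param z_thresh Specificity threshold (default 3).
#' @param margin Winner margin in standard deviations (default 1).
#' @return List of per-vertex vectors: `category` (`"declined"`,
#'   `"assigned"`, `"merge"`), `winner` (parcel index or `NA`), `pair_a`,
#'   `pair_b` (sorted merge-pair indices or `NA`).
#' @export
categorize_vertices <- function(table, z_thresh = 3, margin = 1) {
  stopifnot(inherits(table, "ctf_specificity"))
  Z <- table$Z; sens <- table$sensitive
  nv <- ncol(Z)
  category <- rep("declined", nv)
  winner <- rep(NA_integer_, nv)
  pair_a <- rep(NA_integer_, nv)
  pair_b <- rep(NA_integer_, nv)
  sens_any <- colSums(sens) > 0
  for (v in seq_len(nv)) {
    if (table$sigma_zero[v] || !sens_any[v]) next
    z <- Z[, v]
    i1 <- which.max(z); z1 <- z[i1]
    if (!(z1 > z_thresh)) next
    z[i1] <- -Inf
    i2 <- which.max(z); z2 <- z[i2]
    if (z1 - z2 >= margin) {
      if (sens[i1, v]) { category[v] <- "assigned"; winner[v] <- i1 }
      next
    }
    if (z2 > z_thresh) {
      z[i2] <- -Inf
      z3 <- max(z)
      if (z3 > z_thresh && z1 - z3 < margin) next  # three-way tie: declined
      if (sens[i1, v] && sens[i2, v]) {
        category[v] <- "merge"
        pair_a[v] <- min(i1, i2); pair_b[v] <- max(i1, i2)
      }
    }
  }
  list(category = category, winner = winner, pair_a = pair_a, pair_b = pair_b)
}

#' Cluster merge-candidate vertices into merged parcels
#'
#' One merged parcel per unordered pair of split-parcels with at least one
#' merge-candidate vertex; only clusters at least as large as the smallest
#' split-parcel in the brain are kept. Labels concatenate the pair's labels.
#'
#' @param categories Output of [categorize_vertices()].
#' @param split_parc The `ctf_parcellation` the categories refer to.
#' @return List of merged-parcel descriptors (`base`, `hemisphere`,
#'   `vertices`); empty list when there are no candidates.
#' @export
merge_parcels <- function(categories, split_parc) {
  stopifnot(inherits(split_parc, "ctf_parcellation"))
  idx <- which(categories$category == "merge")
  if (!length(idx)) return(list())
  min_size <- min(lengths(split_parc$vertices))
  key <- paste(categories$pair_a[idx], categories$pair_b[idx])
  out <- list()
  for (k in unique(key)) {
    vs <- idx[key == k]
    if (length(vs) < min_size) next
    ij <- as.integer(strsplit(k, " ")[[1L]])
    hemis <- split_parc$space$hemisphere[vs]
    out[[length(out) + 1L]] <- list(
      base = paste(split_parc$base[ij[1L]], split_parc$base[ij[2L]], sep = "_"),
      hemisphere = names(which.max(table(hemis))),
      vertices = vs)
  }
  out
}

# Reassign vertices to parcels according to the categories: each parcel
# becomes the set of vertices it won; merged parcels are appended. Empty
# parcels are dropped.
apply_categories <- function(parc, categories, merged = list()) {
  verts <- list(); base <- character(0); hemi <- character(0)
  for (p in seq_len(parc$n_parcels)) {
    won <- which(categories$category == "assigned" & categories$winner == p)
    if (!length(won)) next
    verts <- c(verts, list(won))
    base <- c(base, parc$base[p])
    hemi <- c(hemi, parc$hemisphere[p])
  }
  for (m in merged) {
    b <- m$base
    while (any(base == b & hemi == m$hemisphere)) b <- paste0(b, "+")
    verts <- c(verts, list(m$vertices))
    base <- c(base, b)
    hemi <- c(hemi, m$hemisphere)
  }
  if (!length(verts)) stop("empty parcellation: no vertices won or merged")
  parcellation(verts, base, hemi, parc$space, kind = "intermediate")
}

#' Final homogeneity evaluation of a modified parcel list
#'
#' Re-runs the homogeneity step (sensitivity, specificity,
#' winner-takes-all) on the modified parcels' own subject-averaged CTFs,
#' keeps only parcels that win at least `min_vertices` vertices, removes
#' parcels whose PRmat row has an off-diagonal element exceeding the
#' diagonal, and enforces bilateral symmetry: a parcel surviving in only one
#' hemisphere is dropped, and for surviving contralateral pairs the
#' better-covered hemisphere's version is kept and mirrored through the
#' mirror map (overlaps resolved by sequential claim in parcel order,
#' symmetric by construction on mirror-symmetric fixtures).
#'
#' @param parc Intermediate `ctf_parcellation` (split + merged parcels).
#' @param subjects A `ctf_subject_set`.
#' @param min_vertices Minimum number of won vertices for a parcel to
#'   survive (default 10).
#' @param lambda2,z_thresh,margin As elsewhere.
#' @param normalization,rank_tol Passed to [compute_prmat()].
#' @param absR Optional precomputed [subject_abs_resolutions()] list.
#' @return List with `parcellation` (final), `prmat` (its `ctf_prmat`) and
#'   `log` (counts of parcels surviving each step).
#' @export
finalize_parcellation <- function(parc, subjects, min_vertices = 10L,
                                  lambda2 = 1 / 9, z_thresh = 3, margin = 1,
                                  normalization = "per-vertex-share",
                                  rank_tol = 0.05, absR = NULL) {
  stopifnot(inherits(parc, "ctf_parcellation"))
  space <- parc$space
  if (is.null(absR)) absR <- subject_abs_resolutions(subjects, lambda2)
  log <- list(n_input = parc$n_parcels)

  # repeat the homogeneity criterion on the modified list's own CTFs
  cm <- group_parcel_ctfs(parc, subjects, lambda2, absR = absR)
  cats <- categorize_vertices(score_specificity(cm), z_thresh, margin)
  keep <- integer(0); verts <- list()
  for (p in seq_len(parc$n_parcels)) {
    won <- which(cats$category == "assigned" & cats$winner == p)
    if (length(won) >= min_vertices) {
      keep <- c(keep, p)
      verts <- c(verts, list(won))
    }
  }
  if (!length(keep)) stop("empty parcellation: no parcel won ", min_vertices,
                          " vertices")
  parc2 <- parcellation(verts, parc$base[keep], parc$hemisphere[keep], space,
                        kind = "final-eval")
  log$n_win <- parc2$n_parcels

  # PRmat-based removal: row off-diagonal above the diagonal
  pr <- parcellation_prmat(parc2, subjects, lambda2,
                           normalization = normalization, rank_tol = rank_tol,
                           absR = absR)
  P <- pr$PRmat
  dom <- vapply(seq_len(nrow(P)), function(i) {
    off <- P[i, -i]
    !length(off) || max(off) <= P[i, i]
  }, logical(1))
  if (!any(dom)) stop("empty parcellation: all parcels removed by the ",
                      "diagonal-dominance criterion")
  parc3 <- parcellation(parc2$vertices[dom], parc2$base[dom],
                        parc2$hemisphere[dom], space, kind = "final-eval")
  log$n_dominant <- parc3$n_parcels

  # bilateral symmetry: keep the better-covered hemisphere and mirror
  verts <- list(); base <- character(0); hemi <- character(0)
  for (b in unique(parc3$base)) {
    idx <- which(parc3$base == b)
    hset <- parc3$hemisphere[idx]
    if (!all(c("lh", "rh") %in% hset)) next  # single-hemisphere survivor
    sizes <- lengths(parc3$vertices[idx])
    best <- idx[which.max(sizes)]
    own <- parc3$vertices[[best]]
    own <- own[space$hemisphere[own] == parc3$hemisphere[best]]
    if (!length(own)) next
    twin <- space$mirror_map[own]
    if (parc3$hemisphere[best] == "lh") {
      verts <- c(verts, list(own), list(twin)); hemi <- c(hemi, "lh", "rh")
    } else {
      verts <- c(verts, list(twin), list(own)); hemi <- c(hemi, "lh", "rh")
    }
    base <- c(base, b, b)
  }
  if (!length(verts)) stop("empty parcellation: no bilateral parcel pairs survived")
  # sequential claim to restore disjointness after mirroring (symmetric
  # overlaps resolve symmetrically since claims are made pair-wise)
  claimed <- logical(space$n_vertices)
  for (i in seq_along(verts)) {
    v <- verts[[i]][!claimed[verts[[i]]]]
    verts[[i]] <- v
    claimed[v] <- TRUE
  }
  ok <- rep(TRUE, length(verts))
  for (i in seq(1, length(verts), by = 2)) {
    if (length(verts[[i]]) < min_vertices || length(verts[[i + 1]]) < min_vertices) {
      ok[c(i, i + 1)] <- FALSE
    }
  }
  if (!any(ok)) stop("empty parcellation: all mirrored pairs fell below the ",
                     "size threshold")
  final <- parcellation(verts[ok], base[ok], hemi[ok], space, kind = "final")
  log$n_final <- final$n_parcels
  pr_final <- parcellation_prmat(final, subjects, lambda2,
                                 normalization = normalization,
                                 rank_tol = rank_tol, absR = absR)
  list(parcellation = final, prmat = pr_final, log = log)
}

#' Split-and-merge adaptive parcellation
#'
#' Runs the full non-iterative split-and-merge pipeline on an initial atlas:
#' split CTF-heterogeneous parcels, reassign every vertex by CTF sensitivity
#' and specificity, cluster merge candidates into merged parcels, and apply
#' the final homogeneity evaluation (minimum size, PRmat diagonal dominance,
#' bilateral mirror symmetry).
#'
#' @param atlas Initial bilateral `ctf_parcellation`.
#' @param subjects A `ctf_subject_set`.
#' @param variance_threshold Splitting variance fraction (default 0.90).
#' @param z_thresh,margin Specificity thresholds (defaults 3 and 1).
#' @param min_vertices Minimum final parcel size (default 10).
#' @param lambda2 Inverse-operator regularization (default `1/9`).
#' @param normalization,rank_tol Passed to [compute_prmat()].
#' @return An object of class `ctf_parc_fit` with the final `parcellation`,
#'   its `prmat`, the `initial_prmat` of the input atlas, the split `plan`,
#'   and a `log` of parcel counts per stage.
#' @seealso [run_rg()] for the atlas-free region-growing variant.
#' @export
run_sam <- function(atlas, subjects, variance_threshold = 0.9,
                    z_thresh = 3, margin = 1, min_vertices = 10L,
                    lambda2 = 1 / 9, normalization = "per-vertex-share",
                    rank_tol = 0.05) {
  cl <- match.call()
  absR <- subject_abs_resolutions(subjects, lambda2)
  initial_prmat <- parcellation_prmat(atlas, subjects, lambda2,
                                      normalization = normalization,
                                      rank_tol = rank_tol, absR = absR)
  sp <- split_parcels(atlas, subjects, variance_threshold, lambda2,
                      absR = absR)
  cm <- group_parcel_ctfs(sp$parcellation, subjects, lambda2, absR = absR)
  cats <- categorize_vertices(score_specificity(cm), z_thresh, margin)
  merged <- merge_parcels(cats, sp$parcellation)
  intermediate <- apply_categories(sp$parcellation, cats, merged)
  fin <- finalize_parcellation(intermediate, subjects, min_vertices, lambda2,
                               z_thresh, margin, normalization, rank_tol,
                               absR = absR)
  structure(list(parcellation = fin$parcellation, prmat = fin$prmat,
                 initial_prmat = initial_prmat, split_plan = sp$plan,
                 log = c(list(n_initial = atlas$n_parcels,
                              n_split = sp$parcellation$n_parcels,
                              n_merged = length(merged),
                              n_intermediate = intermediate$n_parcels),
                         fin$log),
                 method = "sam",
                 config = list(variance_threshold = variance_threshold,
                               z_thresh = z_thresh, margin = margin,
                               min_vertices = min_vertices, lambda2 = lambda2,
                               normalization = normalization,
                               rank_tol = rank_tol),
                 call = cl),
            class = "ctf_parc_fit")
}
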