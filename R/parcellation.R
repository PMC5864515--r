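# Parcellation container used by atlases, intermediate and final parcellations.

#' Construct a parcellation
#'
#' A parcellation is an ordered list of labelled, pairwise-disjoint vertex
#' sets over a source space. `base` labels are hemisphere-free names used to
#' pair contralateral twins; display labels are `base-lh` / `base-rh`.
#'
#' @param vertices List of integer vertex-index vectors, one per parcel.
#' @param base Character vector of hemisphere-free parcel names.
#' @param hemisphere Character vector (`"lh"`/`"rh"`), one per parcel.
#' @param space The `ctf_source_space` the indices refer to.
#' @param kind Optional tag (e.g. `"anatomical-stand-in"`).
#' @return An object of class `ctf_parcellation` with `labels`, `base`,
#'   `hemisphere`, `vertices`, `space`, `n_parcels`, `coverage` (total number
#'   of vertices covered).
#' @export
parcellation <- function(vertices, base, hemisphere, space, kind = NULL) {
  stopifnot(length(vertices) == length(base),
            length(base) == length(hemisphere))
  vertices <- lapply(vertices, function(v) sort(unique(as.integer(v))))
  all_v <- unlist(vertices)
  if (length(all_v) && (anyDuplicated(all_v) ||
                        min(all_v) < 1 || max(all_v) > space$n_vertices)) {
    stop("parcels must be pairwise disjoint with valid vertex indices")
  }
  labels <- paste0(base, "-", hemisphere)
  if (anyDuplicated(labels)) stop("parcel labels must be unique")
  structure(list(labels = labels, base = as.character(base),
                 hemisphere = as.character(hemisphere),
                 vertices = vertices, space = space,
                 n_parcels = length(vertices),
                 coverage = length(all_v), kind = kind),
            class = "ctf_parcellation")
}

#' @export
print.ctf_parcellation <- function(x, ...) {
  sizes <- lengths(x$vertices)
  cat("Parcellation", if (!is.null(x$kind)) paste0("(", x$kind, ")") else "",
      ": ", x$n_parcels, " parcels, coverage ", x$coverage, "/",
      x$space$n_vertices, " vertices (sizes ",
      if (length(sizes)) paste0(min(sizes), "-", max(sizes)) else "0",
      ")\n", sep = "")
  invisible(x)
}

#' Generate a synthetic atlas on a source space
#'
#' Tiles each hemisphere into spatially contiguous, mirror-symmetric parcels
#' by multi-source breadth-first growth on the vertex adjacency graph from
#' deterministic seed vertices. The `"anatomical-stand-in"` kind covers every
#' vertex (like a whole-cortex anatomical atlas); the
#' `"functional-seed-stand-in"` kind grows each parcel only a bounded graph
#' radius from its seed, leaving gaps (like a functional seed atlas used to
#' place simulated active nodes).
#'
#' @param space A `ctf_source_space`.
#' @param n_parcels_per_hemisphere Parcels per hemisphere (>= 1); e.g. 34
#'   yields 68 parcels bilaterally.
#' @param kind `"anatomical-stand-in"` or `"functional-seed-stand-in"`.
#' @param seed Integer seed for seed-vertex placement.
#' @param max_radius Graph-growth radius for the functional kind.
#' @return A `ctf_parcellation`.
#' @export
make_atlas <- function(space, n_parcels_per_hemisphere,
                       kind = c("anatomical-stand-in", "functional-seed-stand-in"),
                       seed = 1L, max_radius = 2L) {
  kind <- match.arg(kind)
  k <- n_parcels_per_hemisphere
  nh <- space$n_vertices / 2L
  if (k < 1) stop("n_parcels_per_hemisphere must be >= 1")
  if (k > nh) stop("more parcels than vertices per hemisphere")
  lh_verts <- which(space$hemisphere == "lh")

  assign_lh <- with_seed(seed, {
    seeds <- sample(lh_verts, k)
    lab <- rep(NA_integer_, space$n_vertices)
    depth <- rep(NA_integer_, space$n_vertices)
    lab[seeds] <- seq_len(k)
    depth[seeds] <- 0L
    frontier <- seeds
    while (length(frontier)) {
      nxt <- integer(0)
      for (v in frontier) {
        if (kind == "functional-seed-stand-in" && depth[v] >= max_radius) next
        for (u in space$adjacency[[v]]) {
          if (is.na(lab[u]) && space$hemisphere[u] == "lh") {
            lab[u] <- lab[v]
            depth[u] <- depth[v] + 1L
            nxt <- c(nxt, u)
          }
        }
      }
      frontier <- nxt
    }
    if (kind == "anatomical-stand-in") {
      # guarantee full coverage even if the adjacency graph is disconnected
      left_open <- lh_verts[is.na(lab[lh_verts])]
      if (length(left_open)) {
        d <- as.matrix(stats::dist(space$coords[c(seeds, left_open), , drop = FALSE]))
        d <- d[-seq_len(k), seq_len(k), drop = FALSE]
        lab[left_open] <- apply(d, 1, which.min)
      }
    }
    lab
  })

  base <- sprintf("p%03d", seq_len(k))
  verts_lh <- lapply(seq_len(k), function(i) lh_verts[!is.na(assign_lh[lh_verts]) &
                                                      assign_lh[lh_verts] == i])
  verts_rh <- lapply(verts_lh, function(v) space$mirror_map[v])
  parcellation(c(verts_lh, verts_rh),
               base = c(base, base),
               hemisphere = rep(c("lh", "rh"), each = k),
               space = space, kind = kind)
}
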