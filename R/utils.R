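# Internal helpers shared across modules.

# Run `code` under a temporary RNG state seeded with `seed`; restores the
# caller's RNG stream afterwards so generators are pure functions of
# (config, seed) without clobbering the session.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a child seed from a master seed
#'
#' Deterministic child seeds for independent stages of an experiment; the
#' result stays below `2^31 - 1` so it is a valid integer seed.
#'
#' @param seed Master seed.
#' @param k Stage index.
#' @return Integer seed.
#' @export
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + 1103 * as.double(k)) %% 2147483629)
}

# Deterministic Fibonacci lattice of n points on the unit sphere (or a
# spherical cap of half-angle `cap` radians around the +z pole).
fibonacci_sphere <- function(n, cap = pi) {
  i <- seq_len(n) - 0.5
  z <- 1 - (i / n) * (1 - cos(cap))
  phi <- i * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

# Rotate points so the +z pole maps onto unit vector `pole`.
rotate_pole <- function(pts, pole) {
  pole <- pole / sqrt(sum(pole^2))
  z <- c(0, 0, 1)
  v <- c(z[2] * pole[3] - z[3] * pole[2],
         z[3] * pole[1] - z[1] * pole[3],
         z[1] * pole[2] - z[2] * pole[1])
  s <- sqrt(sum(v^2))
  c_ <- sum(z * pole)
  if (s < 1e-12) {
    if (c_ > 0) return(pts)
    return(cbind(pts[, 1], -pts[, 2], -pts[, 3]))
  }
  vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  rot <- diag(3) + vx + vx %*% vx * ((1 - c_) / s^2)
  pts %*% t(rot)
}

# Symmetric k-nearest-neighbour adjacency (list of integer vectors) for the
# row-points of `coords`, restricted within groups given by `group`.
knn_adjacency <- function(coords, k = 6L, group = NULL) {
  n <- nrow(coords)
  if (is.null(group)) group <- rep(1L, n)
  adj <- vector("list", n)
  for (g in unique(group)) {
    idx <- which(group == g)
    d <- as.matrix(stats::dist(coords[idx, , drop = FALSE]))
    diag(d) <- Inf
    kk <- min(k, length(idx) - 1L)
    for (a in seq_along(idx)) {
      nb <- idx[order(d[a, ])[seq_len(kk)]]
      adj[[idx[a]]] <- nb
    }
  }
  # symmetrise
  for (v in seq_len(n)) {
    for (u in adj[[v]]) {
      if (!(v %in% adj[[u]])) adj[[u]] <- sort(c(adj[[u]], v))
    }
  }
  lapply(adj, function(x) sort(unique(as.integer(x))))
}

# Connected components of the subgraph induced by `subset` (BFS).
graph_components <- function(adj, subset = seq_along(adj)) {
  subset <- as.integer(subset)
  comp <- integer(0)
  lab <- stats::setNames(rep(NA_integer_, length(subset)), subset)
  cur <- 0L
  inset <- logical(length(adj))
  inset[subset] <- TRUE
  for (s in subset) {
    key <- as.character(s)
    if (!is.na(lab[key])) next
    cur <- cur + 1L
    queue <- s
    lab[key] <- cur
    while (length(queue)) {
      v <- queue[1L]
      queue <- queue[-1L]
      for (u in adj[[v]]) {
        if (inset[u] && is.na(lab[as.character(u)])) {
          lab[as.character(u)] <- cur
          queue <- c(queue, u)
        }
      }
    }
  }
  list(n = cur, membership = lab)
}

upper_tri_pairs <- function(n) {
  which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
}

#' Number of possible undirected connections among parcels
#'
#' For a parcellation with `n` parcels treated as network nodes there are
#' `n * (n - 1) / 2` possible undirected edges; e.g. 68 parcels admit 2278.
#'
#' @param n Number of parcels (nodes).
#' @return Integer count of unordered node pairs.
#' @export
n_possible_pairs <- function(n) {
  stopifnot(n >= 0)
  as.integer(round(n * (n - 1) / 2))
}

#' Percentage improvement of an index over a reference value
#'
#' Relative gain `100 * (value - reference) / reference`, the form in which
#' gains of the sensitivity and distinguishability indices of a modified
#' parcellation over its initial atlas are usually quoted.
#'
#' @param reference Baseline index value (non-zero).
#' @param value Improved index value.
#' @return Percentage gain (not rounded).
#' @export
percent_improvement <- function(reference, value) {
  stopifnot(reference != 0)
  100 * (value - reference) / reference
}
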