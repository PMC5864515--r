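# Scoring of network reconstruction: baseline correction, max-statistic
# permutation tests, ground truth with missed-connection accounting, and
# TPR/FPR.

# Upper-triangular edge matrix (n_subj x n_edge) from a subject stack
# (n_subj x p x p). Returns list(values, pairs).
stack_edges <- function(stack) {
  d <- dim(stack)
  stopifnot(length(d) == 3, d[2] == d[3])
  pr <- upper_tri_pairs(d[2])
  vals <- matrix(0, d[1], nrow(pr))
  for (s in seq_len(d[1])) {
    m <- stack[s, , ]
    vals[s, ] <- m[pr]
  }
  list(values = vals, pairs = pr)
}

#' Baseline-correct a subject stack of connectivity matrices
#'
#' Per subject, the mean absolute off-diagonal connectivity is subtracted
#' from the absolute value of every element, so connection strengths are
#' distributed around zero and suitable for one-tailed permutation testing.
#'
#' @param stack `n_subj x p x p` array of connectivity matrices.
#' @return Array of the same shape; diagonals set to zero; each subject's
#'   corrected off-diagonal mean is exactly zero.
#' @export
baseline_correct <- function(stack) {
  d <- dim(stack)
  stopifnot(length(d) == 3, d[2] == d[3], d[1] >= 2)
  out <- stack
  off <- row(matrix(0, d[2], d[3])) != col(matrix(0, d[2], d[3]))
  for (s in seq_len(d[1])) {
    m <- abs(stack[s, , ])
    m <- m - mean(m[off])
    diag(m) <- 0
    out[s, , ] <- m
  }
  out
}

#' Max-statistic sign-flip permutation test on network edges
#'
#' One-sample, one-tailed test of whether edges are consistently above
#' baseline across subjects. The null distribution of the maximum statistic
#' across edges is built from random sign flips of the per-subject corrected
#' values, which controls the family-wise error across all edges; an edge is
#' significant if its corrected p-value — the add-one-corrected share of
#' max-null draws at least as large as its observed statistic — is at most
#' `alpha`.
#'
#' @param stack Baseline-corrected `n_subj x p x p` array (>= 6 subjects for
#'   reasonable permutation resolution).
#' @param n_perm Number of permutations (default 10000).
#' @param alpha Family-wise level (default 0.05).
#' @param seed Integer seed (permutations are deterministic given the seed).
#' @param stat `"mean"` (default) or `"t"` (one-sample t statistic).
#' @return An object of class `ctf_edge_test`: `significant` (edge indices),
#'   `pairs` (edge index to node pair), `observed`, `pvalues` (family-wise
#'   corrected), `threshold` (critical max-null order statistic), `alpha`,
#'   `n_perm`.
#' @export
permutation_test <- function(stack, n_perm = 10000L, alpha = 0.05, seed = 1L,
                             stat = c("mean", "t")) {
  stat <- match.arg(stat)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (n_perm < 100) warning("n_perm < 100 gives a coarse max-null")
  ed <- stack_edges(stack)
  E <- ed$values
  ns <- nrow(E)
  if (ns < 6) warning("fewer than 6 subjects: permutation resolution is low")
  edge_stat <- function(M) {
    m <- colMeans(M)
    if (stat == "mean") return(m)
    s <- sqrt(pmax(colMeans(M^2) - m^2, 0) * ns / (ns - 1))
    ifelse(s > 0, m / (s / sqrt(ns)), 0)
  }
  obs <- edge_stat(E)
  maxnull <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    flips <- sample(c(-1, 1), ns, replace = TRUE)
    max(edge_stat(E * flips))
  }, numeric(1)))
  # corrected p-value per edge: share of max-null draws at least as extreme
  # (with the add-one convention that keeps the test exact)
  pvalues <- vapply(obs, function(o) {
    (1 + sum(maxnull >= o)) / (1 + n_perm)
  }, numeric(1))
  thr <- sort(maxnull, decreasing = TRUE)[max(1L, floor(alpha * (n_perm + 1)))]
  structure(list(significant = which(pvalues <= alpha), pairs = ed$pairs,
                 observed = obs, pvalues = pvalues, threshold = thr,
                 alpha = alpha, n_perm = as.integer(n_perm), stat = stat),
            class = "ctf_edge_test")
}

#' @export
print.ctf_edge_test <- function(x, ...) {
  cat("Max-statistic permutation test:", length(x$significant),
      "significant edge(s) of", length(x$observed),
      sprintf("(alpha %.3g, %d permutations)\n", x$alpha, x$n_perm))
  invisible(x)
}

#' Ground-truth edges of a parcellation for a simulated network
#'
#' Runs the identical baseline-correction and permutation pipeline on the
#' no-leakage connectivity stack to obtain the "true significant
#' connectivity" of the parcellation, and counts active nodes with no
#' vertex overlap with the parcellation together with their incident
#' effective connections as *missed* (a sparse parcellation cannot recover
#' them; they enter the true-positive denominator).
#'
#' @param noleak_stack `n_subj x p x p` connectivity stack computed from the
#'   no-leakage dataset with the same parcellation.
#' @param spec The `ctf_network_spec` of the simulated network (or `NULL`
#'   for a null network).
#' @param parc The `ctf_parcellation` under test.
#' @param n_perm,alpha,seed,stat Passed to [permutation_test()].
#' @return List: `true_edges` (edge indices), `pairs`, `n_true`,
#'   `missed_nodes` (active-node indices), `n_missed_connections`.
#' @export
ground_truth_edges <- function(noleak_stack, spec, parc, n_perm = 10000L,
                               alpha = 0.05, seed = 1L, stat = "mean") {
  test <- permutation_test(baseline_correct(noleak_stack), n_perm = n_perm,
                           alpha = alpha, seed = seed, stat = stat)
  covered <- sort(unique(unlist(parc$vertices)))
  if (is.null(spec)) {
    missed_nodes <- integer(0)
    n_missed <- 0L
  } else {
    missed_nodes <- which(vapply(spec$an_vertices, function(v) {
      !any(v %in% covered)
    }, logical(1)))
    n_missed <- if (length(missed_nodes) && nrow(spec$effective)) {
      sum(spec$effective[, 1] %in% missed_nodes |
            spec$effective[, 2] %in% missed_nodes)
    } else 0L
  }
  list(true_edges = test$significant, pairs = test$pairs,
       n_true = length(test$significant),
       missed_nodes = missed_nodes,
       n_missed_connections = as.integer(n_missed))
}

#' Score a detected edge set against ground truth
#'
#' `TPR = |detected intersect true| / (|true| + missed connections)` and
#' `FPR = |detected \ true| / (n(n-1)/2 - |true|)`. Undefined rates (zero
#' denominators) are returned as `NA`.
#'
#' @param detected Integer edge indices detected in the realistic network.
#' @param truth Output of [ground_truth_edges()].
#' @param n_parcels Number of parcels (network nodes).
#' @return An object of class `ctf_score`: `TPR`, `FPR`, `n_true`
#'   (including missed), `n_missed_connections`, `n_possible_pairs`,
#'   `n_detected`.
#' @export
score_edges <- function(detected, truth, n_parcels) {
  npairs <- n_possible_pairs(n_parcels)
  n_true <- truth$n_true
  n_missed <- truth$n_missed_connections
  tp <- length(intersect(detected, truth$true_edges))
  fp <- length(setdiff(detected, truth$true_edges))
  tpr <- if (n_true + n_missed > 0) tp / (n_true + n_missed) else NA_real_
  fpr <- if (npairs - n_true > 0) fp / (npairs - n_true) else NA_real_
  structure(list(TPR = tpr, FPR = fpr,
                 n_true = n_true + n_missed,
                 n_missed_connections = n_missed,
                 n_possible_pairs = npairs,
                 n_detected = length(detected)),
            class = "ctf_score")
}

#' @export
print.ctf_score <- function(x, ...) {
  cat(sprintf("Network score: TPR = %s, FPR = %s (%d detected, %d true incl. %d missed, %d possible pairs)\n",
              format(x$TPR, digits = 3), format(x$FPR, digits = 3),
              x$n_detected, x$n_true, x$n_missed_connections,
              x$n_possible_pairs))
  invisible(x)
}
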