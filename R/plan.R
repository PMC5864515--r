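# Experiment planning and the end-to-end simulation driver.

#' Enumerate a factorial simulation design
#'
#' Crosses the number of active nodes, the percentage of effective
#' connections and the SNR over the requested repetitions, with each
#' combination simulated in two scenarios (no-leakage ground truth and
#' leakage), plus a set of null-network repetitions. The canonical design —
#' seeds {3, 5, 10, 15} x connection percentages {25, 50, 100} x SNR
#' {1, 3} x 36 repetitions x 2 scenarios + 36 null networks — enumerates
#' 1764 datasets. Every entry carries a seed derived deterministically from
#' the master seed.
#'
#' @param n_seeds Numbers of active nodes.
#' @param pct_connections Connection percentages.
#' @param snr SNR levels.
#' @param repetitions Random datasets per cell (default 36).
#' @param null_repetitions Null-network datasets (default 36).
#' @param master_seed Master seed.
#' @return An object of class `ctf_experiment_plan`: data frame with
#'   `scenario`, `n_seeds`, `pct`, `snr`, `rep`, `seed`.
#' @export
plan_experiment <- function(n_seeds = c(3, 5, 10, 15),
                            pct_connections = c(25, 50, 100),
                            snr = c(1, 3), repetitions = 36L,
                            null_repetitions = 36L, master_seed = 1L) {
  if (repetitions < 1 || null_repetitions < 0) stop("invalid repetition counts")
  grid <- expand.grid(rep = seq_len(repetitions), snr = snr,
                      pct = pct_connections, n_seeds = n_seeds,
                      KEEP.OUT.ATTRS = FALSE)
  plan <- rbind(
    data.frame(scenario = "no-leakage", grid[, c("n_seeds", "pct", "snr", "rep")]),
    data.frame(scenario = "leakage", grid[, c("n_seeds", "pct", "snr", "rep")]))
  if (null_repetitions > 0) {
    plan <- rbind(plan, data.frame(scenario = "null", n_seeds = 0, pct = 0,
                                   snr = NA_real_,
                                   rep = seq_len(null_repetitions)))
  }
  rownames(plan) <- NULL
  # the leakage scenario reuses the matching no-leakage network's seed
  key <- with(plan, paste(n_seeds, pct, snr, rep))
  plan$seed <- derive_seed(master_seed, match(key, unique(key)))
  structure(plan, class = c("ctf_experiment_plan", "data.frame"))
}

#' @export
print.ctf_experiment_plan <- function(x, ...) {
  cat("Experiment plan:", nrow(x), "datasets (",
      sum(x$scenario == "no-leakage"), "no-leakage,",
      sum(x$scenario == "leakage"), "leakage,",
      sum(x$scenario == "null"), "null )\n")
  invisible(x)
}

#' Run the simulation-reconstruction-scoring pipeline
#'
#' Executes simulate -> (project) -> reconstruct -> score for every
#' repetition of a (reduced) experiment plan, for each candidate
#' parcellation. No-leakage and leakage scenarios of the same cell share
#' the simulated network; the no-leakage reconstruction defines the ground
#' truth.
#'
#' @param plan A `ctf_experiment_plan` (typically reduced in size).
#' @param subjects A `ctf_subject_set`.
#' @param parcellations Named list of `ctf_parcellation` objects to score.
#' @param seed_atlas Functional-seed `ctf_parcellation` for node placement.
#' @param metric `"coh"` or `"imcoh"`.
#' @param n_perm,alpha Permutation-test settings.
#' @param lambda2 Inverse-operator regularization.
#' @param n_epochs,sample_rate Epoching of the simulated data.
#' @param verbose Print progress lines?
#' @return Data frame with one row per (parcellation x plan cell):
#'   scenario, condition, TPR, FPR, counts.
#' @export
run_pipeline <- function(plan, subjects, parcellations, seed_atlas,
                         metric = "coh", n_perm = 1000L, alpha = 0.05,
                         lambda2 = 1 / 9, n_epochs = 40L, sample_rate = 250,
                         verbose = FALSE) {
  stopifnot(inherits(plan, "ctf_experiment_plan"),
            is.list(parcellations), length(names(parcellations)) > 0)
  space <- subjects$space
  rows <- list()

  nets <- plan[plan$scenario == "no-leakage", , drop = FALSE]
  for (i in seq_len(nrow(nets))) {
    cell <- nets[i, ]
    basis <- make_basis(cell$n_seeds, n_epochs = n_epochs,
                        sample_rate = sample_rate, seed = cell$seed)
    spec <- make_network(cell$n_seeds, cell$pct, cell$snr, seed_atlas,
                         seed = cell$seed)
    clean <- synthesize(spec, basis, space, n_subjects = subjects$n_subjects,
                        seed = derive_seed(cell$seed, 11L))
    leaky <- project_leakage(clean, subjects, lambda2 = lambda2)
    for (pn in names(parcellations)) {
      parc <- parcellations[[pn]]
      st_clean <- connectivity_stack(clean, parc, metric = metric)
      st_leaky <- connectivity_stack(leaky, parc, metric = metric)
      truth <- ground_truth_edges(st_clean, spec, parc, n_perm = n_perm,
                                  alpha = alpha, seed = derive_seed(cell$seed, 13L))
      det <- permutation_test(baseline_correct(st_leaky), n_perm = n_perm,
                              alpha = alpha,
                              seed = derive_seed(cell$seed, 17L))$significant
      sc <- score_edges(det, truth, parc$n_parcels)
      rows[[length(rows) + 1L]] <- data.frame(
        parcellation = pn, scenario = "leakage", n_seeds = cell$n_seeds,
        pct = cell$pct, snr = cell$snr, rep = cell$rep,
        TPR = sc$TPR, FPR = sc$FPR, n_true = sc$n_true,
        n_missed = sc$n_missed_connections, n_detected = sc$n_detected)
      if (verbose) message("cell ", i, " parcellation ", pn, " done")
    }
  }

  nulls <- plan[plan$scenario == "null", , drop = FALSE]
  for (i in seq_len(nrow(nulls))) {
    cell <- nulls[i, ]
    ds <- make_null(subjects, n_epochs = n_epochs, sample_rate = sample_rate,
                    seed = cell$seed, lambda2 = lambda2)
    for (pn in names(parcellations)) {
      parc <- parcellations[[pn]]
      st <- connectivity_stack(ds, parc, metric = metric)
      det <- permutation_test(baseline_correct(st), n_perm = n_perm,
                              alpha = alpha,
                              seed = derive_seed(cell$seed, 17L))$significant
      rows[[length(rows) + 1L]] <- data.frame(
        parcellation = pn, scenario = "null", n_seeds = 0, pct = 0,
        snr = NA_real_, rep = cell$rep, TPR = NA_real_,
        FPR = length(det) / n_possible_pairs(parc$n_parcels),
        n_true = 0L, n_missed = 0L, n_detected = length(det))
      if (verbose) message("null ", i, " parcellation ", pn, " done")
    }
  }
  do.call(rbind, rows)
}
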