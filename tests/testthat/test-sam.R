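# helper: a specificity table built directly from z-score columns
spec_table <- function(Z, sens = NULL) {
  if (is.null(sens)) sens <- matrix(TRUE, nrow(Z), ncol(Z))
  structure(list(Z = Z, sensitive = sens,
                 sigma_zero = rep(FALSE, ncol(Z))),
            class = "ctf_specificity")
}

test_that("across-subject harmonization takes the mode, minimum on ties", {
  expect_equal(ctfparc:::mode_min(c(2L, 2L, 3L)), 2L)
  expect_equal(ctfparc:::mode_min(c(1L, 1L, 2L, 2L)), 1L)
  expect_equal(ctfparc:::mode_min(c(4L)), 4L)
})

test_that("splitting keeps homogeneous parcels and splits two-pattern parcels", {
  sp <- make_source_space(8, seed = 5)
  # parcel a: identical gain columns; parcel b: two orthogonal equal-energy
  # patterns -> one component explains only 50% of the CTF variance
  G <- matrix(0, 6, 16)
  G[1, 1:4] <- 1                      # a-lh
  G[2, 5:6] <- 1; G[3, 7:8] <- 1      # b-lh
  G[4, 9:12] <- 1                     # a-rh
  G[5, 13:14] <- 1; G[6, 15:16] <- 1  # b-rh
  subs <- manual_subject_set(sp, list(G))
  atlas <- parcellation(list(1:4, 5:8, 9:12, 13:16),
                        base = c("a", "b", "a", "b"),
                        hemisphere = c("lh", "lh", "rh", "rh"), space = sp)
  out <- split_parcels(atlas, subs, lambda2 = 1e-6)
  expect_equal(out$plan$n_pc[out$plan$base == "a"], 1L)
  expect_equal(out$plan$n_pc[out$plan$base == "b"], 2L)
  expect_equal(out$plan$n_subparcels[out$plan$base == "b"], 2L)
  # parcel a survives unchanged, parcel b becomes two contiguous sub-parcels
  labs <- out$parcellation$base
  expect_true("a" %in% labs)
  expect_equal(sum(grepl("^b\\.s", labs)) / 2, 2)  # two sub-parcels per hemisphere
  # mirrored split: each lh sub-parcel has an rh twin of equal size
  for (b in unique(labs)) {
    idx <- which(labs == b)
    expect_length(idx, 2)
    expect_setequal(sp$mirror_map[out$parcellation$vertices[[idx[1]]]],
                    out$parcellation$vertices[[idx[2]]])
  }
})

test_that("specificity z-scores follow the population formula", {
  cm <- matrix(c(10, 1, 1), 3, 1)   # three parcels at one vertex
  tbl <- score_specificity(cbind(cm, cm))   # need >=2 columns for matrix shape
  expect_equal(tbl$Z[1, 1], (10 - 4) / sqrt(18), tolerance = 1e-12)
  expect_equal(tbl$Z[1, 1], 1.414214, tolerance = 1e-6)
  # one-hot column of length N gives z = sqrt(N - 1) for the hot parcel
  for (N in c(5, 11, 16)) {
    one <- matrix(0, N, 2); one[3, ] <- 1
    tb <- score_specificity(one)
    expect_equal(tb$Z[3, 1], sqrt(N - 1), tolerance = 1e-10)
  }
  # constant column: flagged zero-variance
  tb0 <- score_specificity(matrix(1, 4, 3))
  expect_true(all(tb0$sigma_zero))
})

test_that("vertex categories implement winner-takes-all with margin", {
  Z <- cbind(c(5, 2, 0), c(4, 3.5, 0), c(2.9, 2.8, 0),
             c(4, 3.5, 3.2), c(5, 2, 0))
  sens <- matrix(TRUE, 3, 5)
  sens[1, 5] <- FALSE                      # winner not sensitive
  cats <- categorize_vertices(spec_table(Z, sens))
  expect_equal(cats$category, c("assigned", "merge", "declined",
                                "declined", "declined"))
  expect_equal(cats$winner[1], 1L)
  expect_equal(c(cats$pair_a[2], cats$pair_b[2]), c(1L, 2L))
  # three-way near-tie declined (column 4); insensitive winner declined (5)
})

test_that("merge candidates cluster per pair and respect the size floor", {
  sp <- make_source_space(10, seed = 6)
  split_parc <- parcellation(list(1:3, 4:6, 7:9),
                             base = c("A", "B", "C"),
                             hemisphere = rep("lh", 3), space = sp)
  n <- sp$n_vertices
  cats <- list(category = rep("declined", n),
               winner = rep(NA_integer_, n),
               pair_a = rep(NA_integer_, n), pair_b = rep(NA_integer_, n))
  expect_length(merge_parcels(cats, split_parc), 0)
  # pair (A,B) with 4 vertices (>= smallest split-parcel, 3) and pair (A,C)
  # with 3; both kept, disjoint by construction
  idx_ab <- 11:14; idx_ac <- 15:17
  cats$category[c(idx_ab, idx_ac)] <- "merge"
  cats$pair_a[idx_ab] <- 1L; cats$pair_b[idx_ab] <- 2L
  cats$pair_a[idx_ac] <- 1L; cats$pair_b[idx_ac] <- 3L
  m <- merge_parcels(cats, split_parc)
  expect_length(m, 2)
  expect_setequal(vapply(m, `[[`, character(1), "base"), c("A_B", "A_C"))
  expect_length(intersect(m[[1]]$vertices, m[[2]]$vertices), 0)
  # a 2-vertex cluster falls below the smallest split-parcel and is dropped
  cats$category[idx_ac[3]] <- "declined"
  m2 <- merge_parcels(cats, split_parc)
  expect_setequal(vapply(m2, `[[`, character(1), "base"), "A_B")
})

test_that("finalize keeps an identity-resolution toy intact", {
  sp <- make_source_space(8, seed = 7)
  subs <- manual_subject_set(sp, list(diag(16)))
  parc <- parcellation(as.list(1:16),
                       base = rep(sprintf("v%02d", 1:8), 2),
                       hemisphere = rep(c("lh", "rh"), each = 8), space = sp)
  fin <- finalize_parcellation(parc, subs, min_vertices = 1L, lambda2 = 0)
  expect_equal(fin$parcellation$n_parcels, 16L)
  expect_equal(unname(fin$prmat$PRmat), diag(16), tolerance = 1e-10)
  expect_equal(fin$prmat$S_ind, 1)
})

test_that("the split-and-merge pipeline yields a valid, reproducible parcellation", {
  subs <- fix_parc_subjects()
  atlas <- fix_parc_atlas()
  fit <- suppressWarnings(run_sam(atlas, subs))
  parc <- fit$parcellation
  sp <- parc$space
  # disjoint, min size, exact mirror symmetry
  expect_false(anyDuplicated(unlist(parc$vertices)) > 0)
  expect_true(all(lengths(parc$vertices) >= 10))
  for (b in unique(parc$base)) {
    idx <- which(parc$base == b)
    expect_length(idx, 2)
    expect_setequal(sp$mirror_map[parc$vertices[[idx[1]]]],
                    parc$vertices[[idx[2]]])
    expect_equal(length(parc$vertices[[idx[1]]]),
                 length(parc$vertices[[idx[2]]]))
  }
  # row-diagonal dominance of the final PRmat
  P <- fit$prmat$PRmat
  for (i in seq_len(nrow(P))) {
    expect_true(all(P[i, i] >= P[i, -i]))
  }
  # counting: final <= split + merged
  expect_lte(fit$log$n_final, fit$log$n_split + fit$log$n_merged)
  # determinism
  fit2 <- suppressWarnings(run_sam(atlas, subs))
  expect_identical(fit$parcellation$vertices, fit2$parcellation$vertices)
  expect_identical(fit$parcellation$labels, fit2$parcellation$labels)
  expect_equal(fit$prmat$PRmat, fit2$prmat$PRmat)
})
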