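test_that("single-vertex and rank-1 parcels give the expected representative CTF", {
  set.seed(20)
  R <- matrix(rnorm(25), 5, 5)
  # singleton: normalized |CTF| row
  pc <- parcel_ctf(R, 3)
  expect_equal(pc$ctf_p, abs(R[3, ]) / sqrt(sum(R[3, ]^2)), tolerance = 1e-12)
  # identical rows: proportional to that row, first component explains all
  R2 <- rbind(abs(R[1, ]), abs(R[1, ]), abs(R[1, ]))
  pc2 <- parcel_ctf(R2, 1:3)
  expect_equal(pc2$ctf_p, abs(R[1, ]) / sqrt(sum(R[1, ]^2)), tolerance = 1e-10)
  expect_equal(pc2$explained_variance[1], 1, tolerance = 1e-12)
  expect_error(parcel_ctf(R, integer(0)), "empty parcel")
})

test_that("representative CTF matches an eigendecomposition oracle", {
  set.seed(21)
  M <- matrix(abs(rnorm(2 * 7)), 2, 7)
  pc <- parcel_ctf(rbind(M, matrix(0, 1, 7)), 1:2)
  ev <- eigen(t(M) %*% M, symmetric = TRUE)$vectors[, 1]
  if (sum(ev) < 0) ev <- -ev
  expect_equal(pc$ctf_p, ev, tolerance = 1e-8)
  expect_equal(sum(pc$ctf_p^2), 1, tolerance = 1e-12)
  expect_true(all(pc$ctf_p >= 0))
})

test_that("identity resolution with singleton parcels gives an identity PRmat", {
  sp <- make_source_space(8, seed = 1)
  parc <- parcellation(as.list(1:16),
                       base = rep(sprintf("v%02d", 1:8), 2),
                       hemisphere = rep(c("lh", "rh"), each = 8), space = sp)
  cm <- diag(16)           # each parcel's ctf is its own one-hot vector
  pr <- compute_prmat(cm, parc)
  expect_equal(unname(pr$PRmat), diag(16), tolerance = 1e-12)
  expect_equal(pr$S_ind, 1)
  expect_equal(pr$D_ind, 1)
  expect_equal(pr$rank, 16L)
  expect_equal(pr$cond, 1)
})

test_that("PRmat equals a nested-loop double-normalization oracle", {
  sp <- make_source_space(8, seed = 2)
  verts <- list(c(1, 2, 9), c(3, 4, 5), c(6, 10, 11))
  parc <- parcellation(verts, base = c("a", "b", "c"),
                       hemisphere = c("lh", "lh", "rh"), space = sp)
  set.seed(22)
  cm <- matrix(abs(rnorm(3 * 16)), 3, 16)
  pr <- compute_prmat(cm, parc)
  oracle <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3) {
    kj <- verts[[j]]
    shares <- vapply(kj, function(k) cm[i, k] / sum(cm[, k]), numeric(1))
    oracle[i, j] <- mean(shares)
  }
  expect_equal(unname(pr$PRmat), oracle, tolerance = 1e-12)
  # column-stochastic
  expect_equal(unname(colSums(pr$PRmat)), rep(1, 3), tolerance = 1e-12)
  expect_true(all(pr$PRmat >= 0 & pr$PRmat <= 1))
})

test_that("zero-CTF vertices are excluded from the PRmat means", {
  sp <- make_source_space(8, seed = 2)
  parc <- parcellation(list(c(1, 2), c(3, 4)), base = c("a", "b"),
                       hemisphere = c("lh", "lh"), space = sp)
  cm <- matrix(0, 2, 16)
  cm[1, 1] <- 1; cm[2, 3] <- 1       # vertices 2 and 4 have zero total mass
  pr <- compute_prmat(cm, parc)
  expect_equal(unname(pr$PRmat), diag(2))
  expect_equal(pr$n_zero_vertices, 2L)
})

test_that("sensitivity and distinguishability indices follow their definitions", {
  expect_equal(sensitivity_index(diag(5)), 1)
  expect_equal(sensitivity_index(matrix(c(0.8, 0.3, 0.2, 0.7), 2, 2)), 0.75)
  set.seed(23)
  P <- matrix(runif(36), 6, 6)
  expect_equal(sensitivity_index(P), sum(diag(P)) / 6)
  expect_equal(distinguishability_index(diag(4)), 1)
  expect_true(is.na(distinguishability_index(matrix(0.3, 4, 4))))
  P5 <- matrix(runif(25), 5, 5)
  expect_equal(distinguishability_index(P5),
               stats::cor(as.numeric(P5), as.numeric(diag(5))))
})

test_that("rank uses the heuristic tolerance and cond the full spectrum", {
  rc <- prmat_rank_cond(diag(70))
  expect_equal(rc$rank, 70L)
  expect_equal(rc$cond, 1)
  v <- rep(1, 6) / sqrt(6)
  expect_equal(prmat_rank_cond(outer(v, v))$rank, 1L)
  # constructed singular values {1, 0.1, 0.04} at tol 0.05
  set.seed(24)
  Q <- qr.Q(qr(matrix(rnorm(9), 3)))
  M <- Q %*% diag(c(1, 0.1, 0.04)) %*% t(Q)
  rc2 <- prmat_rank_cond(M, tol = 0.05)
  expect_equal(rc2$rank, 2L)
  expect_equal(rc2$cond, 25, tolerance = 1e-8)
  rc0 <- prmat_rank_cond(matrix(0, 3, 3))
  expect_equal(rc0$rank, 0L)
  expect_true(is.infinite(rc0$cond))
})

test_that("PRmat and its indices are invariant to global gain scaling", {
  sp <- fix_space()
  sen <- fix_sensors()
  lf <- make_leadfield(sp, sen)
  lf2 <- leadfield(lf$G * 37, sp, sen)
  cov <- make_noise_cov(sen$n_sensors, seed = 3)
  atlas <- fix_atlas()
  pr1 <- local({
    R <- abs(resolution_matrix(mne_operator(lf, cov))$R)
    cm <- t(vapply(atlas$vertices, function(v) parcel_ctf(R, v)$ctf_p,
                   numeric(sp$n_vertices)))
    compute_prmat(cm, atlas)
  })
  pr2 <- local({
    R <- abs(resolution_matrix(mne_operator(lf2, cov))$R)
    cm <- t(vapply(atlas$vertices, function(v) parcel_ctf(R, v)$ctf_p,
                   numeric(sp$n_vertices)))
    compute_prmat(cm, atlas)
  })
  expect_equal(pr1$PRmat, pr2$PRmat, tolerance = 1e-8)
  expect_equal(pr1$S_ind, pr2$S_ind, tolerance = 1e-8)
  expect_equal(pr1$D_ind, pr2$D_ind, tolerance = 1e-8)
})

test_that("distinguishability does not increase with heavier regularization", {
  sp <- fix_space()
  sen <- fix_sensors()
  atlas <- fix_atlas()
  dind <- vapply(c(0.01, 1, 100), function(l2) {
    ds <- vapply(1:5, function(s) {
      subs <- make_subject_set(1, sp, sen, perturbation_scale = 0.1, seed = s)
      parcellation_prmat(atlas, subs, lambda2 = l2)$D_ind
    }, numeric(1))
    mean(ds)
  }, numeric(1))
  expect_true(all(diff(dind) <= 1e-6))
})
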