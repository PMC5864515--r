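test_that("basis frequencies tile the band with inclusive endpoints", {
  b <- make_basis(3, seed = 1)
  expect_equal(b$frequencies, c(10, 25, 40))
  expect_equal(make_basis(1, seed = 1)$frequencies, 10)
  expect_equal(make_basis(7, seed = 1)$frequencies, seq(10, 40, by = 5))
  expect_error(make_basis(3, sample_rate = 100), "110")
  b2 <- make_basis(3, seed = 1)
  expect_identical(b$phases, b2$phases)
  # epoch clock: 182 samples at 250 Hz, 31 pre-stimulus
  expect_length(b$t, 182)
  expect_equal(sum(b$t < 0), 31)
  expect_equal(max(b$t), 0.6)
})

test_that("random epoch phases keep distinct basis functions incoherent", {
  # phasor-average oracle: E|mean of N_e unit phasors|^2 = 1/N_e
  b <- make_basis(2, n_epochs = 40, seed = 3)
  msc <- replicate(30, {
    s <- derive_seed(sample.int(1e6, 1), 1)
    bb <- make_basis(2, n_epochs = 40, seed = s)
    ph <- bb$phases[, 1] - bb$phases[, 2]
    Mod(mean(exp(1i * ph)))^2
  })
  expect_lt(mean(msc), 0.15)
  expect_equal(mean(msc), 1 / 40, tolerance = 0.6)
})

test_that("mixing matrices hit the requested effective connection count", {
  out <- make_A(3, 100, seed = 2)
  expect_equal(diag(out$A), rep(1, 3))
  expect_equal(nrow(out$effective), 3L)
  # indirect connectivity through a common third source
  A <- diag(3); A[1, 3] <- 1; A[2, 3] <- 1
  eff <- ctfparc:::effective_pairs(A)
  expect_true(any(eff[, 1] == 1 & eff[, 2] == 2))
  # brute-force row-intersection oracle across random draws
  for (n in c(4, 6)) for (pct in c(25, 50, 100)) {
    out <- make_A(n, pct, seed = n * pct)
    target <- round(pct / 100 * n * (n - 1) / 2)
    oracle <- 0L
    for (j in seq_len(n - 1)) for (k in (j + 1):n) {
      if (sum(out$A[j, ] * out$A[k, ]) > 0) oracle <- oracle + 1L
    }
    expect_equal(nrow(out$effective), target)
    expect_equal(oracle, target)
  }
  expect_error(make_A(3, 0), "pct_connections")
})

test_that("synthesized datasets reach the requested SNR", {
  sp <- fix_space()
  fatlas <- make_atlas(sp, 8, "functional-seed-stand-in", seed = 11)
  achieved <- vapply(1:25, function(r) {
    b <- make_basis(3, n_epochs = 10, seed = r)
    net <- make_network(3, 100, snr = 3, fatlas, seed = r)
    ds <- synthesize(net, b, sp, seed = r)
    post <- ds$t >= 0
    an <- unlist(net$an_vertices)
    noise_v <- setdiff(seq_len(sp$n_vertices), an)[1:20]
    sd_noise <- stats::sd(ds$subject_tc[[1]][, noise_v, ])
    # noiseless signal RMS re-measured from a fresh noise-free synthesis
    net_inf <- net; net_inf$snr <- Inf
    clean <- synthesize(net_inf, b, sp, seed = r)
    rms <- sqrt(mean(clean$subject_tc[[1]][, an, post]^2))
    (rms / sd_noise) / 3
  }, numeric(1))
  expect_lt(max(abs(achieved - 1)), 0.05)
})

test_that("noiseless shared-basis nodes are perfectly coherent at the basis frequency", {
  sp <- fix_space()
  fatlas <- make_atlas(sp, 8, "functional-seed-stand-in", seed = 11)
  b <- make_basis(2, n_epochs = 20, seed = 4)
  net <- make_network(2, 100, snr = Inf, fatlas, seed = 5)
  ds <- synthesize(net, b, sp, seed = 6)
  v1 <- net$an_vertices[[1]][1]; v2 <- net$an_vertices[[2]][1]
  tc <- array(0, dim = c(20, 2, length(ds$t)))
  tc[, 1, ] <- ds$subject_tc[[1]][, v1, ]
  tc[, 2, ] <- ds$subject_tc[[1]][, v2, ]
  con <- spectral_connectivity(tc, t = ds$t, sample_rate = 250, metric = "coh")
  shared <- which(rowSums(net$A) > 1)
  f <- b$frequencies[which(net$A[1, ] * net$A[2, ] > 0)][1]
  fbin <- which.min(abs(con$freqs - f))
  expect_gt(con$per_bin[1, 2, fbin], 0.99)
})

test_that("leakage projection is linear and harmless for identity resolution", {
  sp <- make_source_space(8, seed = 4)
  subs <- manual_subject_set(sp, list(diag(16)))
  arr <- array(stats::rnorm(3 * 16 * 20), dim = c(3, 16, 20))
  ds <- structure(list(subject_tc = list(arr), t = seq(-0.1, by = 1 / 250,
                                                       length.out = 20),
                       sample_rate = 250, scenario = "no-leakage",
                       spec = NULL, noise_sd = 1), class = "ctf_simdata")
  out <- project_leakage(ds, subs, lambda2 = 0)
  expect_equal(out$subject_tc[[1]], arr, tolerance = 1e-10)
  # linearity with a genuine (blurring) subject set
  subs2 <- fix_subjects(2)
  mk <- function(seed) {
    a <- array(stats::rnorm(2 * 120 * 2 * 10, sd = 1), dim = c(2, 240, 10))
    structure(list(subject_tc = list(a, a * 0.5), t = seq_len(10) / 250,
                   sample_rate = 250, scenario = "no-leakage", spec = NULL,
                   noise_sd = 1), class = "ctf_simdata")
  }
  x <- mk(1); y <- mk(2)
  z <- x; z$subject_tc <- Map(function(a, b) 2 * a + 3 * b,
                              x$subject_tc, y$subject_tc)
  pz <- project_leakage(z, subs2)
  px <- project_leakage(x, subs2); py <- project_leakage(y, subs2)
  expect_equal(pz$subject_tc[[1]],
               2 * px$subject_tc[[1]] + 3 * py$subject_tc[[1]],
               tolerance = 1e-8)
})

test_that("leakage spreads a single active node along its CTF support", {
  sp <- fix_space()
  subs <- fix_subjects(2)
  fatlas <- make_atlas(sp, 8, "functional-seed-stand-in", seed = 11)
  b <- make_basis(1, n_epochs = 6, seed = 4)
  net <- make_network(1, 100, snr = Inf, fatlas, seed = 5)
  ds <- synthesize(net, b, sp, n_subjects = 2, seed = 6)
  out <- project_leakage(ds, subs)
  an <- net$an_vertices[[1]]
  energy <- rowMeans(out$subject_tc[[1]][1, , ]^2)
  outside <- setdiff(seq_len(sp$n_vertices), an)
  expect_gt(max(energy[outside]), 0)
  # energy concentrates where the AN's averaged CTF support lies
  Ravg <- average_abs_resolution(subs)
  ctf_an <- colMeans(Ravg[an, , drop = FALSE])
  expect_gt(stats::cor(energy, ctf_an, method = "spearman"), 0.4)
})

test_that("null datasets carry no ground-truth connections", {
  subs <- fix_subjects(2)
  ds <- make_null(subs, n_epochs = 4, seed = 9)
  expect_identical(ds$scenario, "null")
  expect_null(ds$spec)
  expect_length(ds$subject_tc, 2)
  expect_equal(dim(ds$subject_tc[[1]]), c(4, 240, 182))
  tr <- ground_truth_edges(
    connectivity_stack(structure(list(subject_tc = ds$subject_tc[c(1, 2, 1, 2, 1, 2)],
                                      t = ds$t, sample_rate = 250,
                                      scenario = "null", spec = NULL,
                                      noise_sd = 1), class = "ctf_simdata"),
                       make_atlas(subs$space, 4, seed = 2)),
    spec = NULL, parc = make_atlas(subs$space, 4, seed = 2),
    n_perm = 300, seed = 1)
  expect_equal(tr$n_missed_connections, 0L)
})
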