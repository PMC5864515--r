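test_that("source space has exact mirror symmetry and valid geometry", {
  sp <- make_source_space(8, "sphere-patch", seed = 1)
  expect_equal(sp$n_vertices, 16L)
  # involution and x-negation pairing
  expect_equal(sp$mirror_map[sp$mirror_map], seq_len(16))
  expect_equal(sp$coords[sp$mirror_map, 1], -sp$coords[, 1])
  expect_equal(sp$coords[sp$mirror_map, 2:3], sp$coords[, 2:3])
  expect_equal(sum(sp$hemisphere == "lh"), sum(sp$hemisphere == "rh"))
  # unit normals
  expect_equal(sqrt(rowSums(sp$normals^2)), rep(1, 16), tolerance = 1e-12)
  # symmetric adjacency
  for (v in seq_len(16)) {
    for (u in sp$adjacency[[v]]) expect_true(v %in% sp$adjacency[[u]])
  }
})

test_that("source space generation is deterministic in the seed", {
  a <- make_source_space(20, "two-lobe", seed = 11)
  b <- make_source_space(20, "two-lobe", seed = 11)
  c <- make_source_space(20, "two-lobe", seed = 12)
  expect_identical(a$coords, b$coords)
  expect_identical(a$normals, b$normals)
  expect_false(identical(a$coords, c$coords))
})

test_that("adjacency is connected within each hemisphere (graph oracle)", {
  skip_if_not_installed("igraph")
  sp <- make_source_space(100, "two-lobe", seed = 7)
  for (h in c("lh", "rh")) {
    expect_equal(oracle_components(sp$adjacency, which(sp$hemisphere == h)), 1L)
  }
})

test_that("invalid vertex counts are rejected", {
  expect_error(make_source_space(4), "must be an integer >= 8")
  expect_error(make_source_space(10.5), "must be an integer >= 8")
})

test_that("leadfield construction validates geometry and entries", {
  sp <- fix_space()
  inside <- make_sensors(16, radius = 10)
  expect_error(make_leadfield(sp, inside), "outside the source surface")
  expect_error(leadfield(rbind(c(0, 0), c(1, 2))), "all-zero sensor row")
  expect_error(leadfield(rbind(c(NA, 1), c(1, 2))), "finite")
})

test_that("narrow gaussian-spread gain has one dominant entry per column", {
  sp <- make_source_space(30, "two-lobe", seed = 2, jitter = 0)
  sen <- make_sensors(60, radius = 90)
  lf <- make_leadfield(sp, sen, model = "gaussian-spread", spread = 2)
  ratio <- apply(lf$G, 2, function(g) max(g) / sum(g))
  expect_gt(median(ratio), 0.5)
})

test_that("deeper sources have smaller gain-column norms", {
  sp <- make_source_space(200, "two-lobe", seed = 5)
  sen <- make_sensors(64)
  for (model in c("dipole-in-sphere", "gaussian-spread")) {
    lf <- make_leadfield(sp, sen, model = model)
    depth <- apply(sp$coords, 1, function(p) {
      min(sqrt(colSums((t(sen$positions) - p)^2)))
    })
    norms <- sqrt(colSums(lf$G^2))
    expect_lt(stats::cor(depth, norms, method = "spearman"), -0.8)
  }
})

test_that("leadfield generation is deterministic", {
  sp <- fix_space()
  sen <- fix_sensors()
  expect_identical(make_leadfield(sp, sen)$G, make_leadfield(sp, sen)$G)
})

test_that("noise covariance is symmetric positive definite after loading", {
  nc <- make_noise_cov(24, seed = 4)
  expect_equal(nc$C, t(nc$C))
  expect_gt(min(eigen(nc$C, symmetric = TRUE, only.values = TRUE)$values), 0)
  expect_identical(make_noise_cov(24, seed = 4)$C, nc$C)
})

test_that("zero perturbation gives bitwise-identical subjects", {
  sp <- fix_space()
  sen <- fix_sensors()
  ss <- make_subject_set(3, sp, sen, perturbation_scale = 0, seed = 5)
  expect_identical(ss$subjects[[1]]$leadfield$G, ss$subjects[[2]]$leadfield$G)
  expect_identical(ss$subjects[[2]]$leadfield$G, ss$subjects[[3]]$leadfield$G)
  expect_identical(ss$subjects[[1]]$mapping, seq_len(sp$n_vertices))
})

test_that("subject mappings are mirror-consistent permutations", {
  ss <- fix_subjects()
  sp <- ss$space
  for (s in ss$subjects) {
    expect_setequal(s$mapping, seq_len(sp$n_vertices))
    # mirror of mapped vertex = mapped mirror, exhaustively
    expect_equal(sp$mirror_map[s$mapping], s$mapping[sp$mirror_map])
  }
  expect_error(make_subject_set(2, sp, fix_sensors(), perturbation_scale = 0.9),
               "perturbation_scale")
})

test_that("anatomical atlas tiles each hemisphere with contiguous mirror parcels", {
  skip_if_not_installed("igraph")
  sp <- fix_space()
  atlas <- make_atlas(sp, 34, "anatomical-stand-in", seed = 1)
  expect_equal(atlas$n_parcels, 68L)
  expect_setequal(unlist(atlas$vertices), seq_len(sp$n_vertices))
  for (p in seq_len(atlas$n_parcels)) {
    expect_equal(oracle_components(sp$adjacency, atlas$vertices[[p]]), 1L)
  }
  # mirror twins: same base, mirrored vertex sets
  for (b in unique(atlas$base)) {
    idx <- which(atlas$base == b)
    expect_length(idx, 2L)
    expect_setequal(sp$mirror_map[atlas$vertices[[idx[1]]]],
                    atlas$vertices[[idx[2]]])
  }
})

test_that("functional atlas leaves gaps but stays contiguous", {
  skip_if_not_installed("igraph")
  sp <- fix_space()
  atlas <- make_atlas(sp, 6, "functional-seed-stand-in", seed = 9)
  expect_lt(atlas$coverage, sp$n_vertices)
  for (p in seq_len(atlas$n_parcels)) {
    expect_equal(oracle_components(sp$adjacency, atlas$vertices[[p]]), 1L)
  }
  expect_error(make_atlas(sp, 500), "more parcels than vertices")
})
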