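# Shared fixtures, built lazily once per test run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(expr)
  .fixtures[[name]]
}

# small geometry for unit tests
fix_space <- function() fixture("space", make_source_space(120, "two-lobe", seed = 3))
fix_sensors <- function() fixture("sensors", make_sensors(32))
fix_subjects <- function(n = 3) {
  fixture(paste0("subjects", n),
          make_subject_set(n, fix_space(), fix_sensors(),
                           perturbation_scale = 0.1, seed = 7))
}
fix_atlas <- function() fixture("atlas", make_atlas(fix_space(), 6, seed = 2))

# mid-size fixture on which SaM/RG complete with the default thresholds
fix_parc_space <- function() fixture("pspace", make_source_space(500, "two-lobe", seed = 3))
fix_parc_sensors <- function() fixture("psensors", make_sensors(64))
fix_parc_subjects <- function() {
  fixture("psubjects",
          make_subject_set(5, fix_parc_space(), fix_parc_sensors(),
                           perturbation_scale = 0.1, seed = 7))
}
fix_parc_atlas <- function() fixture("patlas", make_atlas(fix_parc_space(), 6, seed = 2))

# independent graph-component oracle built on igraph
oracle_components <- function(adjacency, subset) {
  edges <- do.call(rbind, lapply(subset, function(v) {
    nb <- intersect(adjacency[[v]], subset)
    if (length(nb)) cbind(v, nb) else NULL
  }))
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(edges[, 1]), to = as.character(edges[, 2])),
    directed = FALSE,
    vertices = data.frame(name = as.character(subset)))
  igraph::components(g)$no
}

# hand-built subject set with explicit gain matrices (bypasses the synthetic
# generators; used for identity-resolution scenarios)
manual_subject_set <- function(space, G_list, mapping_list = NULL, cov = NULL) {
  n <- length(G_list)
  subs <- lapply(seq_len(n), function(i) {
    list(leadfield = leadfield(G_list[[i]], space),
         cov = cov,
         mapping = if (is.null(mapping_list)) seq_len(space$n_vertices) else mapping_list[[i]])
  })
  structure(list(subjects = subs, space = space, sensors = NULL,
                 n_subjects = n, perturbation_scale = 0, seed = NA),
            class = "ctf_subject_set")
}
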