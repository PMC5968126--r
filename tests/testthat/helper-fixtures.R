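# lazily built, session-cached expensive fixtures shared across test files
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# small atlas for unit tests (642 vertices per chamber)
small_atlas <- function() fixture("small_atlas", function() {
  suppressWarnings(build_atlas(atlas_config(subdiv = 3, torso_nodes = 1500),
                               rng_seed = 2))
})

# full-size study atlas (2562 vertices per chamber) used by acceptance tests
study_atlas <- function() fixture("study_atlas", function() {
  build_atlas(atlas_config(subdiv = 4, torso_nodes = 14157), rng_seed = 1)
})

study_library <- function() fixture("study_library", function() {
  build_case_library(surface_domain(study_atlas(), "LA"), rng_base = 100)
})

study_template <- function() fixture("study_template", function() {
  pace_single_cell(myocyte_params("LA"), bcl = 500, n_beats = 20,
                   sample_dt = 1)
})

study_leadfield <- function() fixture("study_leadfield", function() {
  a <- study_atlas()
  layout <- reduce_electrodes(a, 256, rng_seed = 1)
  list(layout = layout,
       lf = build_lead_field(a, a$torso$verts[layout$representatives, ]))
})

study_features <- function(model) fixture(paste0("feat_", model), function() {
  a <- study_atlas()
  ds <- build_dataset(a, study_library(), model)
  X <- bspim_features(ds, study_leadfield()$lf, study_template(),
                      rng_seed = 1000)
  list(dataset = ds, X = X)
})

study_graph <- function() fixture("study_graph", function() {
  ectopic_graph(study_atlas())
})
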