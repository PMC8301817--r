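# Shared fixtures. The standard dataset and its all-vs-all hit table are
# comparatively expensive, so they are built once per test run.

small_params <- function(...) {
  synth_params(n_families = 2L, family_sizes = c(3L, 3L), n_species = 3L,
               seed = 11L, ...)
}

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

default_dataset <- function() {
  cached("default_dataset", generate_family_dataset(synth_params()))
}

default_hits <- function() {
  cached("default_hits", all_vs_all(default_dataset()$proteins))
}

default_graph <- function() {
  cached("default_graph", {
    ds <- default_dataset()
    prot <- dedupe_strains(ds$proteins)
    bh <- best_hits_per_species(default_hits(), prot)
    build_bbh_graph(bh, nodes = prot$protein_id)
  })
}
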