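# Shared fixtures, built once per test run and cached.
.fixture_cache <- new.env(parent = emptyenv())

# A small cohort for module-level tests: quick to generate and score.
small_cohort <- function() {
  if (is.null(.fixture_cache$small)) {
    spec <- synthetic_cohort_spec(n_studies = 3L, samples_per_study = 10L,
                                  n_genes = 400L, n_pathways = 10L,
                                  genes_per_pathway = c(10L, 20L),
                                  n_informative = 2L, seed = 11L)
    .fixture_cache$small <- generate_cohort(spec)
  }
  .fixture_cache$small
}

# The default study-scale cohort pipeline run, shared by several acceptance
# checks (planted-signal recovery, support recovery, PDS fidelity, leakage).
acceptance_run <- function() {
  if (is.null(.fixture_cache$run)) {
    cfg <- pipeline_config(synthetic = synthetic_cohort_spec(seed = 1L),
                           seed = 1L)
    .fixture_cache$run <- run_pipeline(cfg)
  }
  .fixture_cache$run
}

# Deterministic toy expression matrix with named dimensions.
toy_matrix <- function(nr = 4, nc = 3, seed = 5) {
  set.seed(seed)
  m <- matrix(rnorm(nr * nc, mean = 8), nr, nc,
              dimnames = list(paste0("g", seq_len(nr)),
                              paste0("s", seq_len(nc))))
  m
}
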