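# Shared synthetic cohorts, built once per test run and cached. Seeds are
# fixed so every statistic asserted downstream is reproducible.

.cohorts <- new.env(parent = emptyenv())

cohort_fixture <- function(name, build) {
  if (is.null(.cohorts[[name]])) {
    dir <- file.path(tempdir(), paste0("fi_", name))
    sim <- build()
    write_bundle(sim, dir)
    .cohorts[[name]] <- list(sim = sim, dir = dir)
  }
  .cohorts[[name]]
}

planted_cohort <- function() {
  cohort_fixture("planted", function()
    simulate_cohort(sim_config(n_genes = 2000, seed = 2025)))
}

null_cohort <- function() {
  cohort_fixture("null", function()
    simulate_cohort(sim_config(n_genes = 1000, seed = 2026, null = TRUE)))
}

small_cohort <- function() {
  cohort_fixture("small", function()
    simulate_cohort(sim_config(n_genes = 100, seed = 2029,
                               n_overlap_genes = 3)))
}

pipeline_result <- function(name, cohort) {
  key <- paste0("res_", name)
  if (is.null(.cohorts[[key]])) {
    .cohorts[[key]] <- run_pipeline(run_config(bundle_dir = cohort$dir))
  }
  .cohorts[[key]]
}
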