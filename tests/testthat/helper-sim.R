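# Shared simulation fixtures, built once per test run.

.sim_cache <- new.env(parent = emptyenv())

# the default study-condition simulation plus its pipeline results
default_sim <- function() {
  if (is.null(.sim_cache$sim))
    .sim_cache$sim <- simulate_genomes(simulation_config(seed = 11L))
  .sim_cache$sim
}

default_pipeline <- function() {
  if (is.null(.sim_cache$res))
    .sim_cache$res <- run_pipeline(default_sim())
  .sim_cache$res
}

# a small, fast simulation for module-level checks
small_config <- function(...) {
  defaults <- list(n_proto = 2L, genes_per_chrom = 60L,
                   wgd_times = list(shared = 60),
                   fusion_plan = list(),
                   inversion_rate = 0.02, tandem_rate = 0.01,
                   pav_rate = 0.01, seed = 3L)
  dots <- list(...)
  defaults[names(dots)] <- dots
  do.call(simulation_config, defaults)
}
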