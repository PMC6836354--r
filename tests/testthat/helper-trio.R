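# The default synthetic trio and its full pipeline run are shared by
# several test files; compute them once per test session.
trio_cache <- new.env(parent = emptyenv())

get_trio <- function() {
  if (is.null(trio_cache$sim)) trio_cache$sim <- simulate_trio(sim_config(seed = 101))
  trio_cache$sim
}

get_scan <- function() {
  if (is.null(trio_cache$scan)) {
    sim <- get_trio()
    trio_cache$scan <- cms_scan(sim$genomes$cms, sim$genomes$recipient,
                                sim$genomes$donor, verbose = FALSE)
  }
  trio_cache$scan
}
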