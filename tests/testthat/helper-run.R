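# One shared end-to-end run of the default synthetic study (seed 1), reused
# across test files to keep the suite fast.
.seflow_test_cache <- new.env(parent = emptyenv())

default_run <- function() {
  if (is.null(.seflow_test_cache$run))
    .seflow_test_cache$run <- run_pipeline(simulation_config(seed = 1))
  .seflow_test_cache$run
}
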