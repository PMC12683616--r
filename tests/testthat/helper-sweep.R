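# Shared mini-sweep for the frequency-response checks: a 50 x 50 m domain,
# 300-year runs, 20 Sobol' parameter sets, both risk models at the low and
# high ends of the frequency sweep. Computed once per test run and cached.

.sweep_cache <- new.env(parent = emptyenv())

mini_sweep_results <- function() {
  if (!is.null(.sweep_cache$res)) {
    return(.sweep_cache$res)
  }
  traits <- gen_species(seed = 42)
  forcing <- gen_forcing(seed = 42)
  binned <- gen_binned_mortality(n_per_cell = 10000, seed = 42)
  paramsets <- sobol_sample(20)
  manifest <- lambda_sweep_manifest(c(9, 23), paramsets, base_seed = 42)
  res <- lapply(c(CLLR = "CLLR", SSLR = "SSLR"), function(mode) {
    cfg <- default_config(domain = list(width = 50, length = 50),
                          duration_yr = 300L, avg_window_yr = 50L,
                          mode = mode)
    # small-d members can have zero-observed cells in the calibration
    suppressWarnings(run_sweep(manifest, cfg, traits = traits,
                               forcing = forcing, binned = binned))
  })
  .sweep_cache$res <- res
  res
}
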