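# Lazily computed, cached cohort analyses shared by the cohort-level tests:
# the same 20-seed study conditions are examined from several angles, so the
# pipeline runs once per seed.

cohort_cache_env <- new.env(parent = emptyenv())

cohort_run <- function(seed, n_flux_samples = 500L) {
  key <- sprintf("seed_%d_%d", seed, n_flux_samples)
  if (!is.null(cohort_cache_env[[key]])) return(cohort_cache_env[[key]])
  model <- make_toy_model()
  cfg <- cohort_config(seed = seed)
  sim <- simulate_expression(model, cfg)
  resp <- simulate_respirometry(cfg)
  res <- analyze_cohort(model, sim$expr, sim$groups, respirometry = resp,
                        n_flux_samples = n_flux_samples, seed = seed)
  out <- list(model = model, config = cfg, sim = sim, resp = resp, res = res)
  cohort_cache_env[[key]] <- out
  out
}
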