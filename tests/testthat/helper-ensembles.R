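# Shared simulation ensembles, computed once per test run.

.ens_cache <- new.env(parent = emptyenv())

cached <- function(key, fn) {
  if (!exists(key, envir = .ens_cache)) assign(key, fn(), envir = .ens_cache)
  get(key, envir = .ens_cache)
}

wt_ensemble <- function(n = 500L, matp = TRUE) {
  key <- paste0("wt_", n, "_", matp)
  cached(key, function()
    run_replicas(chromosome_config(matp_active = matp), loop_params(),
                 n_replicas = n, base_seed = if (matp) 1000L else 21000L))
}

uni_ensemble <- function(n = 500L) {
  cached(paste0("uni_", n), function()
    run_replicas(chromosome_config(),
                 loop_params(directionality = "unidirectional"),
                 n_replicas = n, base_seed = 41000L))
}

# increased-occupancy ensemble at the experimentally inferred bound count
# (110 total x 6.3-fold overexpression x 25.4% bound ~ 176 bound complexes)
io_ensemble <- function(n = 200L) {
  cached(paste0("io_", n), function() {
    target <- occupancy_report()$io_bound
    N <- cached("io_copy_number", function()
      calibrate_copy_number(target, n_pilot = 40L, base_seed = 61000L))
    run_replicas(chromosome_config(), loop_params(n_total = N),
                 n_replicas = n, base_seed = 62000L)
  })
}
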