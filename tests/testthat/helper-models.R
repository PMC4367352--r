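# Shared fixtures, built once per test run. Sizes are kept modest: the cached
# reference histograms feed many tests, and each test's tolerance accounts for
# the Monte Carlo noise at these sizes.

local_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = local_cache)) {
    assign(name, force(expr), envir = local_cache)
  }
  get(name, envir = local_cache)
}

ref_model <- function() cached("ref_model", {
  scaling_model(simulate_reference(mc_config(seed = 910L, n_photons = 1e5),
                                   c_sim = 0.9995), c_sim = 0.9995)
})

slab_model_cached <- function() cached("slab_model", {
  slab_scaling_model(mc_config(seed = 950L, n_photons = 6e4))
})

lib_cached <- function() cached("lib", chromophore_library())

recipe_row <- function(i) {
  r <- validation_phantoms()[i, ]
  class(r) <- class(validation_phantoms())
  r
}

dataset_cached <- function(i, seed = 700L + i) {
  cached(paste0("dataset", i, "_", seed), {
    build_dataset(recipe_row(i), lib_cached(), noise_cv = 0.01, seed = seed,
                  method = "scaling", model = ref_model())
  })
}

chain_cached <- function() cached("chain", {
  run_full_chain(seed = 11L, ref_photons = 2e5, n_photons = 3e4)
})

random_spectrum <- function(n = 25, kind = "fluorescence") {
  w <- sort(runif(n, 380, 600))
  while (any(diff(w) <= 0)) w <- sort(runif(n, 380, 600))
  spectrum(w, runif(n, 0.01, 1), kind = kind)
}

random_ctx <- function(egrid = emission_grid(5)) {
  n <- length(egrid)
  R0x <- runif(1, 0.6, 0.99)
  R0m <- runif(1, 0.6, 0.99)
  fluor_context(
    emission_grid_nm = egrid,
    R_x = runif(1, 0.05, 1) * R0x,
    R_m = runif(n, 0.05, 1) * R0m,
    R0_x = R0x, R0_m = R0m,
    mus_x_per_cm = runif(1, 1, 200),
    g_x = runif(1, 0.5, 0.98), g_m = runif(n, 0.5, 0.98),
    l_cm = runif(1, 0.1, 2), S = runif(1, 0.2, 3))
}
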