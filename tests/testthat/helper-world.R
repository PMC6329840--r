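# Small study worlds shared across test files. Sizes are chosen so a single
# file runs in seconds while keeping >= 20 decadal blocks for GEV fits.

tiny_world <- function(seed = 1, ...) {
  args <- list(nlat = 4, nlon = 4, pop_nlat = 12, pop_nlon = 12,
               n_countries = 9, years = 200, seed = seed)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(world_config, args)
}

tiny_run_config <- function(seed = 1, ...) {
  args <- list(seed = seed, n_models = 2, model_shapes = list(c(4, 4)),
               years = 200, pop_shape = c(12, 12), n_countries = 9,
               compute_ad = FALSE, compute_ci = FALSE, compute_tx5x = FALSE,
               min_unique = 8)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(run_config, args)
}

# One year of synthetic daily Tmax with a few prescribed heatwaves
flat_year <- function(base = 20) rep(base, 365)
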