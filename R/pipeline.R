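#' Configuration of a full pipeline run
#'
#' Fixes the scenario grid ({1.5 degC, 2 degC} x {SSP1, SSP4} x {present,
#' 2075-analog}), the synthetic multi-model ensemble and every analysis
#' default. The return period is configurable (`T = 100` gives the HW100Y
#' variant).
#'
#' @param seed Master seed; every stage derives its own seed from it.
#' @param n_models Number of synthetic climate models.
#' @param model_shapes List of `c(nlat, nlon)` per model (recycled).
#' @param years Ensemble years per climate state (multiple of 10).
#' @param pop_shape Native population/country raster shape.
#' @param n_countries Number of synthetic countries.
#' @param T Return period in blocks (decades); 500 is the headline event.
#' @param block_length Block length in years.
#' @param min_blocks Minimum blocks for a GEV fit.
#' @param min_unique Minimum unique values for a Johnson normalization fit.
#' @param compute_ad,ad_boot Whether / how deeply to bootstrap the
#'   Anderson-Darling goodness-of-fit p-value per cell.
#' @param compute_ci Whether to compute profile-likelihood intervals for the
#'   present return level per cell.
#' @param compute_tx5x Whether to compute the TX5x validation hazard.
#' @param hazard_breaks,iri_breaks Bin edges of the exposure tables (hazard:
#'   per-decade probabilities; IRI: 10-percentage-point classes).
#' @param ... Further arguments passed to [world_config()] (warming offsets,
#'   noise bands, population and HDI settings).
#' @return List of class `run_config`.
#' @export
run_config <- function(seed = 1L, n_models = 2,
                       model_shapes = list(c(9, 9), c(12, 12)),
                       years = 500, pop_shape = c(36, 36), n_countries = 36,
                       T = 500, block_length = 10, min_blocks = 20,
                       min_unique = 30,
                       compute_ad = TRUE, ad_boot = 200,
                       compute_ci = TRUE, compute_tx5x = TRUE,
                       hazard_breaks = c(0, 0.002, 0.005, 0.01, 0.02, 0.05,
                                         0.1, 0.2, 0.5, 1),
                       iri_breaks = seq(0, 100, by = 10), ...) {
  extra <- list(...)
  cfg <- list(seed = as.integer(seed), n_models = n_models,
              model_shapes = model_shapes, years = years,
              pop_shape = pop_shape, n_countries = n_countries,
              T = T, block_length = block_length, min_blocks = min_blocks,
              min_unique = min_unique,
              compute_ad = compute_ad, ad_boot = ad_boot,
              compute_ci = compute_ci, compute_tx5x = compute_tx5x,
              hazard_breaks = hazard_breaks, iri_breaks = iri_breaks,
              world_args = extra)
  class(cfg) <- "run_config"
  cfg
}

.model_world_config <- function(cfg, m) {
  shp <- cfg$model_shapes[[(m - 1L) %% length(cfg$model_shapes) + 1L]]
  do.call(world_config, c(list(
    nlat = shp[1], nlon = shp[2],
    pop_nlat = cfg$pop_shape[1], pop_nlon = cfg$pop_shape[2],
    n_countries = cfg$n_countries, years = cfg$years,
    model = m, seed = cfg$seed), cfg$world_args))
}

#' Generate the shared socioeconomic inputs and per-model configurations
#'
#' The native-grid population fields, HDI table and country raster are
#' shared by all synthetic climate models (they derive from the master seed
#' only); each model gets its own [world_config()] whose climate noise seed
#' is offset by the model index.
#'
#' @param cfg A [run_config()].
#' @return List with `native` (grid, population fields, HDI, country raster,
#'   present global population) and `model_configs`.
#' @export
generate_world_inputs <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  model_configs <- lapply(seq_len(cfg$n_models), .model_world_config, cfg = cfg)
  w0 <- model_configs[[1]]
  hdi <- generate_hdi(w0)
  pop_present <- generate_population(w0, "present")
  native <- list(
    grid = w0$pop_grid,
    pop_present = pop_present,
    pop_future = list(SSP1 = generate_population(w0, "future", "SSP1"),
                      SSP4 = generate_population(w0, "future", "SSP4")),
    hdi = hdi,
    present_total = sum(pop_present * cell_areas(w0$pop_grid))
  )
  list(native = native, model_configs = model_configs)
}

#' Heatwave hazard analysis for one synthetic climate model
#'
#' Runs the hazard chain for one model: generate the three climate states,
#' build the present-climate threshold climatology and reference quartiles,
#' compute annual HWMId (and optionally TX5x), take decadal block maxima,
#' fit the shape-constrained GEV per cell, and evaluate the present
#' `T`-block return level together with its exceedance probability under the
#' warmed states. Cells whose block-maxima series is degenerate are masked.
#'
#' @param wcfg A [world_config()] for the model.
#' @param cfg The [run_config()].
#' @return List with per-cell vectors/matrices: `fits` (per state), `z_T`
#'   (present return level), `hazard` (probabilities per state; present is
#'   `1/T` at fitted cells), `hwmid_bm`, plus optional `ad_p`, `ci`,
#'   `tx5x_hazard`, and the `grid`.
#' @export
model_hazard <- function(wcfg, cfg) {
  states <- c("present", "1.5C", "2C")
  g <- wcfg$grid
  ncell <- g$nlat * g$nlon

  tmax_present <- generate_climate(wcfg, "present")
  thresholds <- compute_thresholds(tmax_present)
  quart <- reference_quartiles(tmax_present)

  hw_bm <- list(); tx_bm <- list()
  for (s in states) {
    tm <- if (s == "present") tmax_present else generate_climate(wcfg, s)
    hw <- annual_index_series(tm, thresholds, quart, "hwmid")
    hw_bm[[s]] <- block_maxima(hw, cfg$block_length)
    if (cfg$compute_tx5x) {
      tx <- annual_index_series(tm, thresholds, index = "tx5x")
      tx_bm[[s]] <- block_maxima(tx, cfg$block_length)
    }
    if (s != "present") rm(tm)
  }
  rm(tmax_present)

  fits <- lapply(hw_bm, fit_gev_cells, min_blocks = cfg$min_blocks)
  fitted <- !vapply(fits$present, is.null, logical(1))
  z_T <- rep(NA_real_, ncell)
  z_T[fitted] <- vapply(fits$present[fitted], return_level, numeric(1),
                        T = cfg$T)
  hazard <- list(
    present = ifelse(fitted, 1 / cfg$T, NA_real_),
    `1.5C` = hazard_under_state(fits$present, fits$`1.5C`, cfg$T),
    `2C` = hazard_under_state(fits$present, fits$`2C`, cfg$T)
  )

  out <- list(grid = g, fits = fits, fitted = fitted, z_T = z_T,
              hazard = hazard, hwmid_bm = hw_bm)

  if (cfg$compute_tx5x) {
    tx_fits <- lapply(tx_bm, fit_gev_cells, min_blocks = cfg$min_blocks)
    out$tx5x_hazard <- list(
      `1.5C` = hazard_under_state(tx_fits$present, tx_fits$`1.5C`, cfg$T),
      `2C` = hazard_under_state(tx_fits$present, tx_fits$`2C`, cfg$T))
  }
  if (cfg$compute_ad) {
    set.seed(wcfg$climate_seed + 1L)
    out$ad_p <- vapply(seq_len(ncell), function(c)
      ad_test_gev(hw_bm$present[, c], cfg$ad_boot, cfg$min_blocks)$p_value,
      numeric(1))
  }
  if (cfg$compute_ci) {
    ci <- lapply(seq_len(ncell), function(c) {
      if (!fitted[c]) return(list(lower = NA_real_, upper = NA_real_))
      confidence_interval(hw_bm$present[, c], cfg$T,
                          min_blocks = cfg$min_blocks)
    })
    out$ci <- list(lower = vapply(ci, `[[`, numeric(1), "lower"),
                   upper = vapply(ci, `[[`, numeric(1), "upper"))
  }
  out
}

#' Exposure, vulnerability and risk analysis for one model
#'
#' Remaps the native population and HDI fields onto the model grid
#' (first-order conservative), rasterizes countries (majority-area rule),
#' fits the present-period Johnson normalizations, and builds the normalized
#' and non-normalized IRI fields plus the population-exposure tables for all
#' scenario combinations.
#'
#' @param hz Output of [model_hazard()].
#' @param world Output of [generate_world_inputs()] (its `native` part).
#' @param cfg The [run_config()].
#' @return List with remapped fields, Johnson fits, normalized scores, IRI
#'   fields (`iri$normalized[[warming]][[ssp]]`, `iri$normalized$present`,
#'   same for `nonnormalized`), the HDI class mask, and `tables` (named list
#'   of exposure tables).
#' @export
model_risk <- function(hz, world, cfg) {
  native <- world$native
  g <- hz$grid
  src <- native$grid

  pop <- list(
    present = remap_conservative(native$pop_present, src, g),
    SSP1 = remap_conservative(native$pop_future$SSP1, src, g),
    SSP4 = remap_conservative(native$pop_future$SSP4, src, g))
  tab <- native$hdi$table
  hdi_named <- function(col) stats::setNames(tab[[col]], tab$country_id)
  hdi_f <- list(
    present = remap_conservative(
      hdi_field(hdi_named("hdi_present"), native$hdi$raster), src, g),
    SSP1 = remap_conservative(
      hdi_field(hdi_named("hdi_ssp1_future"), native$hdi$raster), src, g),
    SSP4 = remap_conservative(
      hdi_field(hdi_named("hdi_ssp4_future"), native$hdi$raster), src, g))
  countries <- rasterize_countries(native$hdi$raster, src, g)
  class_mask <- classify_hdi(hdi_named("hdi_present"), countries)

  pop_fit <- fit_johnson(pop$present, "nonnegative",
                         min_unique = cfg$min_unique)
  vuln_fit <- fit_johnson(1 - hdi_f$present, "unit",
                          min_unique = cfg$min_unique)
  pop_score <- lapply(pop, normalize_field, fit = pop_fit)
  vuln_score <- lapply(hdi_f, function(h) normalize_field(1 - h, vuln_fit))

  hzf <- function(s) matrix(hz$hazard[[s]], g$nlat, g$nlon)
  iri <- list(normalized = list(), nonnormalized = list())
  iri$normalized$present <-
    iri_normalized(hzf("present"), pop_score$present, vuln_score$present)
  iri$nonnormalized$present <-
    iri_nonnormalized(hzf("present"), pop$present, 1 - hdi_f$present)
  for (w in c("1.5C", "2C")) {
    iri$normalized[[w]] <- list(); iri$nonnormalized[[w]] <- list()
    for (ssp in c("SSP1", "SSP4")) {
      iri$normalized[[w]][[ssp]] <-
        iri_normalized(hzf(w), pop_score[[ssp]], vuln_score[[ssp]])
      iri$nonnormalized[[w]][[ssp]] <-
        iri_nonnormalized(hzf(w), pop[[ssp]], 1 - hdi_f[[ssp]])
    }
  }

  scopes <- list(global = NULL, low = class_mask == "low",
                 medium = class_mask == "medium",
                 very_high = class_mask == "very_high")
  tables <- list()
  for (w in c("1.5C", "2C")) for (ssp in c("SSP1", "SSP4"))
    for (sc in names(scopes)) {
      tables[[paste("hazard", sc, w, ssp, sep = ".")]] <-
        exposure_distribution(hzf(w), pop[[ssp]], g, cfg$hazard_breaks,
                              native$present_total, scopes[[sc]],
                              sc, ssp, w)
      tables[[paste("iri", sc, w, ssp, sep = ".")]] <-
        exposure_distribution(iri$normalized[[w]][[ssp]], pop[[ssp]], g,
                              cfg$iri_breaks, native$present_total,
                              scopes[[sc]], sc, ssp, w)
    }

  list(pop = pop, hdi = hdi_f, countries = countries,
       class_mask = class_mask, pop_fit = pop_fit, vuln_fit = vuln_fit,
       pop_score = pop_score, vuln_score = vuln_score,
       iri = iri, tables = tables, grid = g)
}

#' Scenario-difference fields of the normalized IRI
#'
#' The four headline contrasts plus the worst-minus-best combination,
#' computed from one representative model's normalized IRI fields.
#'
#' @param iri_norm `risk$iri$normalized` of one model.
#' @return Named list of difference fields.
#' @export
iri_differences <- function(iri_norm) {
  list(
    d_2C_minus_1.5C_SSP1 = scenario_difference(iri_norm$`2C`$SSP1,
                                               iri_norm$`1.5C`$SSP1),
    d_2C_minus_1.5C_SSP4 = scenario_difference(iri_norm$`2C`$SSP4,
                                               iri_norm$`1.5C`$SSP4),
    d_SSP4_minus_SSP1_1.5C = scenario_difference(iri_norm$`1.5C`$SSP4,
                                                 iri_norm$`1.5C`$SSP1),
    d_SSP4_minus_SSP1_2C = scenario_difference(iri_norm$`2C`$SSP4,
                                               iri_norm$`2C`$SSP1),
    d_worst_minus_best = scenario_difference(iri_norm$`2C`$SSP4,
                                             iri_norm$`1.5C`$SSP1)
  )
}

.config_hash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(cfg[setdiff(names(cfg), "world_args")]), f)
  unname(tools::md5sum(f))
}

#' Run the full heatwave-risk pipeline
#'
#' Executes, for every synthetic model: simulate -> heat indices -> block
#' maxima / GEV -> hazard (1.5 degC, 2 degC) -> Johnson normalization ->
#' IRI (normalized and non-normalized; SSP1, SSP4) -> HDI class masks ->
#' exposure and IRI tables; then ensemble summaries across models and the
#' scenario-difference fields from model 1. Deterministic given the config:
#' re-running with the same config reproduces the bundle exactly.
#'
#' @param cfg A [run_config()].
#' @param outdir Optional directory; when given, fields are written as CSV
#'   rasters, tables as CSV, and a JSON run manifest is emitted.
#' @return The result bundle (config, world, per-model results, ensemble
#'   tables, difference fields, manifest), invisibly if `outdir` is used.
#' @export
run_all <- function(cfg, outdir = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  world <- generate_world_inputs(cfg)
  models <- vector("list", cfg$n_models)
  for (m in seq_len(cfg$n_models)) {
    hz <- model_hazard(world$model_configs[[m]], cfg)
    rk <- model_risk(hz, world, cfg)
    models[[m]] <- list(hazard = hz, risk = rk)
  }
  tab_names <- names(models[[1]]$risk$tables)
  ensemble <- lapply(stats::setNames(tab_names, tab_names), function(nm)
    ensemble_summary(lapply(models, function(mm) mm$risk$tables[[nm]])))
  differences <- iri_differences(models[[1]]$risk$iri$normalized)

  manifest <- list(
    package = "heatrisk",
    config_hash = .config_hash(cfg),
    seed = cfg$seed,
    n_models = cfg$n_models,
    years = cfg$years,
    return_period_blocks = cfg$T,
    stages = c("simulate", "indices", "block-maxima-gev", "hazard",
               "normalize", "iri", "classes", "exposure-tables",
               "ensemble-summary", "scenario-differences")
  )
  bundle <- list(config = cfg, world = world, models = models,
                 ensemble = ensemble, differences = differences,
                 manifest = manifest)
  if (!is.null(outdir)) {
    write_bundle(bundle, outdir)
    return(invisible(bundle))
  }
  bundle
}

#' Write the artifact bundle of a pipeline run
#'
#' Emits per-model hazard and IRI fields as CSV rasters, all exposure and
#' ensemble tables as CSV, the difference fields, the HDI table and the JSON
#' manifest under `outdir`.
#'
#' @param bundle A [run_all()] result.
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_bundle <- function(bundle, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  artifacts <- character(0)
  put_field <- function(field, grid, name) {
    p <- file.path(outdir, paste0(name, ".csv"))
    write_field_csv(field, grid, p)
    artifacts <<- c(artifacts, basename(p))
  }
  for (m in seq_along(bundle$models)) {
    hz <- bundle$models[[m]]$hazard
    rk <- bundle$models[[m]]$risk
    g <- hz$grid
    put_field(matrix(hz$z_T, g$nlat, g$nlon), g,
              sprintf("model%d_hw%dy_level", m, bundle$config$T))
    for (s in names(hz$hazard))
      put_field(matrix(hz$hazard[[s]], g$nlat, g$nlon), g,
                sprintf("model%d_hazard_%s", m, gsub("\\.", "p", s)))
    for (w in c("1.5C", "2C")) for (ssp in c("SSP1", "SSP4"))
      put_field(rk$iri$normalized[[w]][[ssp]], g,
                sprintf("model%d_iri_norm_%s_%s", m, gsub("\\.", "p", w), ssp))
  }
  g1 <- bundle$models[[1]]$hazard$grid
  for (nm in names(bundle$differences))
    put_field(bundle$differences[[nm]], g1, nm)
  for (nm in names(bundle$ensemble)) {
    p <- file.path(outdir, paste0("table_", nm, ".csv"))
    write_exposure_csv(bundle$ensemble[[nm]], p)
    artifacts <- c(artifacts, basename(p))
  }
  write_hdi_csv(bundle$world$native$hdi$table, file.path(outdir, "hdi.csv"))
  artifacts <- c(artifacts, "hdi.csv")
  manifest <- c(bundle$manifest, list(artifacts = artifacts))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(outdir)
}
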