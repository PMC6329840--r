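#!/usr/bin/env Rscript
# Stage 1 -- build the synthetic study world.
#
# Two synthetic climate models (9x9 and 12x12 grids, 500-year ensembles per
# climate state) share one socioeconomic world: a 36x36 native raster of
# log-normal population density with an uninhabited southern band, 36
# rectangular countries with HDI spread across all development classes, and
# future population/HDI under SSP1 (rapid development) and SSP4 (inequality).

suppressPackageStartupMessages(library(heatrisk))

outdir <- "results"
dir.create(file.path(outdir, "world"), recursive = TRUE, showWarnings = FALSE)

cfg <- run_config(seed = 42)
world <- generate_world_inputs(cfg)
saveRDS(list(cfg = cfg, world = world), file.path(outdir, "01_world.rds"))

native <- world$native
areas <- cell_areas(native$grid)
tot <- native$present_total

write_field_csv(native$pop_present, native$grid,
                file.path(outdir, "world", "pop_present.csv"))
write_field_csv(native$pop_future$SSP1, native$grid,
                file.path(outdir, "world", "pop_2075_ssp1.csv"))
write_field_csv(native$pop_future$SSP4, native$grid,
                file.path(outdir, "world", "pop_2075_ssp4.csv"))
write_hdi_csv(native$hdi$table, file.path(outdir, "world", "hdi.csv"))

cls <- classify_hdi(setNames(native$hdi$table$hdi_present,
                             native$hdi$table$country_id),
                    native$hdi$raster)
message("Synthetic world (seed 42)")
message(sprintf("  present global population: %.3g people over %d cells (%.0f%% inhabited)",
                tot, length(native$pop_present),
                100 * mean(native$pop_present > 0)))
message(sprintf("  2075 population: %.1f%% (SSP1) / %.1f%% (SSP4) of present",
                100 * sum(native$pop_future$SSP1 * areas) / tot,
                100 * sum(native$pop_future$SSP4 * areas) / tot))
message(sprintf("  countries: %d (low-HDI cells %d, medium %d, very-high %d)",
                nrow(native$hdi$table), sum(cls == "low"),
                sum(cls == "medium"), sum(cls == "very_high")))
message(sprintf("  climate models: %d, %d-year ensembles per state",
                cfg$n_models, cfg$years))
message("Wrote results/01_world.rds and results/world/*.csv")
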