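#' Configuration of a synthetic world
#'
#' Bundles every knob of the synthetic inputs that stand in for the real
#' prescribed-SST climate ensembles, SSP population rasters and country HDI
#' projections. The defaults define the study conditions used throughout the
#' package:
#'
#' * daily Tmax = latitudinal baseline + hemisphere-phased seasonal cycle +
#'   state warming offset + within-year AR(1) noise whose standard deviation
#'   is low inside a contiguous tropical band and higher outside it
#'   (low year-to-year variability in the tropics is the mechanism behind
#'   amplified changes in heat-extreme odds there);
#' * warming offsets of +0.6 degC (1.5 degC world) and +1.1 degC (2 degC
#'   world) relative to the present-climate state, the approximate additional
#'   warming of the two stabilization targets over a present decade;
#' * log-normal population density with a contiguous uninhabited band
#'   (exactly zero density) covering `pop_zero_frac` of the latitude rows,
#'   and future totals at 120% (SSP1) and 140% (SSP4) of the present total;
#' * contiguous rectangular countries with present HDI spread over
#'   `hdi_range` so all development classes are populated, and future HDI
#'   converging toward 1 faster under SSP1 than under SSP4.
#'
#' Climate noise is drawn from `seed + 7919 * model`, while population,
#' country and HDI draws use `seed` alone, so multiple synthetic climate
#' models share one socioeconomic world.
#'
#' @param nlat,nlon Climate (model) grid shape.
#' @param pop_nlat,pop_nlon Native population/country raster shape (finer
#'   than the model grid; remapped onto it by the pipeline).
#' @param n_countries Number of synthetic countries (>= 3 so every HDI class
#'   can be populated); arranged as contiguous rectangular blocks.
#' @param years Ensemble years per climate state; must be a positive multiple
#'   of 10 (the decadal block length).
#' @param model Integer tag of the synthetic climate model (offsets the
#'   climate noise seed only).
#' @param baseline_equator Baseline daily Tmax at the equator (degC).
#' @param lat_gradient Baseline decrease from equator to the poleward edge
#'   (degC).
#' @param seasonal_amplitude Seasonal cycle amplitude (degC).
#' @param ar1 AR(1) coefficient of daily noise (within-year; reset at each
#'   year boundary so decadal block maxima are exchangeable across years).
#' @param sd_low,sd_high Stationary noise standard deviation (degC) inside /
#'   outside the low-variance band.
#' @param low_band_lat Absolute latitude (deg) bounding the low-variance band.
#' @param dt_15,dt_2 Warming offsets (degC) of the 1.5 degC and 2 degC states
#'   over present; must satisfy `dt_2 > dt_15 > 0`.
#' @param pop_meanlog,pop_sdlog Log-normal parameters of present population
#'   density (persons/km^2).
#' @param pop_zero_frac Fraction of latitude rows (from the southern edge)
#'   that are uninhabited (density exactly 0).
#' @param pop_growth Named growth factors of the future / present global
#'   population total per scenario; must be non-negative.
#' @param hdi_range Present-period country HDI range (inside (0,1)).
#' @param hdi_gain Named per-scenario fraction of each country's remaining
#'   headroom `1 - HDI` closed by the future period; SSP1 >= SSP4 >= 0 keeps
#'   future HDI monotone in time and ordered across scenarios.
#' @param seed Integer random seed.
#' @return An object of class `world_config`.
#' @export
world_config <- function(nlat = 9, nlon = 9,
                         pop_nlat = 36, pop_nlon = 36,
                         n_countries = 36,
                         years = 500,
                         model = 1L,
                         baseline_equator = 28,
                         lat_gradient = 12,
                         seasonal_amplitude = 10,
                         ar1 = 0.7,
                         sd_low = 1.0, sd_high = 3.0,
                         low_band_lat = 20,
                         dt_15 = 0.6, dt_2 = 1.1,
                         pop_meanlog = 4, pop_sdlog = 1.5,
                         pop_zero_frac = 0.2,
                         pop_growth = c(SSP1 = 1.2, SSP4 = 1.4),
                         hdi_range = c(0.45, 0.92),
                         hdi_gain = c(SSP1 = 0.5, SSP4 = 0.25),
                         seed = 1L) {
  if (years <= 0 || years %% 10 != 0)
    stop("'years' must be a positive multiple of 10 (decadal blocks)")
  if (!(dt_2 > dt_15 && dt_15 > 0))
    stop("warming offsets must satisfy dt_2 > dt_15 > 0")
  if (n_countries < 3)
    stop("need at least 3 countries so all HDI classes are populated")
  if (any(pop_growth < 0)) stop("population growth factors must be >= 0")
  if (hdi_range[1] <= 0 || hdi_range[2] >= 1 || hdi_range[1] > hdi_range[2])
    stop("hdi_range must lie strictly inside (0, 1)")
  if (any(hdi_gain < 0) || any(hdi_gain >= 1))
    stop("hdi_gain values must lie in [0, 1)")
  if (hdi_gain[["SSP1"]] < hdi_gain[["SSP4"]])
    stop("SSP1 hdi_gain must be >= SSP4 hdi_gain")
  if (sd_low < 0 || sd_high < 0) stop("noise standard deviations must be >= 0")
  cfg <- list(
    grid = grid_spec(nlat, nlon),
    pop_grid = grid_spec(pop_nlat, pop_nlon),
    n_countries = n_countries, years = years, model = as.integer(model),
    baseline_equator = baseline_equator, lat_gradient = lat_gradient,
    seasonal_amplitude = seasonal_amplitude, ar1 = ar1,
    sd_low = sd_low, sd_high = sd_high, low_band_lat = low_band_lat,
    dt_15 = dt_15, dt_2 = dt_2,
    pop_meanlog = pop_meanlog, pop_sdlog = pop_sdlog,
    pop_zero_frac = pop_zero_frac, pop_growth = pop_growth,
    hdi_range = hdi_range, hdi_gain = hdi_gain,
    seed = as.integer(seed)
  )
  cfg$climate_seed <- (cfg$seed + 7919L * cfg$model) %% .Machine$integer.max
  class(cfg) <- "world_config"
  cfg
}

#' Per-cell noise standard deviation field
#'
#' Low inside the contiguous tropical band (`|lat| < low_band_lat`), high
#' outside; the band drives the warming-to-noise amplification mechanism.
#'
#' @param config A [world_config()].
#' @return Matrix `nlat x nlon` of standard deviations (degC).
#' @export
noise_sd_field <- function(config) {
  low <- abs(config$grid$lat) < config$low_band_lat
  matrix(ifelse(low, config$sd_low, config$sd_high),
         config$grid$nlat, config$grid$nlon)
}

#' Warming offset of a climate state
#' @param config A [world_config()].
#' @param state One of `"present"`, `"1.5C"`, `"2C"`.
#' @return Offset in degC.
#' @export
state_offset <- function(config, state) {
  switch(match.arg(state, c("present", "1.5C", "2C")),
         present = 0, `1.5C` = config$dt_15, `2C` = config$dt_2)
}

#' Generate a synthetic daily Tmax ensemble for one climate state
#'
#' Produces a 365-day no-leap calendar series of daily maximum temperature
#' for every grid cell and ensemble year. The three climate states of a model
#' share one noise realization (common random numbers): they differ only by
#' the state's constant warming offset, which isolates the warming signal
#' from sampling noise. AR(1) noise is generated within each year and reset
#' at year boundaries, with the stationary standard deviation of
#' [noise_sd_field()].
#'
#' @param config A [world_config()].
#' @param state One of `"present"`, `"1.5C"`, `"2C"`.
#' @return Numeric array `c(365, years, ncell)` (cells in column-major grid
#'   order) with attributes `grid` and `state`.
#' @export
generate_climate <- function(config, state) {
  stopifnot(inherits(config, "world_config"))
  state <- match.arg(state, c("present", "1.5C", "2C"))
  g <- config$grid
  ncell <- g$nlat * g$nlon
  ny <- config$years
  doy <- seq_len(365)

  lat_cell <- rep(g$lat, times = g$nlon)
  baseline <- config$baseline_equator -
    config$lat_gradient * abs(lat_cell) / max(abs(g$lat_bounds))
  peak <- ifelse(lat_cell >= 0, 196, 15)   # hemisphere-dependent summer peak
  clim <- outer(doy, seq_len(ncell),
                function(d, c) baseline[c] +
                  config$seasonal_amplitude *
                  cos(2 * pi * (d - peak[c]) / 365))

  sd_cell <- as.vector(noise_sd_field(config))
  set.seed(config$climate_seed)
  eps <- array(stats::rnorm(365 * ny * ncell), dim = c(365, ny, ncell))
  phi <- config$ar1
  # year-reset AR(1): e_1 stationary, increments scaled by sqrt(1 - phi^2)
  e <- eps
  if (phi != 0) {
    fac <- sqrt(1 - phi^2)
    for (d in 2:365) e[d, , ] <- phi * e[d - 1L, , ] + fac * eps[d, , ]
  }
  e <- e * rep(sd_cell, each = 365 * ny)

  clim_arr <- aperm(array(clim, dim = c(365, ncell, ny)), c(1, 3, 2))
  out <- e + clim_arr + state_offset(config, state)
  attr(out, "grid") <- g
  attr(out, "state") <- state
  out
}

#' Generate a synthetic population-density raster
#'
#' Present-period density is i.i.d. log-normal on the native raster, with a
#' contiguous uninhabited band (exactly zero density) covering
#' `pop_zero_frac` of the latitude rows from the southern edge. Future fields
#' keep the present spatial pattern and scale the global total by the
#' scenario growth factor, mirroring projections in which the end-of-century
#' global population reaches about 120% (SSP1) and 140% (SSP4) of present.
#'
#' @param config A [world_config()].
#' @param period `"present"` or `"future"`.
#' @param scenario `"SSP1"` or `"SSP4"` (ignored for the present period).
#' @return Matrix `pop_nlat x pop_nlon` of persons/km^2.
#' @export
generate_population <- function(config, period = c("present", "future"),
                                scenario = c("SSP1", "SSP4")) {
  stopifnot(inherits(config, "world_config"))
  period <- match.arg(period)
  scenario <- match.arg(scenario)
  g <- config$pop_grid
  set.seed(config$seed + 104729L)
  pop <- matrix(stats::rlnorm(g$nlat * g$nlon, config$pop_meanlog,
                              config$pop_sdlog), g$nlat, g$nlon)
  nzero <- ceiling(config$pop_zero_frac * g$nlat)
  if (nzero > 0) pop[seq_len(min(nzero, g$nlat)), ] <- 0
  if (period == "future") pop <- pop * config$pop_growth[[scenario]]
  pop
}

#' Generate synthetic country HDI tables and a country-index raster
#'
#' Countries are contiguous rectangular blocks tiling the native raster.
#' Present HDI values are evenly spread over `hdi_range`; future values close
#' a scenario-specific fraction of each country's remaining headroom
#' (`hdi + gain * (1 - hdi)`), so future HDI is always >= present and
#' SSP1 >= SSP4 country by country, and every value stays strictly inside
#' (0, 1).
#'
#' @param config A [world_config()].
#' @param period,scenario Select which HDI column is exposed as `hdi`.
#' @return List with `table` (data.frame: `country_id`, `name`,
#'   `hdi_present`, `hdi_ssp1_future`, `hdi_ssp4_future`), `hdi` (the column
#'   selected by `period`/`scenario`, named by country id) and `raster`
#'   (integer matrix of country ids on the native grid).
#' @export
generate_hdi <- function(config, period = c("present", "future"),
                         scenario = c("SSP1", "SSP4")) {
  stopifnot(inherits(config, "world_config"))
  period <- match.arg(period)
  scenario <- match.arg(scenario)
  n <- config$n_countries
  g <- config$pop_grid

  hdi_present <- seq(config$hdi_range[1], config$hdi_range[2], length.out = n)
  set.seed(config$seed + 224737L)
  hdi_present <- sample(hdi_present)      # decouple HDI from block position
  future <- function(gain) hdi_present + gain * (1 - hdi_present)
  tab <- data.frame(
    country_id = seq_len(n),
    name = sprintf("Country-%02d", seq_len(n)),
    hdi_present = hdi_present,
    hdi_ssp1_future = future(config$hdi_gain[["SSP1"]]),
    hdi_ssp4_future = future(config$hdi_gain[["SSP4"]])
  )
  if (any(tab$hdi_present <= 0 | tab$hdi_present >= 1 |
          tab$hdi_ssp1_future >= 1 | tab$hdi_ssp4_future >= 1))
    stop("generated HDI values must lie strictly inside (0, 1)")

  # near-square block layout covering every cell exactly once
  nbx <- ceiling(sqrt(n))
  nby <- ceiling(n / nbx)
  bx <- pmin(floor(seq(0, nbx, length.out = g$nlon + 1)), nbx - 1)[-(g$nlon + 1)]
  by <- pmin(floor(seq(0, nby, length.out = g$nlat + 1)), nby - 1)[-(g$nlat + 1)]
  idx <- outer(by, bx, function(i, j) i * nbx + j) %% n + 1L
  raster <- matrix(as.integer(idx), g$nlat, g$nlon)

  col <- switch(period, present = "hdi_present",
                future = if (scenario == "SSP1") "hdi_ssp1_future"
                         else "hdi_ssp4_future")
  hdi <- stats::setNames(tab[[col]], tab$country_id)
  list(table = tab, hdi = hdi, raster = raster)
}

#' Map a country-level HDI column onto a raster
#'
#' @param hdi Named vector of HDI values (names = country ids).
#' @param raster Integer matrix of country ids (NA = no country).
#' @return Numeric matrix of cell HDI values (NA where no country or no
#'   table entry).
#' @export
hdi_field <- function(hdi, raster) {
  out <- matrix(unname(hdi[as.character(raster)]), nrow(raster), ncol(raster))
  out
}

#' Write the country HDI table as CSV
#' @param table Data frame from [generate_hdi()].
#' @param path Output path.
#' @export
write_hdi_csv <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_hdi_csv
#' @export
read_hdi_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
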