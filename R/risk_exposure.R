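#' Normalized Illustrative Risk Index
#'
#' `IRI = hazard x exposure x vulnerability x 100`, with the hazard the
#' per-decade probability of exceeding the present-climate 500-decade return
#' level and the exposure / vulnerability factors the Johnson-normalized
#' population and 1-HDI scores. All three factors must lie in \[0, 1\], so
#' the index lies in \[0, 100\] and vanishes wherever any factor is 0; in
#' the present period it is bounded by 100 x the present hazard probability
#' (0.2 for a 500-decade event).
#'
#' @param hazard,pop_score,vuln_score Factors in \[0, 1\] (vectors/matrices
#'   of equal shape; NA propagates).
#' @return IRI in percent.
#' @export
iri_normalized <- function(hazard, pop_score, vuln_score) {
  for (f in list(hazard, pop_score, vuln_score)) {
    v <- f[!is.na(f)]
    if (any(v < 0 | v > 1))
      stop("all normalized IRI factors must lie in [0, 1]")
  }
  hazard * pop_score * vuln_score * 100
}

#' Non-normalized Illustrative Risk Index
#'
#' The raw product hazard probability x population density x (1 - HDI), in
#' physical units (persons/km^2 scaled by a probability); unbounded above
#' and dominated by the wide range of population density.
#'
#' @param hazard Per-decade hazard probability in \[0, 1\].
#' @param pop Population density (>= 0, persons/km^2).
#' @param vuln `1 - HDI` with HDI in (0, 1).
#' @return The raw product.
#' @export
iri_nonnormalized <- function(hazard, pop, vuln) {
  if (any(pop[!is.na(pop)] < 0)) stop("population density must be >= 0")
  hazard * pop * vuln
}

#' Classify cells by country human development
#'
#' Applies the fixed cutoffs of the development classes: `HDI < 0.55` is
#' low, `HDI > 0.8` very high (strict inequalities); everything between is
#' the medium band. Cells without a country or without a table entry are
#' `no_data`.
#'
#' @param hdi Named vector of country HDI (names = country ids), e.g. from
#'   [generate_hdi()].
#' @param raster Integer matrix of country ids on the analysis grid.
#' @return Character matrix with values `"low"`, `"medium"`, `"very_high"`,
#'   `"no_data"`.
#' @export
classify_hdi <- function(hdi, raster) {
  h <- hdi_field(hdi, raster)
  cls <- ifelse(is.na(h), "no_data",
                ifelse(h < 0.55, "low",
                       ifelse(h > 0.8, "very_high", "medium")))
  matrix(cls, nrow(raster), ncol(raster))
}

#' Population distribution over hazard or IRI bins
#'
#' Bins the inhabited cells of a field (hazard probability or IRI percent)
#' and reports, per bin, the resident population as a percentage of the
#' present global population. People are counted as density x spherical cell
#' area; cells with zero population are excluded before binning, as are
#' cells outside `mask` or with a missing field value. Bins are
#' `[edge_i, edge_{i+1})`, the last bin closed.
#'
#' @param values Field to bin (matrix on `grid`).
#' @param pop Population density on the same grid.
#' @param grid The [grid_spec()] of both fields.
#' @param breaks Strictly increasing bin edges.
#' @param present_total Present-day global population (people), the
#'   denominator.
#' @param mask Optional logical matrix restricting the scope (e.g. an HDI
#'   class).
#' @param scope,scenario,warming Optional labels carried into the table.
#' @return Data frame of class `exposure_table` with columns `scope`,
#'   `scenario`, `warming`, `bin_low`, `bin_high`, `pop_pct`.
#' @export
exposure_distribution <- function(values, pop, grid, breaks, present_total,
                                  mask = NULL, scope = "global",
                                  scenario = NA_character_,
                                  warming = NA_character_) {
  if (any(diff(breaks) <= 0))
    stop("bin edges must be strictly increasing (no overlapping bins)")
  stopifnot(all(dim(values) == dim(pop)), present_total > 0)
  people <- pop * cell_areas(grid)
  keep <- !is.na(values) & !is.na(pop) & pop > 0
  if (!is.null(mask)) keep <- keep & mask
  bin <- cut(values[keep], breaks, right = FALSE, include.lowest = TRUE)
  pct <- tapply(people[keep], bin, sum, default = 0) / present_total * 100
  out <- data.frame(
    scope = scope, scenario = scenario, warming = warming,
    bin_low = breaks[-length(breaks)], bin_high = breaks[-1],
    pop_pct = as.numeric(pct)
  )
  class(out) <- c("exposure_table", class(out))
  out
}

#' Ensemble summary of exposure tables
#'
#' Per-bin median, minimum and maximum across climate models; all tables
#' must share bins and scope labels.
#'
#' @param tables List of [exposure_distribution()] tables.
#' @return Data frame with `pop_pct_median`, `pop_pct_min`, `pop_pct_max`
#'   replacing `pop_pct`.
#' @export
ensemble_summary <- function(tables) {
  stopifnot(length(tables) >= 1)
  ref <- tables[[1]]
  for (t in tables[-1]) {
    if (!identical(t$bin_low, ref$bin_low) ||
        !identical(t$bin_high, ref$bin_high) ||
        !identical(t$scope, ref$scope))
      stop("exposure tables must share bins and scope")
  }
  m <- sapply(tables, `[[`, "pop_pct")
  if (is.null(dim(m))) m <- matrix(m, nrow = 1)
  out <- ref[c("scope", "scenario", "warming", "bin_low", "bin_high")]
  out$pop_pct_median <- apply(m, 1, stats::median)
  out$pop_pct_min <- apply(m, 1, min)
  out$pop_pct_max <- apply(m, 1, max)
  out
}

#' Cell-wise difference of two scenario fields
#'
#' `a - b`, missing wherever either input is missing; used for the
#' warming-level and pathway contrasts (2 degC - 1.5 degC, SSP4 - SSP1, and
#' worst minus best combination).
#'
#' @param a,b Fields of identical shape and variant.
#' @return Difference field.
#' @export
scenario_difference <- function(a, b) {
  if (!all(dim(a) == dim(b))) stop("fields must share a grid")
  a - b
}

#' Write / read an exposure table as CSV
#' @param table An exposure or ensemble-summary table.
#' @param path File path.
#' @export
write_exposure_csv <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_exposure_csv
#' @export
read_exposure_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
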