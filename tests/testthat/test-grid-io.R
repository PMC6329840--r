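test_that("grid specs tile their domain without overlap", {
  g <- grid_spec(4, 8)
  expect_equal(length(g$lat_bounds), 5)
  expect_true(all(diff(g$lat_bounds) > 0))
  expect_true(all(diff(g$lon_bounds) > 0))
  expect_equal(g$lat, (g$lat_bounds[-1] + g$lat_bounds[-5]) / 2)
  # total area equals the analytic sphere-segment area
  seg <- 2 * pi * 6371^2 * (sin(60 * pi / 180) - sin(-60 * pi / 180))
  expect_equal(sum(cell_areas(g)), seg, tolerance = 1e-12)
})

test_that("conservative remap is exact on identical grids and uniform fields", {
  g <- grid_spec(5, 6)
  set.seed(2)
  f <- matrix(rnorm(30), 5, 6)
  expect_equal(remap_conservative(f, g, g), f, tolerance = 1e-12)
  g2 <- grid_spec(7, 9)
  u <- matrix(3.5, 5, 6)
  expect_equal(remap_conservative(u, g, g2), matrix(3.5, 7, 9),
               tolerance = 1e-12)
})

test_that("4x4 to 2x2 aggregation matches hand-computed area weights", {
  src <- grid_spec(4, 4)
  dst <- grid_spec(2, 2)
  set.seed(5)
  f <- matrix(rnorm(16), 4, 4)
  got <- remap_conservative(f, src, dst)
  # oracle: every coarse cell contains exactly 2x2 fine cells; weights are
  # the sin-lat band widths (longitude widths are equal)
  w <- diff(sin(src$lat_bounds * pi / 180))
  for (i in 1:2) for (j in 1:2) {
    rows <- (2 * i - 1):(2 * i)
    cols <- (2 * j - 1):(2 * j)
    want <- sum(f[rows, cols] * w[rows]) / (2 * sum(w[rows]))
    expect_equal(got[i, j], want, tolerance = 1e-12)
  }
})

test_that("remap conserves integrated totals and is linear", {
  src <- grid_spec(12, 16)
  dst <- grid_spec(5, 7)
  set.seed(8)
  f <- matrix(rlnorm(12 * 16), 12, 16)
  g <- matrix(rnorm(12 * 16), 12, 16)
  rf <- remap_conservative(f, src, dst)
  # conservation of people: density x area totals agree
  expect_equal(sum(rf * cell_areas(dst)), sum(f * cell_areas(src)),
               tolerance = 1e-9)
  # linearity
  expect_equal(remap_conservative(2 * f - 3 * g, src, dst),
               2 * rf - 3 * remap_conservative(g, src, dst),
               tolerance = 1e-12)
})

test_that("remap propagates missing data and rejects disjoint domains", {
  src <- grid_spec(4, 4)
  dst <- grid_spec(2, 2)
  f <- matrix(1, 4, 4)
  f[1:2, 1:2] <- NA
  r <- remap_conservative(f, src, dst)
  expect_true(is.na(r[1, 1]))          # all contributors missing
  expect_equal(r[2, 2], 1)
  far <- grid_spec(4, 4, lon_range = c(-180, 180))
  g_east <- grid_spec(2, 2, lon_range = c(0, 90))
  expect_silent(remap_conservative(f, far, g_east))
  disjoint <- grid_spec(2, 2, lat_range = c(-60, 60),
                        lon_range = c(-180, 180))
  expect_error(remap_conservative(matrix(1, 2, 2), disjoint,
                                  grid_spec(2, 2, lat_range = c(61, 89),
                                            lon_range = c(-180, 180))),
               class = "simpleError")
})

test_that("country rasterization follows the majority-area rule", {
  src <- grid_spec(4, 4)
  dst <- grid_spec(2, 2)
  one <- matrix(7L, 4, 4)
  expect_equal(rasterize_countries(one, src, dst), matrix(7L, 2, 2))

  # two countries split exactly at a target-cell boundary
  split <- matrix(rep(c(1L, 1L, 2L, 2L), each = 4), 4, 4, byrow = TRUE)
  r <- rasterize_countries(split, src, dst)
  expect_equal(r, matrix(c(1L, 2L, 1L, 2L), 2, 2))

  # exact tie -> lowest id (two equal-area countries inside one cell,
  # symmetric about the equator so the sin-lat areas match)
  tie_src <- grid_spec(2, 1)
  tie <- matrix(c(4L, 3L), 2, 1)
  expect_equal(rasterize_countries(tie, tie_src, grid_spec(1, 1)),
               matrix(3L, 1, 1))

  # sentinel-only coverage stays missing
  sea <- matrix(NA_integer_, 4, 4)
  expect_true(all(is.na(rasterize_countries(sea, src, dst))))
})

test_that("field CSV round trips are bit-exact and keep missing cells", {
  g <- grid_spec(6, 5)
  set.seed(13)
  f <- matrix(rnorm(30) * 1e7, 6, 5)
  f[c(3, 14)] <- NA
  path <- tempfile(fileext = ".csv")
  write_field_csv(f, g, path)
  back <- read_field_csv(path)
  expect_identical(back$field, f)
  expect_equal(back$grid$lat, g$lat)
  expect_equal(back$grid$lon, g$lon)
  unlink(path)
})

test_that("HDI and exposure tables survive CSV round trips", {
  cfg <- tiny_world()
  tab <- generate_hdi(cfg)$table
  p <- tempfile(fileext = ".csv")
  write_hdi_csv(tab, p)
  back <- read_hdi_csv(p)
  expect_equal(back$country_id, tab$country_id)
  expect_equal(back$hdi_present, tab$hdi_present, tolerance = 1e-12)
  unlink(p)

  g <- grid_spec(2, 2)
  pop <- matrix(2, 2, 2)
  tot <- sum(pop * cell_areas(g))
  t1 <- exposure_distribution(matrix(0.3, 2, 2), pop, g, c(0, 0.5, 1), tot,
                              scope = "global", scenario = "SSP1",
                              warming = "1.5C")
  p2 <- tempfile(fileext = ".csv")
  write_exposure_csv(t1, p2)
  b2 <- read_exposure_csv(p2)
  expect_equal(b2$pop_pct, t1$pop_pct, tolerance = 1e-12)
  expect_equal(b2$scope, t1$scope)
  expect_equal(b2$bin_low, t1$bin_low)
  unlink(p2)
})
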