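# buffer selection by haversine, monthly aggregation, temporal/spatial SD
# metrics and their invariances.

test_that("haversine distances match hand values", {
  # 1 degree of latitude = pi * 6371 / 180 = 111.1949 km
  expect_equal(haversine_km(56, -2, 57, -2), pi * 6371 / 180,
               tolerance = 1e-6)
  expect_equal(haversine_km(0, 0, 0, 1), pi * 6371 / 180, tolerance = 1e-6)
  expect_equal(haversine_km(56, -2, 56, -2), 0)
})

# a 5 x 5 grid with exactly 1 km spacing at latitude 0
km_grid <- function() {
  kmdeg <- pi * 6371 / 180
  step <- 1 / kmdeg
  lat <- (0:4) * step
  lon <- (0:4) * step
  vals <- array(0, c(2, 2, 5, 5))
  env_grid("SST", lat, lon, 2000:2001, 4:5, vals)
}

test_that("pixel selection within a radius follows the haversine oracle", {
  g <- km_grid()
  centre <- colony_site("c", g$lat[3], g$lon[3], "toy")
  # radius below the 1 km spacing: only the centre pixel
  one <- pixels_in_range(g, centre, 0.5)
  expect_equal(nrow(one), 1)
  expect_equal(unname(one[1, ]), c(3, 3))
  # hand oracle: 4-neighbours at 1.000 km, diagonals at sqrt(2) = 1.414 km;
  # radius 1.2 km keeps the plus-shaped 5-pixel set, 1.5 km adds diagonals
  expect_equal(nrow(pixels_in_range(g, centre, 1.2)), 5)
  expect_equal(nrow(pixels_in_range(g, centre, 1.5)), 9)
  # radius spanning the whole grid: all 25
  expect_equal(nrow(pixels_in_range(g, centre, 100)), 25)
  expect_error(pixels_in_range(g, colony_site("far", 80, 100, "toy"), 5),
               "no grid pixels")
  expect_error(pixels_in_range(g, centre, -1), "positive")
})

test_that("daily fields aggregate to calendar-month means", {
  dates <- seq(as.Date("2004-01-01"), as.Date("2004-03-31"), by = "day")
  vals <- array(NA_real_, c(length(dates), 1, 1))
  day_of_month <- as.numeric(format(dates, "%d"))
  vals[, 1, 1] <- ifelse(format(dates, "%m") == "03", 7, day_of_month)
  daily <- list(variable = "SSH", lat = 56, lon = -2, dates = dates,
                values = vals)
  g <- monthly_aggregate(daily)
  expect_equal(g$values[1, 1, 1, 1], mean(1:31))    # January 1..31 -> 16
  expect_equal(g$values[1, 2, 1, 1], mean(1:29))    # leap February
  expect_equal(g$values[1, 3, 1, 1], 7)             # constant month
})

test_that("temporal SD per pixel: closed forms and month masking", {
  # constant field
  g0 <- grid_from_values(array(5, c(3, 4, 2, 2)))
  expect_equal(as.numeric(temporal_sd_per_pixel(g0)), rep(0, 4))
  # alternating a, -a over n = 4 samples: SD = a * sqrt(n / (n - 1))
  a <- 2.5
  vals <- array(0, c(2, 2, 1, 1))
  vals[1, 1, 1, 1] <- a; vals[1, 2, 1, 1] <- -a
  vals[2, 1, 1, 1] <- a; vals[2, 2, 1, 1] <- -a
  g1 <- grid_from_values(vals)
  expect_equal(temporal_sd_per_pixel(g1)[1, 1], a * sqrt(4 / 3))
  # month masking: contaminate month 8 and exclude it
  vals2 <- array(1, c(3, 3, 1, 1))
  vals2[, 3, 1, 1] <- 1000
  g2 <- grid_from_values(vals2, months = c(4, 5, 8))
  expect_equal(temporal_sd_per_pixel(g2, months = c(4, 5))[1, 1], 0)
  expect_gt(temporal_sd_per_pixel(g2)[1, 1], 100)
  # single-sample pixels flagged missing
  g3 <- grid_from_values(array(1, c(1, 1, 2, 2)))
  expect_true(all(is.na(temporal_sd_per_pixel(g3))))
})

test_that("climate metric is the buffer mean of pixel temporal SDs", {
  # two-pixel buffer with SDs 1 and 3 -> 2
  vals <- array(0, c(2, 2, 1, 2))
  vals[, , 1, 1] <- c(1, 1, -1, -1) / sqrt(4 / 3)        # SD 1
  vals[, , 1, 2] <- 3 * c(1, 1, -1, -1) / sqrt(4 / 3)    # SD 3
  g <- grid_from_values(vals, lat = 56, lon = c(-2, -1.999))
  site <- colony_site("c", 56, -1.9995, "toy")
  m <- climate_temporal_variation(g, site, radius_km = 5)
  expect_equal(m$value, 2)
  expect_equal(m$n_pixels, 2)
  m2 <- climate_temporal_variation(g, site, radius_km = 5,
                                   year_range = c(2000, 2001))
  expect_equal(m2$value, 2)
  # shift invariance: adding a pixel-specific constant changes nothing
  vals_shift <- vals
  vals_shift[, , 1, 1] <- vals[, , 1, 1] + 17
  vals_shift[, , 1, 2] <- vals[, , 1, 2] - 3
  gs <- grid_from_values(vals_shift, lat = 56, lon = c(-2, -1.999))
  expect_equal(climate_temporal_variation(gs, site, radius_km = 5)$value, 2)
})

test_that("resource metric is the buffer spatial SD of temporal SDs", {
  vals <- array(0, c(2, 2, 1, 2))
  vals[, , 1, 1] <- c(1, 1, -1, -1) / sqrt(4 / 3)
  vals[, , 1, 2] <- 3 * c(1, 1, -1, -1) / sqrt(4 / 3)
  g <- grid_from_values(vals, lat = 56, lon = c(-2, -1.999))
  site <- colony_site("c", 56, -1.9995, "toy")
  m <- resource_spatiotemporal_variation(g, site, radius_km = 5)
  expect_equal(m$value, sqrt(2))                    # sd(c(1, 3))
  # homogeneity: doubling every temporal SD doubles the metric
  g2 <- grid_from_values(2 * vals, lat = 56, lon = c(-2, -1.999))
  expect_equal(resource_spatiotemporal_variation(g2, site,
                                                 radius_km = 5)$value,
               2 * sqrt(2))
  # uniform temporal SDs -> 0
  g3 <- grid_from_values(array(rep(c(1, -1), each = 2), c(2, 2, 1, 2)),
                         lat = 56, lon = c(-2, -1.999))
  expect_equal(resource_spatiotemporal_variation(g3, site,
                                                 radius_km = 5)$value, 0)
  # 1-pixel buffer is an error
  expect_error(resource_spatiotemporal_variation(g, site, radius_km = 0.01),
               "no grid pixels|fewer than 2")
})

test_that("metrics are invariant to pixel and time ordering", {
  set.seed(3)
  vals <- array(rnorm(2 * 3 * 2 * 2), c(2, 3, 2, 2))
  g <- grid_from_values(vals, lat = c(56, 56.001), lon = c(-2, -1.999))
  site <- colony_site("c", 56.0005, -1.9995, "toy")
  base_t <- climate_temporal_variation(g, site, radius_km = 10)$value
  base_s <- resource_spatiotemporal_variation(g, site, radius_km = 10)$value
  # permute years and months
  gp <- grid_from_values(vals[2:1, c(2, 3, 1), , , drop = FALSE],
                         lat = g$lat, lon = g$lon)
  expect_equal(climate_temporal_variation(gp, site, radius_km = 10)$value,
               base_t)
  expect_equal(resource_spatiotemporal_variation(gp, site,
                                                 radius_km = 10)$value,
               base_s)
})

test_that("mask-aware: land (NA) pixels are excluded", {
  vals <- array(0, c(2, 2, 1, 3))
  vals[, , 1, 1] <- c(1, 1, -1, -1) / sqrt(4 / 3)
  vals[, , 1, 2] <- 3 * c(1, 1, -1, -1) / sqrt(4 / 3)
  vals[, , 1, 3] <- NA
  g <- grid_from_values(vals, lat = 56, lon = c(-2, -1.999, -1.998))
  site <- colony_site("c", 56, -1.999, "toy")
  m <- climate_temporal_variation(g, site, radius_km = 5)
  expect_equal(m$value, 2)
  expect_equal(m$n_pixels, 2)
})

test_that("grid CSV round trip preserves values and axes", {
  g <- simulate_env_grid(env_grid_spec("CHL", n_lat = 3, n_lon = 4,
                                       years = 2000:2004, months = 4:7,
                                       temporal_sd_field = 0.5, seed = 9))
  tmp <- tempfile(fileext = ".csv")
  write_env_grid(g, tmp)
  g2 <- read_env_grid(tmp)
  expect_equal(g2$values, g$values)
  expect_equal(g2$lat, g$lat)
  expect_equal(g2$variable, g$variable)
  expect_equal(g2$months, g$months)
})
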