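#' Gridded monthly environmental field
#'
#' A lat/lon/time array of one environmental variable at monthly resolution:
#' values are indexed `[year, month, lat, lon]`. Land or otherwise missing
#' pixels carry `NA`.
#'
#' @param variable `"SST"`, `"SSH"`, `"CHL"` or `"TF"`.
#' @param lat,lon Sorted coordinates of pixel centers (degrees).
#' @param years Integer years covered.
#' @param months Months covered (subset of 1..12).
#' @param values 4-d array `[year, month, lat, lon]`.
#' @return Object of class `env_grid`.
#' @export
env_grid <- function(variable, lat, lon, years, months, values) {
  if (is.unsorted(lat) || is.unsorted(lon))
    stop("coordinate arrays must be sorted")
  if (!all(months %in% 1:12)) stop("months must be in 1..12")
  dims <- c(length(years), length(months), length(lat), length(lon))
  if (!identical(dim(values), as.integer(dims)))
    stop("`values` must be a [year, month, lat, lon] array matching the axes")
  structure(list(variable = variable, lat = lat, lon = lon,
                 years = as.integer(years), months = as.integer(months),
                 values = values),
            class = "env_grid")
}

#' @export
print.env_grid <- function(x, ...) {
  cat(sprintf("<env_grid> %s: %d x %d pixels, years %d-%d, months %s\n",
              x$variable, length(x$lat), length(x$lon), min(x$years),
              max(x$years), paste(x$months, collapse = ",")))
  invisible(x)
}

#' A colony location
#'
#' @param colony_id Colony label.
#' @param lat,lon Coordinates in degrees (|lat| <= 90, |lon| <= 180).
#' @param species Species label (links to the foraging range).
#' @return Object of class `colony_site`.
#' @export
colony_site <- function(colony_id, lat, lon, species) {
  if (abs(lat) > 90 || abs(lon) > 180) stop("coordinates out of range")
  structure(list(colony_id = as.character(colony_id), lat = lat, lon = lon,
                 species = as.character(species)),
            class = "colony_site")
}

#' Write / read an environmental grid as a delimited table
#'
#' Long-format CSV with columns year, month, lat, lon, value (one row per
#' pixel-month; `NA` rows kept so masks round-trip), plus a small JSON
#' sidecar (`<path>.json`) recording the variable and axes.
#'
#' @param grid An [env_grid()].
#' @param path CSV path.
#' @return `read_env_grid`: an [env_grid()].
#' @export
write_env_grid <- function(grid, path) {
  d <- expand.grid(year = grid$years, month = grid$months, lat = grid$lat,
                   lon = grid$lon, KEEP.OUT.ATTRS = FALSE)
  d$value <- as.vector(grid$values)
  utils::write.csv(d, path, row.names = FALSE)
  meta <- list(variable = grid$variable, lat = grid$lat, lon = grid$lon,
               years = grid$years, months = grid$months)
  jsonlite::write_json(meta, paste0(path, ".json"), digits = NA,
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_env_grid
#' @export
read_env_grid <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  d <- utils::read.csv(path)
  dims <- c(length(meta$years), length(meta$months), length(meta$lat),
            length(meta$lon))
  # expand.grid order (year fastest) matches as.vector of the array
  vals <- array(d$value, dims)
  env_grid(meta$variable, meta$lat, meta$lon, meta$years, meta$months, vals)
}

#' Great-circle distance (haversine)
#'
#' Spherical-Earth haversine distance, radius 6371 km. Vectorized over the
#' second point.
#'
#' @param lat1,lon1 First point (degrees).
#' @param lat2,lon2 Second point(s) (degrees).
#' @return Distance(s) in km.
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2) {
  rad <- pi / 180
  dlat <- (lat2 - lat1) * rad
  dlon <- (lon2 - lon1) * rad
  a <- sin(dlat / 2)^2 + cos(lat1 * rad) * cos(lat2 * rad) * sin(dlon / 2)^2
  2 * 6371 * asin(pmin(1, sqrt(a)))
}

#' Pixels within foraging range of a colony
#'
#' Selects grid pixels whose centers lie within `radius_km` great-circle
#' distance of the colony.
#'
#' @param grid An [env_grid()].
#' @param site A [colony_site()].
#' @param radius_km Foraging radius, > 0.
#' @return Integer matrix with columns `lat_idx`, `lon_idx`; attribute
#'   `"distance_km"` carries the distances.
#' @export
pixels_in_range <- function(grid, site, radius_km) {
  if (radius_km <= 0) stop("`radius_km` must be positive")
  g <- expand.grid(lat_idx = seq_along(grid$lat),
                   lon_idx = seq_along(grid$lon), KEEP.OUT.ATTRS = FALSE)
  d <- haversine_km(site$lat, site$lon, grid$lat[g$lat_idx],
                    grid$lon[g$lon_idx])
  sel <- d <= radius_km
  if (!any(sel))
    stop("no grid pixels within ", radius_km, " km of colony ",
         site$colony_id)
  out <- as.matrix(g[sel, , drop = FALSE])
  dimnames(out) <- list(NULL, c("lat_idx", "lon_idx"))
  attr(out, "distance_km") <- d[sel]
  out
}

#' Aggregate a daily field to calendar-month means
#'
#' @param daily List with fields `variable`, `lat`, `lon`, `dates` (Date
#'   vector) and `values` (array `[day, lat, lon]`).
#' @return An [env_grid()] of per-pixel calendar-month means.
#' @export
monthly_aggregate <- function(daily) {
  stopifnot(inherits(daily$dates, "Date"),
            dim(daily$values)[1] == length(daily$dates))
  yr <- as.integer(format(daily$dates, "%Y"))
  mo <- as.integer(format(daily$dates, "%m"))
  years <- sort(unique(yr)); months <- sort(unique(mo))
  nlat <- length(daily$lat); nlon <- length(daily$lon)
  vals <- array(NA_real_, c(length(years), length(months), nlat, nlon))
  for (i in seq_along(years)) {
    for (j in seq_along(months)) {
      sel <- yr == years[i] & mo == months[j]
      if (!any(sel)) next
      sub <- daily$values[sel, , , drop = FALSE]
      vals[i, j, , ] <- apply(sub, c(2, 3), mean)
    }
  }
  env_grid(daily$variable, daily$lat, daily$lon, years, months, vals)
}

#' Per-pixel temporal standard deviation
#'
#' Sample SD (n-1 denominator) of the monthly values at each pixel over all
#' included (year, month) combinations, e.g. breeding-season months over the
#' study years. Pixels with fewer than 2 non-missing samples are `NA`.
#'
#' @param grid An [env_grid()].
#' @param months Month subset (default: all months in the grid).
#' @param year_range Optional length-2 year range filter.
#' @return Matrix `[lat, lon]` of temporal SDs.
#' @export
temporal_sd_per_pixel <- function(grid, months = grid$months,
                                  year_range = range(grid$years)) {
  mi <- which(grid$months %in% months)
  if (length(mi) == 0) stop("requested months not present in the grid")
  yi <- which(grid$years >= year_range[1] & grid$years <= year_range[2])
  sub <- grid$values[yi, mi, , , drop = FALSE]
  apply(sub, c(3, 4), function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2) NA_real_ else stats::sd(v)
  })
}

#' Temporal climate variation around a colony
#'
#' Per-pixel temporal SD of monthly values (breeding-season months over the
#' study years), averaged across all pixels within the species' foraging
#' range of the colony -- the "temporal variation in climate" metric (one
#' value per series). Missing (land) pixels are excluded.
#'
#' @param grid An [env_grid()].
#' @param site A [colony_site()].
#' @param species A [species_params()] (foraging range and breeding months),
#'   or a numeric radius via `radius_km`.
#' @param months Months used (default: the species' breeding months that are
#'   present in the grid).
#' @param year_range Year range (default: grid span).
#' @param radius_km Override for the foraging radius.
#' @return One-row data.frame (colony_id, variable, metric_kind, value,
#'   n_pixels).
#' @export
climate_temporal_variation <- function(grid, site, species = NULL,
                                       months = NULL,
                                       year_range = range(grid$years),
                                       radius_km = NULL) {
  r <- radius_km %||% species$foraging_range_km
  if (is.null(months))
    months <- if (!is.null(species))
      intersect(species$breeding_months, grid$months) else grid$months
  px <- pixels_in_range(grid, site, r)
  sdf <- temporal_sd_per_pixel(grid, months, year_range)
  vals <- sdf[px]
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0)
    stop("all buffer pixels missing for colony ", site$colony_id)
  data.frame(colony_id = site$colony_id, variable = grid$variable,
             metric_kind = "temporal_climate", value = mean(vals),
             n_pixels = length(vals), stringsAsFactors = FALSE)
}

#' Spatiotemporal resource variation around a colony
#'
#' Spatial sample SD, across buffer pixels, of the per-pixel temporal SDs --
#' the "spatiotemporal variation in resources" metric. Needs at least 2
#' non-missing pixels in the buffer.
#'
#' @inheritParams climate_temporal_variation
#' @return One-row data.frame as in [climate_temporal_variation()].
#' @export
resource_spatiotemporal_variation <- function(grid, site, species = NULL,
                                              months = NULL,
                                              year_range = range(grid$years),
                                              radius_km = NULL) {
  r <- radius_km %||% species$foraging_range_km
  if (is.null(months))
    months <- if (!is.null(species))
      intersect(species$breeding_months, grid$months) else grid$months
  px <- pixels_in_range(grid, site, r)
  sdf <- temporal_sd_per_pixel(grid, months, year_range)
  vals <- sdf[px]
  vals <- vals[!is.na(vals)]
  if (length(vals) < 2)
    stop("spatial SD undefined: fewer than 2 usable buffer pixels for ",
         site$colony_id)
  data.frame(colony_id = site$colony_id, variable = grid$variable,
             metric_kind = "spatiotemporal_resource", value = stats::sd(vals),
             n_pixels = length(vals), stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
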