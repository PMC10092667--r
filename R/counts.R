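#' Annual colony count time series
#'
#' Container for one breeding colony's annual counts. Years are stored on a
#' contiguous annual grid between the first and last surveyed year; years
#' without a count are `NA` ("missing" in the monitoring-programme sense, and
#' latent variables during model fitting). The count unit records whether the
#' series counts breeding pairs or individual birds; individuals series need
#' an individuals-to-pairs conversion at fitting time.
#'
#' @param colony_id Colony label.
#' @param species Species label.
#' @param years Integer vector of years (strictly increasing; gaps allowed,
#'   they are filled with `NA` counts).
#' @param counts Non-negative integer counts, `NA` for missing years. Same
#'   length as `years`.
#' @param unit `"pairs"` or `"individuals"`.
#' @return An object of class `count_series`.
#' @examples
#' count_series("c1", "kittiwake", 1990:1999, c(10:14, NA, 16:19), "pairs")
#' @export
count_series <- function(colony_id, species, years, counts,
                         unit = c("pairs", "individuals")) {
  unit <- match.arg(unit)
  years <- as.integer(years)
  if (length(years) != length(counts))
    stop("`years` and `counts` must have the same length")
  if (length(years) > 1 && any(diff(years) <= 0))
    stop("`years` must be strictly increasing")
  if (all(is.na(counts)))
    stop("a count series needs at least one non-missing count")
  if (any(counts < 0, na.rm = TRUE))
    stop("counts must be non-negative")
  # expand to a contiguous annual grid
  full <- seq(min(years), max(years))
  cnt <- rep(NA_real_, length(full))
  cnt[match(years, full)] <- as.numeric(counts)
  structure(
    list(colony_id = as.character(colony_id),
         species = as.character(species),
         years = as.integer(full),
         counts = cnt,
         unit = unit),
    class = "count_series")
}

#' @export
print.count_series <- function(x, ...) {
  cat(sprintf("<count_series> %s (%s), %d-%d, %d years, %d observed, unit=%s\n",
              x$colony_id, x$species, min(x$years), max(x$years),
              length(x$years), sum(!is.na(x$counts)), x$unit))
  invisible(x)
}

#' Number of non-missing counts in a series
#' @param series A `count_series`.
#' @return Integer count of observed years.
#' @export
n_observed <- function(series) sum(!is.na(series$counts))

#' First non-missing count of a series
#' @param series A `count_series`.
#' @return The earliest observed count.
#' @export
first_count <- function(series) series$counts[which(!is.na(series$counts))[1]]

#' Convert a list of count series to a tidy table
#'
#' @param collection List of `count_series`.
#' @param keep_missing Keep rows for missing years (blank count)?
#' @return `data.frame` with columns colony_id, species, year, count, unit.
#' @export
counts_to_table <- function(collection, keep_missing = TRUE) {
  rows <- lapply(collection, function(s) {
    d <- data.frame(colony_id = s$colony_id, species = s$species,
                    year = s$years, count = s$counts, unit = s$unit,
                    stringsAsFactors = FALSE)
    if (!keep_missing) d <- d[!is.na(d$count), , drop = FALSE]
    d
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Build count series from a tidy table
#'
#' Inverse of [counts_to_table()]. Rows with blank/NA counts mark missing
#' years.
#'
#' @param tab `data.frame` with columns colony_id, species, year, count, unit.
#' @return List of `count_series`, one per colony_id.
#' @export
table_to_counts <- function(tab) {
  need <- c("colony_id", "species", "year", "count", "unit")
  if (!all(need %in% names(tab)))
    stop("count table needs columns: ", paste(need, collapse = ", "))
  lapply(split(tab, tab$colony_id), function(d) {
    d <- d[order(d$year), , drop = FALSE]
    count_series(d$colony_id[1], d$species[1], d$year, d$count, d$unit[1])
  })
}

#' Read / write count tables
#'
#' Delimited (CSV) count tables with one row per colony-year; blank counts
#' denote missing years.
#'
#' @param path File path.
#' @return `read_counts`: a list of `count_series`.
#' @export
read_counts <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  table_to_counts(tab)
}

#' @rdname read_counts
#' @param collection List of `count_series`.
#' @export
write_counts <- function(collection, path) {
  utils::write.csv(counts_to_table(collection), path, row.names = FALSE,
                   na = "")
  invisible(path)
}

#' Individuals-to-pairs conversion series
#'
#' Annual smoothed conversion factor from counts of individuals to breeding
#' pairs: mean `m_kt` and pointwise standard error `s_kt` of the smoother.
#'
#' @param years Integer years.
#' @param m_kt Smoothed conversion means (> 0).
#' @param s_kt Pointwise standard errors (>= 0); recycled if scalar.
#' @return Object of class `conversion_series`.
#' @export
conversion_series <- function(years, m_kt, s_kt) {
  s_kt <- rep_len(s_kt, length(years))
  if (length(m_kt) != length(years))
    stop("`m_kt` must match `years`")
  if (any(m_kt <= 0)) stop("conversion means must be positive")
  if (any(s_kt < 0)) stop("conversion standard errors must be non-negative")
  structure(list(years = as.integer(years), m_kt = as.numeric(m_kt),
                 s_kt = as.numeric(s_kt)),
            class = "conversion_series")
}

#' Species life-history configuration
#'
#' Life-history quantities used by the model priors and the environmental
#' buffers: maximum clutch size `c` (eggs per pair per year), a floor `u` on
#' annual adult survival, the foraging range radius, and the breeding-season
#' months over which environmental metrics are computed.
#'
#' @param species Species label.
#' @param clutch_max Maximum clutch size, > 0.
#' @param survival_floor Annual survival lower bound in (0, 1); 0.2 is the
#'   conservative default used for all species.
#' @param foraging_range_km Foraging radius around the colony, > 0.
#' @param breeding_months Months (1-12) when birds associate with colonies;
#'   defaults to April-July.
#' @return Object of class `species_params`.
#' @export
species_params <- function(species, clutch_max, survival_floor = 0.2,
                           foraging_range_km = 50,
                           breeding_months = 4:7) {
  if (clutch_max <= 0) stop("`clutch_max` must be positive")
  if (survival_floor <= 0 || survival_floor >= 1)
    stop("`survival_floor` must lie in (0, 1)")
  if (foraging_range_km <= 0) stop("`foraging_range_km` must be positive")
  if (!all(breeding_months %in% 1:12)) stop("months must be in 1..12")
  structure(list(species = as.character(species),
                 clutch_max = clutch_max,
                 survival_floor = survival_floor,
                 foraging_range_km = foraging_range_km,
                 breeding_months = as.integer(breeding_months)),
            class = "species_params")
}
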