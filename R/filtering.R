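#' Colony-selection filters
#'
#' Data-selection rules applied to a collection of colony count series before
#' model fitting, in the order: minimum years with counts, low-maximum-count
#' sub-sites, low-first-count colonies, leading-gap truncation. Each filter
#' attaches a `"drops"` attribute naming the series it removed so the
#' pipeline can report per-rule drop counts.
#'
#' @name colony_filters
NULL

with_drops <- function(kept, dropped_ids, rule) {
  dropped_ids <- as.character(dropped_ids)
  attr(kept, "drops") <- data.frame(rule = rep(rule, length(dropped_ids)),
                                    colony_id = dropped_ids,
                                    stringsAsFactors = FALSE)
  kept
}

#' Keep series with enough years of counts
#'
#' Retains series with at least `min_years` non-missing annual counts
#' (number of observed years, not calendar span).
#'
#' @param collection List of [count_series()].
#' @param min_years Minimum number of observed counts, >= 1 (default 20).
#' @return Filtered collection, with a `"drops"` attribute.
#' @export
filter_min_years <- function(collection, min_years = 20) {
  if (min_years < 1) stop("`min_years` must be at least 1")
  keep <- vapply(collection, n_observed, 1L) >= min_years
  with_drops(collection[keep],
             vapply(collection[!keep], `[[`, "", "colony_id"),
             "min_years")
}

quantile7 <- function(x, q) as.numeric(stats::quantile(x, q, type = 7))

filter_by_species_quantile <- function(collection, q, stat_fun, rule) {
  if (q < 0 || q > 1) stop("`q` must lie in [0, 1]")
  species <- vapply(collection, `[[`, "", "species")
  stat <- vapply(collection, stat_fun, 1.0)
  keep <- rep(TRUE, length(collection))
  for (sp in unique(species)) {
    idx <- which(species == sp)
    thr <- quantile7(stat[idx], q)
    keep[idx] <- stat[idx] >= thr
  }
  with_drops(collection[keep],
             vapply(collection[!keep], `[[`, "", "colony_id"), rule)
}

#' Drop low-maximum-count sub-sites
#'
#' Within each species, drops series whose maximum observed count is below
#' the `q` sample quantile (type 7) of the per-series maximum counts. Removes
#' SMP-style "sub-sites" (partial colony sections) with very low numbers.
#'
#' @inheritParams filter_min_years
#' @param q Quantile level (default 0.10).
#' @return Filtered collection, with a `"drops"` attribute.
#' @export
filter_low_max_count <- function(collection, q = 0.10) {
  filter_by_species_quantile(collection, q,
                             function(s) max(s$counts, na.rm = TRUE),
                             "low_max_count")
}

#' Drop low-first-count colonies
#'
#' Within each species, drops series whose first observed count is below the
#' `q` sample quantile (type 7) of the per-series first observed counts.
#'
#' @inheritParams filter_low_max_count
#' @export
filter_low_first_count <- function(collection, q = 0.05) {
  filter_by_species_quantile(collection, q, first_count, "low_first_count")
}

#' Truncate a sporadic leading observation
#'
#' If the gap between the first observed count and the next observed count
#' exceeds `max_gap` years, the first observation is removed (applied once,
#' not iterated: a one-time correction for sporadic pre-programme counts).
#'
#' @param series A [count_series()].
#' @param max_gap Maximum allowed leading gap in years (default 5; a gap of
#'   exactly `max_gap` is kept).
#' @return The (possibly truncated) series.
#' @export
truncate_leading_gap <- function(series, max_gap = 5) {
  obs <- which(!is.na(series$counts))
  if (length(obs) < 2) return(series)
  gap <- series$years[obs[2]] - series$years[obs[1]]
  if (gap <= max_gap) return(series)
  keep <- obs[-1]
  count_series(series$colony_id, series$species,
               series$years[seq(min(keep), max(obs))],
               series$counts[seq(min(keep), max(obs))], series$unit)
}

#' Apply the full colony-selection pipeline
#'
#' Composes the four filters in their canonical order (minimum years ->
#' low-max -> low-first -> leading-gap truncation) and collects a per-rule
#' drop report.
#'
#' @param collection List of [count_series()].
#' @param min_years,max_q,first_q,max_gap Rule thresholds; see the individual
#'   filters.
#' @return The filtered collection; attribute `"report"` is a data.frame of
#'   per-rule drop counts, attribute `"drops"` the per-series detail.
#' @export
filter_colonies <- function(collection, min_years = 20, max_q = 0.10,
                            first_q = 0.05, max_gap = 5) {
  steps <- list()
  out <- filter_min_years(collection, min_years)
  steps$min_years <- attr(out, "drops")
  out <- filter_low_max_count(out, max_q)
  steps$low_max_count <- attr(out, "drops")
  out <- filter_low_first_count(out, first_q)
  steps$low_first_count <- attr(out, "drops")
  truncated <- vapply(out, function(s) {
    obs <- which(!is.na(s$counts))
    length(obs) >= 2 && (s$years[obs[2]] - s$years[obs[1]]) > max_gap
  }, TRUE)
  out <- lapply(out, truncate_leading_gap, max_gap = max_gap)
  drops <- do.call(rbind, steps)
  report <- data.frame(
    rule = c("min_years", "low_max_count", "low_first_count",
             "leading_gap_truncated"),
    n = c(vapply(steps, nrow, 1L), sum(truncated)))
  attr(out, "drops") <- drops
  attr(out, "report") <- report
  out
}

#' Smooth empirical individuals-to-pairs ratios
#'
#' Fits a penalized regression spline (GAM, [mgcv::gam()]) to empirical
#' annual conversion ratios and returns the smooth trajectory with pointwise
#' standard errors. With fewer than 4 points the fallback is a constant fit
#' at the sample mean with the standard error of the mean.
#'
#' @param years Years of the empirical ratios.
#' @param ratios Empirical individuals-to-pairs ratios, > 0.
#' @param predict_years Years at which to evaluate the smooth (default: the
#'   input years).
#' @return A [conversion_series()].
#' @export
smooth_conversion <- function(years, ratios, predict_years = years) {
  if (length(years) != length(ratios)) stop("length mismatch")
  if (any(ratios <= 0)) stop("ratios must be positive")
  n <- length(years)
  if (n < 4 || length(unique(ratios)) == 1) {
    m <- rep(mean(ratios), length(predict_years))
    se <- if (n > 1) stats::sd(ratios) / sqrt(n) else 0
    return(conversion_series(predict_years, m, se))
  }
  k <- max(3, min(10, n - 1))
  fit <- mgcv::gam(ratios ~ s(years, k = k), method = "REML",
                   data = data.frame(years = years, ratios = ratios))
  pr <- mgcv::predict.gam(fit, newdata = data.frame(years = predict_years),
                          se.fit = TRUE)
  conversion_series(predict_years, pmax(as.numeric(pr$fit), 0.05),
                    as.numeric(pr$se.fit))
}
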