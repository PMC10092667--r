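#' Simulation specification for a colony count series
#'
#' Describes the generating process for one synthetic colony: the process
#' model (M0 density-independent, M1 direct density dependence, M2 direct +
#' delayed), its parameters, the observation unit and the missingness level.
#'
#' @param model_kind `"M0"`, `"M1"` or `"M2"`.
#' @param beta0 Intrinsic per-year log growth rate.
#' @param beta1 Direct density-dependence coefficient (per pair per year);
#'   required for M1/M2, ignored for M0.
#' @param beta2 Delayed (lag-2) density coefficient; M2 only.
#' @param sigma_eps Process SD on the log scale, >= 0.
#' @param n_years Number of years, >= 3.
#' @param N0 Initial true abundance, > 0.
#' @param count_unit `"pairs"` or `"individuals"`.
#' @param missing_fraction Fraction of years flagged missing, in [0, 1).
#' @param start_year First calendar year.
#' @param seed Integer RNG seed.
#' @return Object of class `sim_spec`.
#' @export
sim_spec <- function(model_kind = c("M1", "M0", "M2"),
                     beta0 = 0.1, beta1 = NULL, beta2 = NULL,
                     sigma_eps = 0.1, n_years = 30, N0 = 200,
                     count_unit = c("pairs", "individuals"),
                     missing_fraction = 0, start_year = 1986L,
                     seed = 1L) {
  model_kind <- match.arg(model_kind)
  count_unit <- match.arg(count_unit)
  if (n_years < 3) stop("`n_years` must be at least 3")
  if (sigma_eps < 0) stop("`sigma_eps` must be non-negative")
  if (N0 <= 0) stop("`N0` must be positive")
  if (missing_fraction < 0 || missing_fraction >= 1)
    stop("`missing_fraction` must lie in [0, 1)")
  if (model_kind == "M0") {
    beta1 <- NULL; beta2 <- NULL
  } else if (model_kind == "M1") {
    if (is.null(beta1)) stop("M1 needs `beta1`")
    beta2 <- NULL
  } else {
    if (is.null(beta1) || is.null(beta2)) stop("M2 needs `beta1` and `beta2`")
  }
  structure(list(model_kind = model_kind, beta0 = beta0, beta1 = beta1,
                 beta2 = beta2, sigma_eps = sigma_eps,
                 n_years = as.integer(n_years), N0 = N0,
                 count_unit = count_unit,
                 missing_fraction = missing_fraction,
                 start_year = as.integer(start_year),
                 seed = as.integer(seed)),
            class = "sim_spec")
}

ricker_step <- function(N_prev, N_prev2, beta0, beta1, beta2, eps, kind) {
  lograte <- beta0 + eps
  if (kind != "M0") lograte <- lograte + beta1 * N_prev
  if (kind == "M2") lograte <- lograte + beta2 * N_prev2
  N_prev * exp(lograte)
}

#' Simulate a colony count time series with known ground truth
#'
#' The latent abundance follows the chosen stochastic Ricker process with
#' log-normal process noise; observed counts are Poisson around the latent
#' state (or around `K_t * N_t` for individuals series, where the annual
#' individuals-to-pairs factor `K_t` is drawn from the supplied conversion
#' series, truncated below at 0.05). Missing years are sampled uniformly at
#' random among interior years (never the first year, which anchors the
#' initial-state prior at fitting time).
#'
#' @param spec A [sim_spec()].
#' @param conversion Optional [conversion_series()] used when
#'   `count_unit = "individuals"`; defaults to a flat 0.67 factor with SE 0.02.
#' @param obs_noise `"poisson"` (default) or `"none"` (diagnostic mode: the
#'   observation is the Poisson mean itself, so trajectories can be compared
#'   with closed-form Ricker iteration exactly).
#' @return List with `series` (a [count_series()]) and `truth` (latent `N`,
#'   process residuals `eps`, `K`, the missing-year flags and the spec).
#' @examples
#' sim <- simulate_colony_counts(sim_spec("M1", beta0 = 0.1, beta1 = -5e-4))
#' sim$series
#' @export
simulate_colony_counts <- function(spec, conversion = NULL,
                                   obs_noise = c("poisson", "none")) {
  stopifnot(inherits(spec, "sim_spec"))
  obs_noise <- match.arg(obs_noise)
  set.seed(spec$seed)
  n <- spec$n_years
  eps <- if (spec$sigma_eps > 0) stats::rnorm(n, 0, spec$sigma_eps) else
    numeric(n)
  N <- numeric(n)
  N[1] <- spec$N0
  # M2 needs two starting states; use N0 for both lags at t = 2
  for (t in 2:n) {
    N2 <- if (t >= 3) N[t - 2] else N[1]
    N[t] <- ricker_step(N[t - 1], N2, spec$beta0,
                        if (is.null(spec$beta1)) 0 else spec$beta1,
                        if (is.null(spec$beta2)) 0 else spec$beta2,
                        eps[t], spec$model_kind)
  }
  K <- rep(NA_real_, n)
  if (spec$count_unit == "individuals") {
    if (is.null(conversion))
      conversion <- conversion_series(spec$start_year + seq_len(n) - 1L,
                                      rep(0.67, n), 0.02)
    m <- conversion$m_kt[match(spec$start_year + seq_len(n) - 1L,
                               conversion$years)]
    s <- conversion$s_kt[match(spec$start_year + seq_len(n) - 1L,
                               conversion$years)]
    if (anyNA(m)) stop("conversion series does not cover the simulated years")
    K <- pmax(stats::rnorm(n, m, s), 0.05)
  }
  rate <- if (spec$count_unit == "individuals") K * N else N
  y <- if (obs_noise == "poisson") stats::rpois(n, rate) else rate
  n_miss <- round(spec$missing_fraction * n)
  miss_idx <- integer(0)
  if (n_miss > 0) {
    interior <- 2:n
    miss_idx <- sort(sample(interior, min(n_miss, length(interior))))
    y[miss_idx] <- NA
  }
  years <- spec$start_year + seq_len(n) - 1L
  series <- count_series(paste0("sim_", spec$seed), "synthetic", years, y,
                         spec$count_unit)
  list(series = series,
       truth = list(N = N, eps = eps, K = K, missing_years = years[miss_idx],
                    spec = spec))
}

#' Simulate smoothed individuals-to-pairs conversion factors
#'
#' The smoothed mean trajectory `m_kt` is a random walk with step SD
#' `wiggle_sd`, recentred on `level`; the pointwise standard error `s_kt` is
#' constant (`se`) or a supplied vector.
#'
#' @param years Integer years.
#' @param level Long-run conversion level, > 0 (0.67 is a typical value for
#'   auk individuals-to-pairs adjustment).
#' @param wiggle_sd SD of year-to-year changes of the smooth mean.
#' @param se Standard error(s) of the smoothed factor, >= 0.
#' @param seed Integer RNG seed.
#' @return A [conversion_series()].
#' @export
simulate_conversion_factors <- function(years, level = 0.67,
                                        wiggle_sd = 0.01, se = 0.02,
                                        seed = 1L) {
  if (level <= 0) stop("`level` must be positive")
  if (any(se < 0)) stop("`se` must be non-negative")
  if (wiggle_sd < 0) stop("`wiggle_sd` must be non-negative")
  set.seed(seed)
  n <- length(years)
  steps <- if (wiggle_sd > 0) stats::rnorm(n - 1, 0, wiggle_sd) else
    numeric(n - 1)
  m <- cumsum(c(0, steps))
  m <- m - mean(m) + level
  m <- pmax(m, 0.05)
  conversion_series(years, m, se)
}

#' Specification of a synthetic environmental grid
#'
#' @param variable One of `"SST"`, `"SSH"`, `"CHL"`, `"TF"`.
#' @param n_lat,n_lon Grid dimensions, > 0.
#' @param cell_km Nominal cell size (used to lay out pixel-center
#'   coordinates; ~10 km emulates the source products).
#' @param years Integer years covered.
#' @param months Month subset of 1..12.
#' @param mean_field Baseline pixel value: scalar or `n_lat x n_lon` matrix.
#' @param temporal_sd_field Per-pixel SD of monthly values: scalar or matrix,
#'   >= 0.
#' @param origin_lat,origin_lon Coordinates of the grid's south-west pixel
#'   center.
#' @param ar1 Optional AR(1) coefficient in time (robustness knob; 0 =
#'   independent draws, the default).
#' @param seed Integer RNG seed.
#' @return Object of class `env_grid_spec`.
#' @export
env_grid_spec <- function(variable = c("SST", "SSH", "CHL", "TF"),
                          n_lat = 10, n_lon = 10, cell_km = 10,
                          years = 1986:2015, months = 4:7,
                          mean_field = 10, temporal_sd_field = 1,
                          origin_lat = 56, origin_lon = -2,
                          ar1 = 0, seed = 1L) {
  variable <- match.arg(variable)
  if (n_lat <= 0 || n_lon <= 0) stop("grid dimensions must be positive")
  if (!all(months %in% 1:12)) stop("months must be in 1..12")
  mf <- matrix(mean_field, n_lat, n_lon)
  sf <- matrix(temporal_sd_field, n_lat, n_lon)
  if (any(sf < 0)) stop("`temporal_sd_field` must be non-negative everywhere")
  if (abs(ar1) >= 1) stop("`ar1` must lie in (-1, 1)")
  structure(list(variable = variable, n_lat = as.integer(n_lat),
                 n_lon = as.integer(n_lon), cell_km = cell_km,
                 years = as.integer(years), months = as.integer(months),
                 mean_field = mf, temporal_sd_field = sf,
                 origin_lat = origin_lat, origin_lon = origin_lon,
                 ar1 = ar1, seed = as.integer(seed)),
            class = "env_grid_spec")
}

#' Simulate a gridded monthly environmental field
#'
#' Monthly pixel values are `mean_field + N(0, temporal_sd_field^2)` draws,
#' independent across months and years by default (optionally AR(1) in time).
#' Pixel centers are laid out on a regular lat/lon grid whose spacing
#' corresponds to `cell_km` on a spherical Earth at the grid origin latitude.
#'
#' @param spec An [env_grid_spec()].
#' @return An [env_grid()].
#' @export
simulate_env_grid <- function(spec) {
  stopifnot(inherits(spec, "env_grid_spec"))
  set.seed(spec$seed)
  km_per_deg_lat <- pi * 6371 / 180
  dlat <- spec$cell_km / km_per_deg_lat
  dlon <- spec$cell_km / (km_per_deg_lat * cos(spec$origin_lat * pi / 180))
  lat <- spec$origin_lat + (seq_len(spec$n_lat) - 1) * dlat
  lon <- spec$origin_lon + (seq_len(spec$n_lon) - 1) * dlon
  ny <- length(spec$years); nm <- length(spec$months)
  vals <- array(NA_real_, c(ny, nm, spec$n_lat, spec$n_lon))
  nt <- ny * nm
  for (i in seq_len(spec$n_lat)) {
    for (j in seq_len(spec$n_lon)) {
      s <- spec$temporal_sd_field[i, j]
      if (s == 0) {
        z <- numeric(nt)
      } else if (spec$ar1 == 0) {
        z <- stats::rnorm(nt, 0, s)
      } else {
        # stationary AR(1) with marginal SD s
        innov_sd <- s * sqrt(1 - spec$ar1^2)
        z <- as.numeric(stats::arima.sim(list(ar = spec$ar1), nt,
                                         sd = innov_sd))
      }
      # time runs month-fastest: (year 1: m1..mk), (year 2: ...)
      vals[, , i, j] <- matrix(spec$mean_field[i, j] + z, ny, nm,
                               byrow = TRUE)
    }
  }
  env_grid(spec$variable, lat, lon, spec$years, spec$months, vals)
}

#' Simulate a stage-two density-dependence vs environment dataset
#'
#' Generates per-colony density-dependence estimates according to the
#' three-level errors-in-variables model: the true effect lies on the line
#' `alpha + beta * env`, colony-level effects scatter around it with SD
#' `sigma_D`, and stage-one estimation adds known measurement noise
#' `meas_sd`.
#'
#' @param alpha Intercept of the true relationship.
#' @param beta Slope on the environmental metric.
#' @param sigma_D Between-colony residual SD, >= 0.
#' @param n_colonies Number of colonies, >= 3.
#' @param env_range Range (length-2) from which environmental metric values
#'   are drawn uniformly; alternatively a length-`n_colonies` vector of fixed
#'   values.
#' @param meas_sd Stage-one posterior SDs: scalar or length-`n_colonies`,
#'   >= 0 (must be > 0 for fitting).
#' @param seed Integer RNG seed.
#' @return List with `estimates` (data.frame colony_id, D_est, sd_D_est),
#'   `env` (metric values) and `truth` (D_true line values, realized D,
#'   generating parameters).
#' @export
simulate_dd_env_dataset <- function(alpha, beta, sigma_D, n_colonies,
                                    env_range = c(0, 1), meas_sd = 1e-4,
                                    seed = 1L) {
  if (n_colonies < 3) stop("`n_colonies` must be at least 3")
  if (sigma_D < 0) stop("`sigma_D` must be non-negative")
  if (any(meas_sd < 0)) stop("`meas_sd` must be non-negative")
  set.seed(seed)
  env <- if (length(env_range) == 2)
    stats::runif(n_colonies, env_range[1], env_range[2]) else
      rep_len(env_range, n_colonies)
  meas_sd <- rep_len(meas_sd, n_colonies)
  D_true <- alpha + beta * env
  D <- stats::rnorm(n_colonies, D_true, sigma_D)
  D_est <- stats::rnorm(n_colonies, D, meas_sd)
  list(estimates = data.frame(colony_id = paste0("col", seq_len(n_colonies)),
                              D_est = D_est, sd_D_est = meas_sd,
                              stringsAsFactors = FALSE),
       env = env,
       truth = list(alpha = alpha, beta = beta, sigma_D = sigma_D,
                    D_true = D_true, D = D))
}
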