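#' Informative prior bounds for the intrinsic growth rate
#'
#' The per-capita population growth rate is bounded above by half the
#' maximum clutch size (all eggs fledged, no mortality) and below by the
#' survival floor `u`, giving `beta0 ~ Uniform(log u, log(1 + c/2))`.
#'
#' @param species A [species_params()].
#' @return Numeric length-2 vector `(low, high)`.
#' @examples
#' beta0_prior_bounds(species_params("kittiwake", clutch_max = 1))
#' # log(0.2)  log(1.5)
#' @export
beta0_prior_bounds <- function(species) {
  stopifnot(inherits(species, "species_params"))
  c(log(species$survival_floor), log(1 + species$clutch_max / 2))
}

#' Model specification for a state-space fit
#'
#' Collects the process-model kind and all prior bounds. The informative
#' clutch-size bounds on `beta0` take precedence over the generic
#' (-10, 10) box (which always contains them); density coefficients get the
#' diffuse (-10, 10) uniform, the process SD a Uniform(0, 2) (its upper
#' bound allows roughly 50-fold year-to-year variation, since exp(4) ~ 55),
#' and the first one or two latent states a uniform prior spanning the range
#' of the first four observed counts.
#'
#' @param kind `"M0"`, `"M1"` or `"M2"`.
#' @param species A [species_params()] (sets the `beta0` bounds).
#' @param beta1_bounds,beta2_bounds Uniform prior bounds for the density
#'   coefficients.
#' @param sigma_bounds Uniform prior bounds for the process SD.
#' @return Object of class `model_spec`.
#' @export
model_spec <- function(kind = c("M1", "M0", "M2"), species,
                       beta1_bounds = c(-10, 10), beta2_bounds = c(-10, 10),
                       sigma_bounds = c(0, 2)) {
  kind <- match.arg(kind)
  b0 <- beta0_prior_bounds(species)
  stopifnot(b0[1] < b0[2], beta1_bounds[1] < beta1_bounds[2],
            sigma_bounds[1] < sigma_bounds[2])
  structure(list(kind = kind, beta0_bounds = b0,
                 beta1_bounds = beta1_bounds, beta2_bounds = beta2_bounds,
                 sigma_bounds = sigma_bounds, species = species),
            class = "model_spec")
}

#' MCMC configuration
#'
#' Desk-scale defaults (3 chains x 10,000 iterations, 2,500 burn-in,
#' thin 5); the publication-scale settings (3 chains of 50,000-100,000 with
#' 20,000-30,000 burn-in) are reachable through the same fields.
#'
#' @param n_chains Number of chains (>= 2 for the convergence diagnostic).
#' @param n_iter Iterations per chain.
#' @param n_burnin Burn-in iterations (`n_iter > n_burnin >= 0`); step sizes
#'   adapt only during burn-in.
#' @param thin Thinning interval for stored draws.
#' @param seed Integer seed; chain `i` uses `seed + i - 1`.
#' @return Object of class `mcmc_config`.
#' @export
mcmc_config <- function(n_chains = 3, n_iter = 10000, n_burnin = 2500,
                        thin = 5, seed = 1L) {
  if (n_iter <= n_burnin || n_burnin < 0) stop("need n_iter > n_burnin >= 0")
  if (n_chains < 1) stop("need at least one chain")
  structure(list(n_chains = as.integer(n_chains), n_iter = as.integer(n_iter),
                 n_burnin = as.integer(n_burnin), thin = as.integer(thin),
                 seed = as.integer(seed)),
            class = "mcmc_config")
}

#' Log-density of the Ricker process transition
#'
#' Log-normal transition density of `N_t` given its predecessors: `log N_t`
#' is normal with mean `log N_prev + beta0 (+ beta1 N_prev) (+ beta2
#' N_prev2)` and SD `sigma_eps`. Includes the Jacobian, i.e. this is a
#' density over `N_t` itself.
#'
#' @param N_t,N_prev Current and previous abundance, > 0.
#' @param N_prev2 Lag-2 abundance (required for M2).
#' @param beta0,beta1,beta2,sigma_eps Process parameters.
#' @param kind `"M0"`, `"M1"` or `"M2"`.
#' @return Log-density (vectorized over `N_t`).
#' @export
log_process_density <- function(N_t, N_prev, N_prev2 = NULL,
                                beta0, beta1 = 0, beta2 = 0,
                                sigma_eps, kind = c("M1", "M0", "M2")) {
  kind <- match.arg(kind)
  if (any(N_t <= 0) || any(N_prev <= 0))
    stop("abundances must be positive")
  if (kind == "M2" && is.null(N_prev2))
    stop("M2 needs the lag-2 abundance `N_prev2`")
  mu <- log(N_prev) + beta0
  if (kind != "M0") mu <- mu + beta1 * N_prev
  if (kind == "M2") mu <- mu + beta2 * N_prev2
  stats::dnorm(log(N_t), mu, sigma_eps, log = TRUE) - log(N_t)
}

#' Log-density of the observation model
#'
#' Poisson log-pmf of the observed count at rate `N_t` (pairs) or
#' `K_t * N_t` (individuals).
#'
#' @param y_t Observed count (non-negative integer); `NA` is not an error
#'   here -- missing counts are latent at fit time -- and yields `NA`.
#' @param N_t Latent abundance, > 0.
#' @param K_t Conversion factor (> 0), used when `unit = "individuals"`.
#' @param unit `"pairs"` or `"individuals"`.
#' @return Log-density.
#' @export
log_obs_density <- function(y_t, N_t, K_t = NULL,
                            unit = c("pairs", "individuals")) {
  unit <- match.arg(unit)
  if (any(N_t <= 0)) stop("`N_t` must be positive")
  rate <- N_t
  if (unit == "individuals") {
    if (is.null(K_t) || any(K_t <= 0))
      stop("individuals series need a positive `K_t`")
    rate <- K_t * N_t
  }
  if (any(!is.na(y_t) & (y_t < 0 | y_t != round(y_t))))
    stop("`y_t` must be a non-negative integer count")
  stats::dpois(y_t, rate, log = TRUE)
}

init_state_bounds <- function(series) {
  obs <- series$counts[!is.na(series$counts)]
  first4 <- obs[seq_len(min(4, length(obs)))]
  lo <- min(first4); hi <- max(first4)
  if (lo == hi) {            # degenerate range: widen by +/- 10%
    lo <- lo * 0.9; hi <- hi * 1.1
  }
  lo <- max(lo, 0.5)         # counts of 0 cannot bound log N below
  c(lo, hi)
}

#' Fit a Bayesian state-space population model
#'
#' Jointly estimates the process parameters, the process SD, the latent
#' abundances (and, for individuals series, the annual conversion factors)
#' by adaptive random-walk Metropolis-within-Gibbs on the log latent states.
#' Missing counts contribute no observation term; their posterior-predictive
#' imputations are returned. Chains are initialised diffusely around the
#' prior means and convergence is summarised by the Brooks-Gelman corrected
#' potential scale reduction factor for every monitored parameter.
#'
#' @param series A [count_series()] with at least 3 usable years.
#' @param spec A [model_spec()].
#' @param mcmc An [mcmc_config()].
#' @param conversion A [conversion_series()]; required iff the series unit
#'   is `"individuals"` and a conversion exists for the species (series
#'   without one -- e.g. black guillemot -- are modelled as unadjusted
#'   individuals with `K_t` pinned at 1).
#' @param sigma_fixed Optional fixed process SD (`NULL` to estimate). `0`
#'   collapses the latent states onto the deterministic Ricker trajectory
#'   from the initial state (used by the grid-posterior oracle checks).
#' @param N1_fixed Optionally pin the initial latent state(s) at this value
#'   instead of sampling them.
#' @param rhat_threshold Convergence flag threshold (default 1.1).
#' @param k_min Lower truncation of the conversion factor prior.
#' @return Object of class `ssm_fit`: matrices of posterior draws
#'   (`draws$params`, `draws$N`, `draws$K`), per-draw observed-data
#'   log-likelihood, per-chain index, imputed missing counts, R-hat table
#'   and a `converged` flag.
#' @export
fit_state_space <- function(series, spec, mcmc = mcmc_config(),
                            conversion = NULL, sigma_fixed = NULL,
                            N1_fixed = NULL, rhat_threshold = 1.1,
                            k_min = 0.05) {
  stopifnot(inherits(series, "count_series"), inherits(spec, "model_spec"),
            inherits(mcmc, "mcmc_config"))
  if (n_observed(series) < 3)
    stop("series too short to fit (< 3 usable years): ", series$colony_id)
  y <- series$counts
  T <- length(y)
  obs <- !is.na(y)
  has_k <- series$unit == "individuals" && !is.null(conversion)
  if (series$unit == "pairs" && !is.null(conversion))
    stop("conversion supplied for a pairs series")
  mk <- rep(1, T); sk <- rep(1, T)
  if (has_k) {
    idx <- match(series$years, conversion$years)
    if (anyNA(idx)) stop("conversion series does not cover all series years")
    mk <- conversion$m_kt[idx]
    sk <- pmax(conversion$s_kt[idx], 1e-6)
  }
  n_init <- if (spec$kind == "M2") 2L else 1L
  b1 <- init_state_bounds(series)
  l1_bounds <- log(b1)
  if (!is.null(N1_fixed)) l1_bounds <- log(c(N1_fixed, N1_fixed)) + c(-1e-9, 1e-9)
  l1_only <- !is.null(sigma_fixed) && sigma_fixed == 0
  sf <- if (is.null(sigma_fixed)) -1 else sigma_fixed

  kind_i <- match(spec$kind, c("M0", "M1", "M2")) - 1L
  # diffuse-from-prior-mean initial values, one jitter per chain
  prior_mean <- c(mean(spec$beta0_bounds), 0, 0, mean(spec$sigma_bounds))
  l_init_base <- log(approx_fill(y))
  l_init_base[seq_len(n_init)] <-
    pmin(pmax(l_init_base[seq_len(n_init)], l1_bounds[1]), l1_bounds[2])

  chains <- vector("list", mcmc$n_chains)
  for (ch in seq_len(mcmc$n_chains)) {
    set.seed(mcmc$seed + ch - 1L)
    jit <- stats::rnorm(4, 0, c(0.05, 1e-4, 1e-4, 0.05))
    init_par <- prior_mean + jit
    init_par[1] <- min(max(init_par[1], spec$beta0_bounds[1] + 1e-6),
                       spec$beta0_bounds[2] - 1e-6)
    init_par[4] <- min(max(init_par[4], spec$sigma_bounds[1] + 1e-3),
                       spec$sigma_bounds[2] - 1e-3)
    init_l <- l_init_base + stats::rnorm(T, 0, 0.02)
    init_l[seq_len(n_init)] <-
      pmin(pmax(init_l[seq_len(n_init)], l1_bounds[1] + 1e-9),
           l1_bounds[2] - 1e-9)
    init_K <- pmax(stats::rnorm(T, mk, sk), k_min)
    if (!has_k) init_K <- rep(1, T)
    chains[[ch]] <- ssm_chain(
      as.numeric(y), obs, kind_i,
      spec$beta0_bounds, spec$beta1_bounds, spec$beta2_bounds,
      spec$sigma_bounds, l1_bounds, n_init,
      has_k, mk, sk, k_min, sf, l1_only,
      mcmc$n_iter, mcmc$n_burnin, mcmc$thin,
      init_par, init_l, init_K)
  }

  par_names <- c("beta0", "beta1", "beta2", "sigma")
  keep_par <- switch(spec$kind, M0 = c(1L, 4L), M1 = c(1L, 2L, 4L),
                     M2 = 1:4)
  if (l1_only || (!is.null(sigma_fixed) && sigma_fixed >= 0))
    keep_par <- setdiff(keep_par, 4L)
  params <- do.call(rbind, lapply(chains, `[[`, "params"))
  colnames(params) <- par_names
  N <- do.call(rbind, lapply(chains, `[[`, "N"))
  colnames(N) <- paste0("N_", series$years)
  K <- if (has_k) do.call(rbind, lapply(chains, `[[`, "K")) else NULL
  loglik <- unlist(lapply(chains, `[[`, "loglik"))
  n_keep <- nrow(chains[[1]]$params)
  chain_id <- rep(seq_len(mcmc$n_chains), each = n_keep)

  # R-hat on every monitored parameter (process params + each latent state)
  monitored <- cbind(params[, keep_par, drop = FALSE], log(N))
  rhat <- apply(monitored, 2, function(v)
    gelman_rubin(matrix(v, ncol = mcmc$n_chains)))
  # imputed missing counts: posterior-predictive Poisson draws
  miss <- which(!obs)
  imputed <- NULL
  if (length(miss)) {
    rates <- N[, miss, drop = FALSE]
    if (has_k) rates <- rates * K[, miss, drop = FALSE]
    imputed <- matrix(stats::rpois(length(rates), rates), nrow = nrow(N))
    colnames(imputed) <- paste0("y_", series$years[miss])
  }
  structure(list(series = series, spec = spec, mcmc = mcmc,
                 draws = list(params = params[, keep_par, drop = FALSE],
                              N = N, K = K),
                 loglik = loglik, chain = chain_id,
                 imputed = imputed, rhat = rhat,
                 converged = all(rhat < rhat_threshold, na.rm = TRUE),
                 rhat_threshold = rhat_threshold,
                 has_k = has_k, obs = obs,
                 init_bounds = b1),
            class = "ssm_fit")
}

# linear interpolation over missing counts for initial values
approx_fill <- function(y) {
  if (!anyNA(y)) return(pmax(y, 0.5))
  idx <- which(!is.na(y))
  out <- stats::approx(idx, y[idx], xout = seq_along(y), rule = 2)$y
  pmax(out, 0.5)
}

#' @export
print.ssm_fit <- function(x, ...) {
  cat(sprintf("<ssm_fit> %s, model %s, %d draws, converged: %s (max Rhat %.3f)\n",
              x$series$colony_id, x$spec$kind, length(x$loglik),
              x$converged, max(x$rhat, na.rm = TRUE)))
  print(round(posterior_summary(x), 6))
  invisible(x)
}

#' Posterior summary of a state-space fit
#'
#' @param fit An `ssm_fit`.
#' @return Matrix with posterior mean, SD and 95% credible bounds for the
#'   process parameters.
#' @export
posterior_summary <- function(fit) {
  p <- fit$draws$params
  t(apply(p, 2, function(v)
    c(mean = mean(v), sd = stats::sd(v),
      q2.5 = unname(stats::quantile(v, 0.025)),
      q97.5 = unname(stats::quantile(v, 0.975)))))
}

#' Brooks-Gelman corrected potential scale reduction factor
#'
#' The Gelman-Rubin convergence statistic with the Brooks-Gelman
#' degrees-of-freedom correction, computed per parameter from parallel
#' chains of equal length. Values near 1 indicate between-chain agreement;
#' identical chains (zero between-chain variance) give values <= 1.
#'
#' @param chains Matrix with one column per chain, or list of equal-length
#'   numeric vectors.
#' @return The corrected R-hat (scalar).
#' @export
gelman_rubin <- function(chains) {
  if (is.list(chains)) {
    len <- lengths(chains)
    if (length(unique(len)) != 1) stop("chains must have equal lengths")
    chains <- do.call(cbind, chains)
  }
  chains <- as.matrix(chains)
  m <- ncol(chains); n <- nrow(chains)
  if (m < 2) stop("need at least 2 chains for R-hat")
  xbar <- colMeans(chains)
  s2 <- apply(chains, 2, stats::var)
  W <- mean(s2)
  B <- n * stats::var(xbar)
  if (W == 0) return(1)
  sig2hat <- (n - 1) / n * W + B / n
  Vhat <- sig2hat + B / (m * n)
  # sampling variance of Vhat (Brooks & Gelman 1998), then d.f. correction
  var_V <- ((n - 1) / n)^2 * stats::var(s2) / m +
    ((m + 1) / (m * n))^2 * 2 * B^2 / (m - 1) +
    2 * ((m + 1) * (n - 1) / (m * n^2)) * (n / m) *
    (stats::cov(s2, xbar^2) - 2 * mean(xbar) * stats::cov(s2, xbar))
  df <- if (var_V > 0) 2 * Vhat^2 / var_V else Inf
  correction <- if (is.finite(df)) (df + 3) / (df + 1) else 1
  sqrt(correction * Vhat / W)
}
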