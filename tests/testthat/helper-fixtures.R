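# Shared fixtures: small species configs and fast MCMC settings for unit
# tests (the acceptance suite uses the desk-scale defaults).

toy_species <- function(clutch_max = 3) {
  species_params("toy", clutch_max = clutch_max, survival_floor = 0.2,
                 foraging_range_km = 50, breeding_months = 4:7)
}

fast_mcmc <- function(seed = 1L, n_chains = 2) {
  mcmc_config(n_chains = n_chains, n_iter = 4000, n_burnin = 1000,
              thin = 3, seed = seed)
}

# deterministic environmental grid whose per-pixel values are set directly
grid_from_values <- function(values, lat = NULL, lon = NULL,
                             years = NULL, months = NULL,
                             variable = "SST") {
  d <- dim(values)
  env_grid(variable,
           lat %||% (56 + 0.1 * (seq_len(d[3]) - 1)),
           lon %||% (-2 + 0.1 * (seq_len(d[4]) - 1)),
           years %||% (2000 + seq_len(d[1]) - 1),
           months %||% seq_len(d[2]),
           values)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# minimal hand-built ssm_fit-shaped object for assessment unit tests
fake_fit <- function(y, N_draws, loglik = NULL, K_draws = NULL,
                     beta1_draws = NULL, kind = "M1") {
  obs <- !is.na(y)
  years <- 2000 + seq_along(y) - 1
  ser <- count_series("fake", "toy", years, y, "pairs")
  params <- cbind(beta0 = rep(0, nrow(N_draws)),
                  beta1 = beta1_draws %||% rep(0, nrow(N_draws)),
                  sigma = rep(0.1, nrow(N_draws)))
  if (is.null(loglik))
    loglik <- vapply(seq_len(nrow(N_draws)), function(i)
      sum(stats::dpois(y[obs], N_draws[i, obs], log = TRUE)), 1.0)
  structure(list(series = ser,
                 spec = list(kind = kind),
                 draws = list(params = params, N = N_draws, K = K_draws),
                 loglik = loglik, obs = obs, has_k = !is.null(K_draws),
                 rhat = 1, converged = TRUE),
            class = "ssm_fit")
}
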