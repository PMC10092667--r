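# priors, transition/observation densities, convergence diagnostic and the
# MCMC sampler itself (support, reproducibility, nesting, recovery smoke).

test_that("beta0 prior bounds follow the clutch-size / survival argument", {
  expect_equal(beta0_prior_bounds(toy_species(clutch_max = 1)),
               c(log(0.2), log(1.5)), tolerance = 1e-12)
  expect_equal(beta0_prior_bounds(toy_species(clutch_max = 3)),
               c(log(0.2), log(2.5)), tolerance = 1e-12)
  # interval collapses toward (0, 0) as u -> 1, c -> 0
  b <- beta0_prior_bounds(species_params("x", clutch_max = 1e-6,
                                         survival_floor = 1 - 1e-6))
  expect_lt(max(abs(b)), 1e-5)
  expect_error(species_params("x", clutch_max = 0), "positive")
  expect_error(species_params("x", clutch_max = 1, survival_floor = 1.2),
               "\\(0, 1\\)")
})

test_that("process transition density: peak, nesting, normalization", {
  # zero residual: density is the log-normal peak term
  v <- log_process_density(100, 100, beta0 = 0.05, beta1 = -5e-4,
                           sigma_eps = 0.1, kind = "M1")
  expect_equal(v, stats::dnorm(0, 0, 0.1, log = TRUE) - log(100))
  # M0 equals M1 with beta1 = 0 across random inputs
  set.seed(1)
  for (i in 1:20) {
    Np <- stats::runif(1, 10, 500); Nt <- stats::runif(1, 10, 500)
    b0 <- stats::runif(1, -0.5, 0.5); s <- stats::runif(1, 0.05, 1)
    expect_equal(log_process_density(Nt, Np, beta0 = b0, sigma_eps = s,
                                     kind = "M0"),
                 log_process_density(Nt, Np, beta0 = b0, beta1 = 0,
                                     sigma_eps = s, kind = "M1"))
  }
  # integrates to 1 over N_t (quadrature oracle)
  Ngrid <- exp(seq(log(1), log(2000), length.out = 20000))
  dens <- exp(log_process_density(Ngrid, 100, beta0 = 0.1, beta1 = -1e-3,
                                  sigma_eps = 0.3, kind = "M1"))
  integral <- sum(diff(Ngrid) * (dens[-1] + dens[-length(dens)]) / 2)
  expect_equal(integral, 1, tolerance = 1e-3)
  expect_error(log_process_density(-1, 100, beta0 = 0, sigma_eps = 0.1),
               "positive")
  expect_error(log_process_density(10, 10, beta0 = 0, sigma_eps = 0.1,
                                   kind = "M2"), "lag-2")
})

test_that("observation density: Poisson pmf and rate equivalence", {
  expect_equal(log_obs_density(0, 1), -1)
  # library-independent oracle: log pmf via explicit log-factorial sum
  oracle <- 100 * log(100) - 100 - sum(log(1:100))
  expect_equal(log_obs_density(100, 100), oracle)
  expect_equal(log_obs_density(100, 200, K_t = 0.5, unit = "individuals"),
               log_obs_density(100, 100))
  expect_error(log_obs_density(5, -1), "positive")
  expect_error(log_obs_density(5, 200, unit = "individuals"), "K_t")
  expect_error(log_obs_density(2.5, 10), "integer")
})

test_that("Brooks-Gelman R-hat: bounds and divergence detection", {
  set.seed(42)
  x <- rnorm(1e4)
  expect_lte(gelman_rubin(cbind(x, x)), 1)        # B = 0
  two <- cbind(rnorm(1e4), rnorm(1e4))
  expect_lt(gelman_rubin(two), 1.01)
  expect_gt(gelman_rubin(cbind(rnorm(500), rnorm(500) + 10)), 1.1)
  expect_error(gelman_rubin(matrix(x, ncol = 1)), "2 chains")
  expect_error(gelman_rubin(list(1:5, 1:6)), "equal lengths")
})

test_that("posterior draws respect prior supports and are reproducible", {
  sim <- simulate_colony_counts(sim_spec("M1", beta0 = 0.2, beta1 = -1e-3,
                                         sigma_eps = 0.1, N0 = 200,
                                         n_years = 25, seed = 11,
                                         missing_fraction = 0.1))
  ms <- model_spec("M1", toy_species())
  fit <- fit_state_space(sim$series, ms, fast_mcmc(seed = 5))
  p <- fit$draws$params
  expect_true(all(p[, "beta0"] >= ms$beta0_bounds[1] &
                    p[, "beta0"] <= ms$beta0_bounds[2]))
  expect_true(all(p[, "sigma"] > 0 & p[, "sigma"] < 2))
  expect_true(all(fit$draws$N > 0))
  expect_true(all(abs(p[, "beta1"]) <= 10))
  # same seed + config reproduces the chains exactly
  fit2 <- fit_state_space(sim$series, ms, fast_mcmc(seed = 5))
  expect_identical(fit$draws$params, fit2$draws$params)
  expect_identical(fit$draws$N, fit2$draws$N)
  # series too short
  short <- count_series("s", "toy", 2000:2002, c(10, NA, NA), "pairs")
  expect_error(fit_state_space(short, ms, fast_mcmc()), "too short")
})

test_that("M1 with beta1 pinned at 0 reproduces the M0 posterior", {
  sim <- simulate_colony_counts(sim_spec("M0", beta0 = 0, sigma_eps = 0.1,
                                         N0 = 300, n_years = 25, seed = 21))
  sp <- toy_species()
  cfg <- mcmc_config(n_chains = 2, n_iter = 12000, n_burnin = 3000,
                     thin = 3, seed = 9)
  fit0 <- fit_state_space(sim$series, model_spec("M0", sp), cfg)
  pin <- model_spec("M1", sp, beta1_bounds = c(-1e-12, 1e-12))
  fit1 <- fit_state_space(sim$series, pin, cfg)
  s0 <- posterior_summary(fit0); s1 <- posterior_summary(fit1)
  expect_equal(s1["beta0", "mean"], s0["beta0", "mean"], tolerance = 0.02)
  expect_equal(s1["sigma", "mean"], s0["sigma", "mean"], tolerance = 0.02)
})

test_that("M0 recovery: posterior mean near truth; imputation tracks", {
  sim <- simulate_colony_counts(sim_spec("M0", beta0 = 0.05,
                                         sigma_eps = 0.05, N0 = 500,
                                         n_years = 30, seed = 31,
                                         missing_fraction = 0.15))
  fit <- fit_state_space(sim$series, model_spec("M0", toy_species()),
                         fast_mcmc(seed = 2))
  s <- posterior_summary(fit)
  expect_lt(abs(s["beta0", "mean"] - 0.05), 3 * s["beta0", "sd"])
  expect_true(fit$converged)
  # imputed counts track neighbouring latent abundance
  miss <- which(is.na(sim$series$counts))
  imput_mean <- colMeans(fit$imputed)
  for (j in seq_along(miss)) {
    t <- miss[j]
    nb <- mean(sim$truth$N[max(1, t - 1):min(30, t + 1)])
    expect_lt(abs(imput_mean[j] - nb) / nb, 0.25)
  }
})

test_that("individuals series with conversion recover the pairs state", {
  conv <- conversion_series(1986:2015, rep(0.67, 30), 0.02)
  sim <- simulate_colony_counts(sim_spec("M0", beta0 = 0, sigma_eps = 0.05,
                                         N0 = 600, n_years = 30,
                                         count_unit = "individuals",
                                         seed = 41), conversion = conv)
  fit <- fit_state_space(sim$series, model_spec("M0", toy_species()),
                         fast_mcmc(seed = 3), conversion = conv)
  expect_true(fit$has_k)
  expect_true(all(fit$draws$K >= 0.05))
  # latent N on pairs scale: near truth (counts are ~0.67 * N)
  Nbar <- colMeans(fit$draws$N)
  expect_lt(median(abs(Nbar - sim$truth$N) / sim$truth$N), 0.15)
  # conversion for a pairs series is an error
  psim <- simulate_colony_counts(sim_spec("M0", beta0 = 0, N0 = 100,
                                          seed = 1))
  expect_error(fit_state_space(psim$series, model_spec("M0", toy_species()),
                               fast_mcmc(), conversion = conv),
               "pairs series")
})

test_that("M2 runs and keeps its extra coefficient inside the prior box", {
  sim <- simulate_colony_counts(sim_spec("M2", beta0 = 0.3, beta1 = -1e-3,
                                         beta2 = -5e-4, sigma_eps = 0.1,
                                         N0 = 200, n_years = 30, seed = 51))
  fit <- fit_state_space(sim$series, model_spec("M2", toy_species()),
                         fast_mcmc(seed = 4))
  expect_true("beta2" %in% colnames(fit$draws$params))
  expect_true(all(abs(fit$draws$params[, "beta2"]) <= 10))
})
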