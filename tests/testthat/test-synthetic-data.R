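# synthetic-data generators: deterministic fixed points, moment checks
# against closed forms, reproducibility.

test_that("deterministic Ricker fixed points and identity dynamics", {
  # exp(0.05 - 0.0005 * 100) = 1: N stays at 100
  sim <- simulate_colony_counts(
    sim_spec("M1", beta0 = 0.05, beta1 = -5e-4, sigma_eps = 0,
             N0 = 100, n_years = 10, seed = 1),
    obs_noise = "none")
  expect_equal(sim$truth$N, rep(100, 10))
  expect_equal(sim$series$counts, rep(100, 10))
  # M0 with beta0 = 0: identity
  sim0 <- simulate_colony_counts(
    sim_spec("M0", beta0 = 0, sigma_eps = 0, N0 = 200, n_years = 8,
             seed = 1), obs_noise = "none")
  expect_equal(sim0$truth$N, rep(200, 8))
  # closed-form iteration matches in diagnostic mode with noise off
  spec <- sim_spec("M1", beta0 = 0.3, beta1 = -2e-3, sigma_eps = 0,
                   N0 = 80, n_years = 12, seed = 2)
  sim2 <- simulate_colony_counts(spec, obs_noise = "none")
  N <- numeric(12); N[1] <- 80
  for (t in 2:12) N[t] <- N[t - 1] * exp(0.3 - 2e-3 * N[t - 1])
  expect_equal(sim2$truth$N, N)
  expect_equal(sim2$series$counts, N)
})

test_that("long-run growth-rate moment matches beta0", {
  sim <- simulate_colony_counts(
    sim_spec("M1", beta0 = 0.2, beta1 = -1e-3, sigma_eps = 0.1,
             n_years = 5000, N0 = 200, seed = 99), obs_noise = "none")
  N <- sim$truth$N
  resid <- diff(log(N)) - (-1e-3) * N[-length(N)] # log growth minus DD term
  # mean eps = 0, so mean resid ~ beta0 within ~3 sigma/sqrt(n)
  expect_lt(abs(mean(resid) - 0.2), 3 * 0.1 / sqrt(4999))
})

test_that("observation layer: integer counts, missingness rules, errors", {
  sim <- simulate_colony_counts(
    sim_spec("M1", beta0 = 0.1, beta1 = -5e-4, sigma_eps = 0.1,
             n_years = 30, N0 = 200, missing_fraction = 0.2, seed = 3))
  y <- sim$series$counts
  expect_true(all(y[!is.na(y)] >= 0 & y[!is.na(y)] == round(y[!is.na(y)])))
  expect_equal(sum(is.na(y)), round(0.2 * 30))
  expect_false(is.na(y[1]))               # first year never missing
  expect_error(sim_spec("M1", beta1 = -1e-3, n_years = 2), "at least 3")
  expect_error(sim_spec("M1", beta1 = -1e-3, sigma_eps = -0.1),
               "non-negative")
  expect_error(sim_spec("M1"), "beta1")
  expect_error(sim_spec("M2", beta1 = -1e-3), "beta2")
})

test_that("individuals series use the conversion layer", {
  conv <- conversion_series(1986:2015, rep(0.5, 30), 1e-9)
  sim <- simulate_colony_counts(
    sim_spec("M0", beta0 = 0, sigma_eps = 0, N0 = 1000, n_years = 30,
             count_unit = "individuals", seed = 4), conversion = conv)
  # K ~ 0.5 almost exactly, so counts scatter around K * N = 500
  expect_equal(sim$truth$K, rep(0.5, 30), tolerance = 1e-6)
  expect_lt(abs(mean(sim$series$counts) - 500), 5 * sqrt(500 / 30))
  expect_identical(sim$series$unit, "individuals")
})

test_that("generators are seed-reproducible", {
  s1 <- simulate_colony_counts(sim_spec("M1", beta1 = -5e-4, seed = 7))
  s2 <- simulate_colony_counts(sim_spec("M1", beta1 = -5e-4, seed = 7))
  s3 <- simulate_colony_counts(sim_spec("M1", beta1 = -5e-4, seed = 8))
  expect_identical(s1$series$counts, s2$series$counts)
  expect_false(identical(s1$series$counts, s3$series$counts))
  g1 <- simulate_env_grid(env_grid_spec(seed = 5))
  g2 <- simulate_env_grid(env_grid_spec(seed = 5))
  expect_identical(g1$values, g2$values)
})

test_that("conversion-factor simulator: constants and random-walk moments", {
  cs <- simulate_conversion_factors(1986:2015, level = 0.67, wiggle_sd = 0,
                                    se = 0.02, seed = 1)
  expect_equal(cs$m_kt, rep(0.67, 30))
  expect_equal(cs$s_kt, rep(0.02, 30))
  expect_error(simulate_conversion_factors(1986:2015, se = -1),
               "non-negative")
  # SD of first differences ~ wiggle_sd (Monte Carlo over many seeds)
  d <- unlist(lapply(1:200, function(s)
    diff(simulate_conversion_factors(1981:2010, wiggle_sd = 0.01,
                                     seed = s)$m_kt)))
  expect_equal(stats::sd(d), 0.01, tolerance = 0.05)
})

test_that("environmental grid simulator matches its spec fields", {
  g0 <- simulate_env_grid(env_grid_spec(n_lat = 3, n_lon = 4,
                                        years = 2000:2005, months = 4:7,
                                        mean_field = 7,
                                        temporal_sd_field = 0, seed = 1))
  expect_true(all(g0$values == 7))
  # sd 1 over 32 years x 4 months: per-pixel sample SD within the
  # chi-square 99.9% envelope at n = 128
  g1 <- simulate_env_grid(env_grid_spec(n_lat = 4, n_lon = 4,
                                        years = 1984:2015, months = 4:7,
                                        temporal_sd_field = 1, seed = 2))
  sds <- temporal_sd_per_pixel(g1)
  n <- 128
  bounds <- sqrt(stats::qchisq(c(5e-4, 1 - 5e-4), n - 1) / (n - 1))
  expect_true(all(sds >= bounds[1] & sds <= bounds[2]))
  # spatial gradient in the mean with zero SD: temporal SDs all zero
  gm <- simulate_env_grid(env_grid_spec(n_lat = 2, n_lon = 5,
                                        mean_field = matrix(1:10, 2, 5),
                                        temporal_sd_field = 0, seed = 3))
  expect_equal(as.numeric(temporal_sd_per_pixel(gm)), rep(0, 10))
  expect_error(env_grid_spec(n_lat = 0), "positive")
  expect_error(env_grid_spec(temporal_sd_field = -1), "non-negative")
})

test_that("stage-two dataset generator: line, variance addition, OLS", {
  d0 <- simulate_dd_env_dataset(alpha = 0.01, beta = -0.02, sigma_D = 0,
                                n_colonies = 10, meas_sd = 0, seed = 1)
  expect_equal(d0$estimates$D_est, 0.01 - 0.02 * d0$env)
  expect_error(simulate_dd_env_dataset(0, 0, 0.1, n_colonies = 2), "at least 3")
  # beta = 0: SD of estimates ~ sqrt(sigma_D^2 + meas_sd^2)
  dv <- simulate_dd_env_dataset(alpha = 0, beta = 0, sigma_D = 1e-3,
                                n_colonies = 4000, meas_sd = 2e-3, seed = 2)
  expect_equal(stats::sd(dv$estimates$D_est), sqrt(1e-3^2 + 2e-3^2),
               tolerance = 0.05)
  # OLS oracle on a near-noiseless line
  dr <- simulate_dd_env_dataset(alpha = 0, beta = -0.01, sigma_D = 1e-5,
                                n_colonies = 200, meas_sd = 1e-5, seed = 3)
  ols <- stats::coef(stats::lm(dr$estimates$D_est ~ dr$env))[2]
  expect_equal(unname(ols), -0.01, tolerance = 1e-3)
})
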