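#' Expected directions of environmental relationships
#'
#' Temporal climate variation (SST, SSH) is hypothesized to strengthen
#' density dependence (more negative slope of the density coefficient on the
#' metric), spatiotemporal resource variation (CHL, TF) to weaken it
#' (positive slope).
#'
#' @param variable Optional variable name; if given, returns just its
#'   direction.
#' @return Named character vector (or single string).
#' @export
expected_directions <- function(variable = NULL) {
  map <- c(SST = "negative", SSH = "negative", CHL = "positive",
           TF = "positive")
  if (is.null(variable)) return(map)
  if (!variable %in% names(map)) stop("unknown variable: ", variable)
  unname(map[variable])
}

#' Fit the stage-two errors-in-variables regression
#'
#' Three-level Bayesian model relating stage-one density-dependence
#' estimates to one environmental metric:
#' `D_est_s ~ N(D_s, sd_D_est_s^2)` (measurement SDs fixed at the stage-one
#' posterior SDs), `D_s ~ N(alpha + beta * env_s, sigma_D^2)`, with
#' minimally informative priors `alpha, beta ~ N(0, precision 1e-4)`
#' (SD 100) and `sigma_D ~ Uniform(0, 1)`. Sampled by Gibbs: the latent
#' `D_s` and `(alpha, beta)` conditionals are conjugate normals and
#' `1/sigma_D^2` is a truncated Gamma.
#'
#' @param estimates data.frame with columns `colony_id`, `D_est` (stage-one
#'   posterior mean of the density coefficient) and `sd_D_est` (> 0).
#' @param env Numeric environmental metric values aligned to `estimates`.
#' @param expected_direction `"negative"` or `"positive"` (sets the evidence
#'   category); alternatively pass `variable` to look it up.
#' @param variable Optional variable name (`"SST"`, `"SSH"`, `"CHL"`,
#'   `"TF"`).
#' @param mcmc An [mcmc_config()] (defaults to 3 chains x 5000, 1000
#'   burn-in).
#' @param slope Set `FALSE` to fit the null (intercept-only) model used by
#'   [r_squared()].
#' @param prior_sd Prior SD of intercept and slope (default 100, i.e.
#'   precision 1e-4).
#' @return Object of class `ddreg_fit`: posterior draws of `alpha`, `beta`,
#'   `sigma_D`, direction fractions, evidence category, R-hat, and (when a
#'   slope is fitted) the R-squared against the refitted null model.
#' @export
fit_dd_env_model <- function(estimates, env, expected_direction = NULL,
                             variable = NULL,
                             mcmc = mcmc_config(n_iter = 5000,
                                                n_burnin = 1000, thin = 2),
                             slope = TRUE, prior_sd = 100) {
  if (!all(c("D_est", "sd_D_est") %in% names(estimates)))
    stop("`estimates` needs columns D_est and sd_D_est")
  n <- nrow(estimates)
  if (n < 3) stop("need at least 3 colonies")
  if (length(env) != n) stop("`env` must align with `estimates`")
  if (any(estimates$sd_D_est <= 0)) stop("`sd_D_est` must be positive")
  if (is.null(expected_direction) && !is.null(variable))
    expected_direction <- expected_directions(variable)
  degenerate <- slope && stats::sd(env) == 0
  if (degenerate)
    warning("all environmental values identical: slope unidentifiable, ",
            "posterior reflects the prior scale")

  d_est <- estimates$D_est
  v_est <- estimates$sd_D_est^2
  X <- if (slope) cbind(1, env) else cbind(rep(1, n))
  p <- ncol(X)
  prior_prec <- diag(1 / prior_sd^2, p)

  XtX <- crossprod(X)
  run_chain <- function(chain_seed) {
    set.seed(chain_seed)
    # init diffuse around data-driven values
    theta <- c(mean(d_est), if (slope) 0) + stats::rnorm(p, 0, 1e-3)
    sigma <- stats::runif(1, 0.05, 0.5)
    D <- d_est
    keep <- (mcmc$n_iter - mcmc$n_burnin) %/% mcmc$thin
    out <- matrix(NA_real_, keep, p + 1)
    k <- 0
    for (it in seq_len(mcmc$n_iter)) {
      mu <- X %*% theta
      # D_s | rest: conjugate normal
      prec <- 1 / v_est + 1 / sigma^2
      mean_d <- (d_est / v_est + mu / sigma^2) / prec
      D <- stats::rnorm(n, mean_d, 1 / sqrt(prec))
      # (alpha, beta) | D, sigma: conjugate normal (closed-form 2x2)
      A <- XtX / sigma^2 + prior_prec
      b <- crossprod(X, D) / sigma^2
      if (p == 1) {
        vm <- 1 / A[1, 1]
        theta <- b[1] * vm + sqrt(vm) * stats::rnorm(1)
      } else {
        det <- A[1, 1] * A[2, 2] - A[1, 2]^2
        V <- matrix(c(A[2, 2], -A[1, 2], -A[1, 2], A[1, 1]), 2) / det
        m <- V %*% b
        # explicit 2x2 Cholesky of V
        L11 <- sqrt(V[1, 1]); L21 <- V[2, 1] / L11
        L22 <- sqrt(V[2, 2] - L21^2)
        z <- stats::rnorm(2)
        theta <- c(m[1] + L11 * z[1], m[2] + L21 * z[1] + L22 * z[2])
      }
      # sigma_D | rest: uniform(0,1) prior on sigma =>
      # tau = sigma^-2 ~ Gamma((n-1)/2, SS/2) truncated to tau >= 1
      ss <- sum((D - X %*% theta)^2)
      sh <- (n - 1) / 2; rt <- ss / 2
      lo <- stats::pgamma(1, sh, rate = rt)
      u <- stats::runif(1, lo, 1)
      tau <- stats::qgamma(pmin(u, 1 - 1e-15), sh, rate = rt)
      sigma <- 1 / sqrt(max(tau, 1))
      if (it > mcmc$n_burnin && (it - mcmc$n_burnin) %% mcmc$thin == 0 &&
          k < keep) {
        k <- k + 1
        out[k, ] <- c(theta, sigma)
      }
    }
    out
  }

  chains <- lapply(seq_len(mcmc$n_chains),
                   function(i) run_chain(mcmc$seed + i - 1L))
  draws <- do.call(rbind, chains)
  colnames(draws) <- c("alpha", if (slope) "beta", "sigma_D")
  rhat <- vapply(colnames(draws), function(nm)
    gelman_rubin(matrix(draws[, nm], ncol = mcmc$n_chains)), 1.0)
  if (mean(draws[, "sigma_D"] > 0.99) > 0.1)
    warning("posterior mass of sigma_D piles at the Uniform(0,1) upper bound")

  frac_neg <- if (slope) mean(draws[, "beta"] < 0) else NA_real_
  category <- if (slope && !is.null(expected_direction))
    evidence_category(draws[, "beta"], expected_direction) else NA_character_

  res <- structure(list(draws = draws, n = n, slope = slope,
                        env = env, estimates = estimates,
                        expected_direction = expected_direction,
                        variable = variable,
                        frac_negative = frac_neg,
                        frac_positive = if (slope) 1 - frac_neg else NA_real_,
                        category = category, rhat = rhat,
                        mcmc = mcmc, degenerate = degenerate),
                   class = "ddreg_fit")
  if (slope) {
    null_fit <- fit_dd_env_model(estimates, env, mcmc = mcmc, slope = FALSE,
                                 prior_sd = prior_sd)
    res$r_squared <- r_squared(res, null_fit)
    res$null_fit <- null_fit
  }
  res
}

#' @export
print.ddreg_fit <- function(x, ...) {
  if (x$slope) {
    b <- x$draws[, "beta"]
    cat(sprintf(
      "<ddreg_fit> n=%d  slope %.3g (95%% CI %.3g, %.3g)  P(beta<0)=%.2f  %s  R2=%.3f\n",
      x$n, mean(b), stats::quantile(b, 0.025), stats::quantile(b, 0.975),
      x$frac_negative, x$category %||% "", x$r_squared))
  } else {
    cat(sprintf("<ddreg_fit> null model, n=%d\n", x$n))
  }
  invisible(x)
}

#' Evidence category for an environmental slope
#'
#' Categorizes the posterior of a slope against its hypothesized direction:
#' `"=="` strong (>= 95% of posterior mass in the expected direction),
#' `"="` weak (>= 90%), `"!=!="` strong contrary, `"!="` weak contrary,
#' `"none"` otherwise.
#'
#' @param slope_draws Posterior draws of the slope.
#' @param expected_direction `"negative"` or `"positive"`.
#' @return Category string.
#' @export
evidence_category <- function(slope_draws,
                              expected_direction = c("negative", "positive")) {
  expected_direction <- match.arg(expected_direction)
  if (length(slope_draws) == 0) stop("empty draws")
  f <- if (expected_direction == "negative") mean(slope_draws < 0) else
    mean(slope_draws > 0)
  if (f >= 0.95) return("==")
  if (f >= 0.90) return("=")
  if (1 - f >= 0.95) return("!=!=")
  if (1 - f >= 0.90) return("!=")
  "none"
}

#' Variance explained by the environmental covariate
#'
#' `R^2 = 1 - sigma_D^2(model) / sigma_D^2(null)` using posterior mean
#' residual variances, floored at 0: the proportional reduction in residual
#' variance relative to the intercept-only null model.
#'
#' @param model_fit `ddreg_fit` with the covariate.
#' @param null_fit `ddreg_fit` of the null model on the same data.
#' @return Scalar R-squared in [0, 1].
#' @export
r_squared <- function(model_fit, null_fit) {
  v_model <- mean(model_fit$draws[, "sigma_D"]^2)
  v_null <- mean(null_fit$draws[, "sigma_D"]^2)
  if (v_null == 0) stop("null residual variance is zero")
  max(0, 1 - v_model / v_null)
}

#' Table-style report row for one species x variable regression
#'
#' @param fit A `ddreg_fit` with slope.
#' @return One-row data.frame: posterior mean slope, 95% CI, % posterior in
#'   the expected direction, category, R-squared.
#' @export
ddreg_report_row <- function(fit) {
  stopifnot(fit$slope)
  b <- fit$draws[, "beta"]
  fexp <- if (identical(fit$expected_direction, "negative"))
    fit$frac_negative else fit$frac_positive
  data.frame(variable = fit$variable %||% NA_character_,
             expected = fit$expected_direction %||% NA_character_,
             slope_mean = mean(b),
             slope_lo = unname(stats::quantile(b, 0.025)),
             slope_hi = unname(stats::quantile(b, 0.975)),
             pct_expected = 100 * fexp,
             category = fit$category %||% NA_character_,
             r_squared = fit$r_squared,
             n_colonies = fit$n,
             stringsAsFactors = FALSE)
}
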