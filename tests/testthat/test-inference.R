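test_that("corrected scores standardize against the null moments", {
  mo <- tibble::tibble(id = "p", mean = 1.0517, var = 1.1052)
  expect_equal(corrected_z(1.0517, mo), 0)
  expect_equal(corrected_z(3, tibble::tibble(id = "p", mean = 0, var = 4)),
               1.5)
  # zero fitted confounding reduces the correction to the identity
  sim <- gen_estimation_data(sim_config(I = 30, seed = 31))
  z <- compute_z(sim$providers)$z
  mo0 <- null_moments(sim$providers, nu = 0, sigma2_alpha = 0)
  expect_equal(corrected_z(z, mo0), z)
})

test_that("frequentist flagging is strict at the threshold", {
  expect_equal(as.character(flag_frequentist(c(-2, 1.96, 2.5), 1.96)),
               c("low", "null", "high"))
  expect_equal(as.character(flag_frequentist(2.5, 3)), "null")
  expect_equal(as.character(flag_frequentist(-1.96, 1.96)), "null")
  expect_error(flag_frequentist(1, threshold = 0), "positive")
})

test_that("the confounding-effect posterior is the conjugate update", {
  # scalars with equal precision: posterior mean is half the estimate
  p <- posterior_nu(c(w = 0.5), matrix(2), prior_cov = matrix(2))
  expect_equal(unname(p$m_post), 0.25)
  expect_equal(p$Sigma_post[1, 1], 1)

  # flat-prior limit recovers the sampling distribution
  p2 <- posterior_nu(c(w = 0.5), matrix(0.04), prior_cov = matrix(1e8))
  expect_equal(unname(p2$m_post), 0.5, tolerance = 1e-6)
  expect_equal(p2$Sigma_post[1, 1], 0.04, tolerance = 1e-6)

  # P = 2 against an independently coded precision-weighting oracle
  Sn <- matrix(c(0.05, 0.02, 0.02, 0.08), 2)
  Sp <- diag(c(1, 4))
  nu_hat <- c(a = 0.3, b = -0.6)
  p3 <- posterior_nu(nu_hat, Sn, prior_cov = Sp)
  post_prec <- solve(Sp) + solve(Sn)
  m_oracle <- solve(post_prec, solve(Sn) %*% nu_hat)
  expect_equal(unname(p3$m_post), as.numeric(m_oracle), tolerance = 1e-10)
  expect_equal(p3$Sigma_post, solve(post_prec), tolerance = 1e-10,
               ignore_attr = TRUE)
  # posterior covariance never exceeds the prior (PSD ordering)
  expect_gte(min(eigen(Sp - p3$Sigma_post)$values), -1e-12)
})

test_that("posterior shrinkage never inflates the estimate", {
  set.seed(32)
  for (r in 1:20) {
    P <- sample(1:3, 1)
    A <- matrix(rnorm(P * P), P)
    Sn <- crossprod(A) + diag(1e-3, P)
    Sp <- diag(runif(P, 0.1, 10), P)
    nu_hat <- rnorm(P)
    p <- posterior_nu(setNames(nu_hat, paste0("w", 1:P)), Sn,
                      prior_cov = Sp)
    expect_lte(sqrt(sum(p$m_post^2)), sqrt(sum(nu_hat^2)) + 1e-10)
  }
})

test_that("the confounding-factor posterior has the stated log moments", {
  sim <- gen_estimation_data(sim_config(I = 20, seed = 33))
  pt <- sim$providers
  post <- structure(
    list(m_post = c(w = 0.3), Sigma_post = matrix(0.02),
         Sigma_prior = matrix(100)),
    class = "nu_posterior"
  )
  lp <- lambda_posterior(pt, post, sigma2_alpha = 0.05)
  expect_equal(lp$mu_log, pt$w * 0.3)
  expect_equal(lp$s2_log, pt$w^2 * 0.02 + 0.05)
  expect_true(all(lp$s2_log >= 0.05))

  # lognormal mean identity vs a sampling oracle
  set.seed(34)
  i <- 3
  draws <- exp(rnorm(2e5, pt$w[i] * 0.3, sqrt(pt$w[i]^2 * 0.02)) +
                 rnorm(2e5, 0, sqrt(0.05)))
  mean_cf <- exp(lp$mu_log[i] + lp$s2_log[i] / 2)
  expect_lt(abs(mean(draws) - mean_cf), 3 * sd(draws) / sqrt(2e5))
})

test_that("degenerate mixtures reduce to the closed-form Gamma", {
  d <- rstar_posterior(18, 20, mu_log = 0, s2_log = 0)
  p_grid <- c(0.025, 0.25, 0.5, 0.75, 0.975)
  expect_equal(rstar_quantile(d, p_grid), qgamma(p_grid, 20, rate = 22),
               tolerance = 1e-8)
  r_grid <- seq(0.2, 2, by = 0.2)
  expect_equal(rstar_density(d, r_grid), dgamma(r_grid, 20, rate = 22),
               tolerance = 1e-12)
  # naive posterior: O = 0, E = 2 is Gamma(2, 4) with mean 1/2
  n0 <- naive_posterior(0, 2)
  expect_equal(rstar_density(n0, 0.5), dgamma(0.5, 2, rate = 4))
  expect_equal(rstar_quantile(n0, 0.5), qgamma(0.5, 2, rate = 4),
               tolerance = 1e-8)
})

test_that("mixture distribution functions are coherent", {
  d <- rstar_posterior(50, 40, mu_log = 0.2, s2_log = 0.05)
  # quantile/CDF consistency
  for (p in c(0.05, 0.5, 0.95)) {
    expect_equal(rstar_cdf(d, rstar_quantile(d, p)), p, tolerance = 1e-6)
  }
  # normalization over a grid of shapes
  for (par in list(c(5, 4, 0, 0.1), c(50, 40, 0.2, 0.05),
                   c(0, 2, -0.3, 0.3), c(200, 180, 0.1, 0.02))) {
    dd <- rstar_posterior(par[1], par[2], par[3], par[4])
    total <- stats::integrate(function(r) rstar_density(dd, r), 0, Inf,
                              rel.tol = 1e-9)$value
    expect_equal(total, 1, tolerance = 1e-6)
  }
  # CDF nondecreasing
  r_grid <- seq(0.1, 4, length.out = 50)
  expect_true(all(diff(rstar_cdf(d, r_grid)) >= 0))
})

test_that("the mixture matches a large sampling oracle", {
  d <- rstar_posterior(50, 40, mu_log = 0.2, s2_log = 0.05)
  set.seed(35)
  B <- 2e5
  lam <- exp(rnorm(B, 0.2, sqrt(0.05)))
  draws <- rgamma(B, 52, rate = 40 * lam + 2)
  r_grid <- seq(0.3, 3.5, length.out = 120)
  ecdf_vals <- stats::ecdf(draws)(r_grid)
  expect_lt(max(abs(ecdf_vals - rstar_cdf(d, r_grid))), 0.005)
})

test_that("credible-interval flags compare the interval to one", {
  expect_equal(as.character(flag_bayes(naive_posterior(2, 30))$flag),
               "low")
  expect_equal(as.character(flag_bayes(naive_posterior(70, 30))$flag),
               "high")
  fb <- flag_bayes(naive_posterior(400, 400))
  expect_equal(as.character(fb$flag), "null")
  expect_lt(fb$ci_lo, 1)
  expect_gt(fb$ci_hi, 1)
  expect_lt(fb$ci_lo, fb$ci_hi)
  expect_error(flag_bayes(naive_posterior(10, 10), level = 1), "level")
})

test_that("confounding uncertainty widens the credible interval", {
  for (pars in list(c(30, 25, 0.1), c(100, 90, -0.2), c(10, 20, 0))) {
    base <- flag_bayes(rstar_posterior(pars[1], pars[2], pars[3], 0))
    wide <- flag_bayes(rstar_posterior(pars[1], pars[2], pars[3], 0.08))
    expect_gte((wide$ci_hi - wide$ci_lo) - (base$ci_hi - base$ci_lo),
               -1e-10)
  }
})

test_that("zero-confounding inference reduces to the naive pipeline", {
  sim <- gen_estimation_data(sim_config(I = 25, seed = 36))
  pt <- sim$providers
  fit0 <- fit_rppclc(pt, sigma2_alpha = 0)
  fit0$nu["w"] <- 0   # force the no-confounding corner
  fit0$cov_nu[] <- 0
  res <- evaluate_providers(pt, fit = fit0,
                            prior_cov = matrix(1e-12))
  naive <- evaluate_providers(pt, naive_only = TRUE)
  expect_equal(res$z_corrected, naive$z_naive, tolerance = 1e-8)
  expect_equal(res$ci_lo, naive$ci_lo, tolerance = 1e-6)
  expect_equal(res$ci_hi, naive$ci_hi, tolerance = 1e-6)
  expect_equal(res$post_median, naive$post_median, tolerance = 1e-6)
})
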