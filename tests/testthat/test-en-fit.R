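test_that("the robust initializer recovers an exact linear signal", {
  pt <- exact_score_table(nu_star = 0.4)
  init <- en_init(pt)
  expect_equal(unname(init$nu0["w"]), 0.4, tolerance = 1e-6)
  expect_equal(init$sigma2_0, 0)
  expect_equal(init$pi0_0, 0.95)
})

test_that("degenerate and deficient designs are handled", {
  df <- tibble::tibble(id = sprintf("p%d", 1:6),
                       observed = c(10, 11, 9, 12, 10, 8),
                       expected = rep(10, 6), w = 0)
  pt <- provider_table(df, covariates = "w", center = FALSE)
  expect_equal(unname(en_init(pt)$nu0), 0)
  fit <- fit_rppclc(pt)
  expect_equal(unname(fit$nu), 0)
  expect_true(all(fit$cov_nu == 0))

  df2 <- dplyr::mutate(df, w = c(-1, 0, 1, 2, -2, 0), w2 = 2 * w)
  pt2 <- provider_table(df2, covariates = c("w", "w2"), center = FALSE)
  expect_error(en_init(pt2), "w2")

  expect_error(en_init(pt[1:2, ]), "P \\+ 2")
})

test_that("null intervals are centered moments plus/minus c sd", {
  pt <- one_provider(100, 100, w = 0)
  iv <- null_intervals(pt, nu = 0, sigma2_alpha = 0, c = 2.5)
  expect_equal(iv$A, -2.5)
  expect_equal(iv$B, 2.5)
  expect_error(null_intervals(pt, 0, 0, c = -1), "positive")

  # c = Inf: no provider is ever excluded
  sim <- gen_estimation_data(sim_config(I = 50, outlier_prop = 0.2,
                                        seed = 21))
  fit <- fit_rppclc(sim$providers, c = Inf, refine = FALSE)
  expect_equal(length(fit$null_set), 50)
})

test_that("outliers at effect size 2 fall outside their null intervals", {
  sim <- gen_estimation_data(sim_config(I = 200, outlier_prop = 0.1,
                                        outlier_c = 2, seed = 22))
  z <- compute_z(sim$providers)$z
  init <- en_init(sim$providers)
  iv <- null_intervals(sim$providers, init$nu0, init$sigma2_0, c = 2.5)
  outside <- z < iv$A | z > iv$B
  expect_gte(mean(outside[sim$truth$is_outlier]), 0.8)
})

test_that("the truncated likelihood reduces to the plain normal one", {
  sim <- gen_estimation_data(sim_config(I = 40, seed = 23))
  pt <- sim$providers
  z <- compute_z(pt)$z
  iv <- tibble::tibble(id = pt$id, A = -Inf, B = Inf)
  nll <- en_negloglik(pt, z, nu = 0.2, sigma2_alpha = 0.05, pi0 = 1,
                      intervals = iv)
  mo <- null_moments(pt, 0.2, 0.05)
  expect_equal(nll, -sum(dnorm(z, mo$mean, sqrt(mo$var), log = TRUE)),
               tolerance = 1e-10)
  expect_error(en_negloglik(pt, z, 0.2, 0.05, pi0 = 0, intervals = iv),
               "pi0")
})

test_that("an excluded provider contributes -log(1 - pi0 * Q)", {
  pt <- one_provider(400, 100, w = 0)   # z = 30, far outside
  z <- compute_z(pt)$z
  iv <- tibble::tibble(id = pt$id, A = qnorm(0.025), B = qnorm(0.975))
  nll <- en_negloglik(pt, z, nu = 0, sigma2_alpha = 0, pi0 = 1,
                      intervals = iv)
  expect_equal(nll, -log(0.05), tolerance = 1e-10)
})

test_that("the fitted optimum does not fall below the initializer", {
  sim <- gen_estimation_data(sim_config(I = 150, outlier_prop = 0.1,
                                        seed = 24))
  pt <- sim$providers
  z <- compute_z(pt)$z
  init <- en_init(pt)
  fit <- fit_rppclc(pt, refine = FALSE)
  nll_init <- en_negloglik(pt, z, init$nu0, init$sigma2_0, init$pi0_0,
                           fit$intervals)
  expect_lte(-fit$loglik, nll_init + 1e-8)
  expect_true(fit$converged)
  expect_gt(fit$n_iter, 0)
})

test_that("without truncation the robust fit equals the normal MLE", {
  sim <- gen_estimation_data(sim_config(I = 120, seed = 25))
  f_inf <- fit_rppclc(sim$providers, c = Inf)
  f_mle <- fit_normal_mle(sim$providers)
  expect_equal(unname(f_inf$nu), unname(f_mle$nu), tolerance = 1e-4)
  expect_equal(f_inf$sigma2_alpha, f_mle$sigma2_alpha, tolerance = 1e-4)
  expect_equal(f_inf$pi0, 1, tolerance = 1e-3)
})

test_that("normal-family MLE with zero overdispersion is least squares", {
  cfg <- sim_config(I = 60, family = "normal", mu_star = -1,
                    sigma2_alpha = 0, seed = 26)
  sim <- gen_estimation_data(cfg)
  pt <- sim$providers
  fit <- fit_normal_mle(pt, sigma2_alpha = 0)
  z <- compute_z(pt)$z
  x <- sqrt(pt$effective_size) * pt$w
  ols <- sum(x * z) / sum(x^2)
  expect_equal(unname(fit$nu["w"]), ols, tolerance = 1e-6)
})

test_that("sandwich covariance has the stated closed forms and scaling", {
  df <- tibble::tibble(id = sprintf("p%d", 1:5),
                       observed = c(40, 60, 80, 100, 150),
                       expected = c(40, 60, 80, 100, 150),
                       w = c(-1, -0.5, 0, 0.5, 1))
  pt <- provider_table(df, covariates = "w", center = FALSE)
  # nu = 0, sigma2 = 0: Omega = I, so the sandwich is the OLS variance
  S <- sandwich_cov(pt, nu = 0, sigma2_alpha = 0, null_ids = pt$id)
  expect_equal(S[1, 1], 1 / sum(pt$expected * pt$w^2), tolerance = 1e-12)

  # scaling every effective size by 4 (Omega unchanged) quarters it
  df4 <- dplyr::mutate(df, observed = observed * 4, expected = expected * 4)
  pt4 <- provider_table(df4, covariates = "w", center = FALSE)
  S4 <- sandwich_cov(pt4, nu = 0, sigma2_alpha = 0, null_ids = pt4$id)
  expect_equal(S4[1, 1], S[1, 1] / 4, tolerance = 1e-12)

  expect_error(sandwich_cov(pt, 0, 0, null_ids = character(0)),
               "smaller than")
})

test_that("sandwich standard errors track the Monte-Carlo spread", {
  cfg <- sim_config(I = 150)
  set.seed(27)
  reps <- 60
  est <- se <- numeric(reps)
  for (r in seq_len(reps)) {
    sim <- gen_estimation_data(cfg)
    fit <- fit_rppclc(sim$providers)
    est[r] <- fit$nu["w"]
    se[r] <- sqrt(fit$cov_nu[1, 1])
  }
  expect_lt(abs(mean(se) - sd(est)) / sd(est), 0.25)
})
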