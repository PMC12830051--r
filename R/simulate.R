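#' Configuration for the synthetic provider studies
#'
#' Collects the generating-model parameters for the Monte-Carlo studies.
#' Defaults describe the reference design used throughout the package's
#' experiments: 200 Poisson clusters with sizes equally spaced (after
#' rounding) between 50 and 450 patients, a single standard-normal
#' cluster confounder with effect `nu = 0.25`, unobserved heterogeneity
#' `sigma2_alpha = 0.1`, patient risk factor \eqn{X_{ij} \sim N(-0.4, 0.5)}
#' (mean, variance) with effect `beta = 1`, and outlying providers (a
#' configurable fraction) whose quality effect is
#' \eqn{\gamma^*_i = c + 0.5 W_i}.
#'
#' `mu_star` fixes the outcome scale: the default 0.15 makes the marginal
#' per-patient expected count 1, so expected counts span the same 50-450
#' range as the cluster sizes — the scale of national transplant-program
#' reports. Distribution parameters written as pairs are (mean, variance)
#' throughout.
#'
#' @param I Number of clusters.
#' @param n_range Smallest and largest cluster size.
#' @param mu_star Population norm on the linear-predictor scale.
#' @param beta Patient-level risk-factor effect.
#' @param nu Cluster-confounder effect (scalar; the design has one
#'   confounder).
#' @param sigma2_alpha Variance of the unobserved cluster effect.
#' @param outlier_prop Fraction of providers with a non-null quality
#'   effect, in `[0, 1)`. The first `round(outlier_prop * I)` clusters are
#'   the outliers.
#' @param outlier_c Outlier effect-size constant `c` in
#'   \eqn{\gamma^* = c + 0.5 W}.
#' @param family `"poisson"` or `"normal"` patient outcomes.
#' @param sigma2_eps Residual variance for normal outcomes.
#' @param x_mean,x_var Mean and variance of the patient risk factor.
#' @param sigma2_gamma,alpha_gamma_cor Optional random-null extension: when
#'   `sigma2_gamma > 0`, null providers receive
#'   \eqn{\gamma^* \sim N(0, \sigma^2_\gamma)} correlated with
#'   \eqn{\alpha} at `alpha_gamma_cor`.
#' @param special Optional list describing the audited provider (index 1)
#'   for flagging studies: `W1` (its confounder value), `gamma1` (its
#'   quality effect), `n1` (its size). See [run_inference_study()].
#' @param seed Optional integer seed; generators are pure functions of
#'   (config, seed).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(I = 200, n_range = c(50, 450), mu_star = 0.15,
                       beta = 1, nu = 0.25, sigma2_alpha = 0.1,
                       outlier_prop = 0, outlier_c = 2,
                       family = c("poisson", "normal"), sigma2_eps = 1,
                       x_mean = -0.4, x_var = 0.5,
                       sigma2_gamma = 0, alpha_gamma_cor = 0,
                       special = NULL, seed = NULL) {
  family <- match.arg(family)
  stopifnot(
    I >= 3, length(n_range) == 2, n_range[1] >= 1,
    n_range[1] <= n_range[2],
    sigma2_alpha >= 0, sigma2_eps > 0, x_var > 0,
    outlier_prop >= 0, outlier_prop < 1,
    sigma2_gamma >= 0, abs(alpha_gamma_cor) <= 1
  )
  if (!is.null(special)) {
    bad <- setdiff(names(special), c("W1", "gamma1", "n1"))
    if (length(bad)) {
      abort(sprintf("Unknown `special` field(s): %s.",
                    paste(bad, collapse = ", ")))
    }
  }
  structure(
    list(I = I, n_range = n_range, mu_star = mu_star, beta = beta,
         nu = nu, sigma2_alpha = sigma2_alpha,
         outlier_prop = outlier_prop, outlier_c = outlier_c,
         family = family, sigma2_eps = sigma2_eps,
         x_mean = x_mean, x_var = x_var,
         sigma2_gamma = sigma2_gamma, alpha_gamma_cor = alpha_gamma_cor,
         special = special, seed = seed),
    class = "sim_config"
  )
}

cluster_sizes <- function(cfg) {
  n <- round(seq(cfg$n_range[1], cfg$n_range[2], length.out = cfg$I))
  if (!is.null(cfg$special$n1)) n[1] <- cfg$special$n1
  as.integer(n)
}

#' Generate synthetic provider summaries from the clustered GLM
#'
#' Draws one synthetic national cohort: cluster confounder
#' \eqn{W_i \sim N(0, 1)}, unobserved effect
#' \eqn{\alpha_i \sim N(0, \sigma^2_\alpha)}, patient risk factors
#' \eqn{X_{ij} \sim N(x_{mean}, x_{var})}, and outcomes from
#' \deqn{\theta^*_{ij} = \mu^* + \gamma^*_i + \beta X_{ij} + \nu W_i
#'   + \alpha_i}
#' (Poisson with log link, or normal with identity link). The published
#' summaries are then assembled exactly as a registry would: observed
#' counts \eqn{O_i}, expected counts
#' \eqn{E_i = \sum_j b'(\mu^* + \beta X_{ij})} from the patient-level risk
#' model that ignores cluster terms, and effective sizes. For Poisson
#' outcomes the cluster total is drawn as
#' \eqn{O_i \sim Pois(E_i e^{\gamma^*_i + \nu W_i + \alpha_i})},
#' which is the exact distribution of the patient-level sum given the
#' risk factors.
#'
#' @param cfg A [sim_config()].
#' @return A list with `providers` (a `provider_tbl`, covariates left
#'   uncentered: the generator draws them with population mean zero) and
#'   `truth` (per-cluster latent values: `W`, `alpha`, `gamma_star`,
#'   `lambda` the total confounding-times-quality factor, `is_outlier`).
#' @export
gen_estimation_data <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  I <- cfg$I
  n <- cluster_sizes(cfg)
  W <- rnorm(I)
  if (!is.null(cfg$special$W1)) W[1] <- cfg$special$W1

  alpha <- rnorm(I, 0, sqrt(cfg$sigma2_alpha))
  gamma <- numeric(I)
  if (cfg$sigma2_gamma > 0) {
    # random-null extension: null gamma* correlated with alpha
    rho <- cfg$alpha_gamma_cor
    resid_sd <- sqrt(cfg$sigma2_gamma * (1 - rho^2))
    gamma <- rho * sqrt(cfg$sigma2_gamma / max(cfg$sigma2_alpha,
                                               .Machine$double.eps)) *
      alpha + rnorm(I, 0, resid_sd)
  }
  k <- round(cfg$outlier_prop * I)
  is_outlier <- seq_len(I) <= k
  if (k > 0) gamma[is_outlier] <- cfg$outlier_c + 0.5 * W[is_outlier]
  if (!is.null(cfg$special$gamma1)) {
    gamma[1] <- cfg$special$gamma1
    is_outlier[1] <- gamma[1] != 0
  }

  X <- rnorm(sum(n), cfg$x_mean, sqrt(cfg$x_var))
  grp <- rep(seq_len(I), n)
  eta_shift <- gamma + cfg$nu * W + alpha

  if (cfg$family == "poisson") {
    lam0 <- exp(cfg$mu_star + cfg$beta * X)
    E <- as.numeric(rowsum(lam0, grp))
    O <- rpois(I, E * exp(eta_shift))
    df <- tibble::tibble(id = sprintf("p%03d", seq_len(I)),
                         observed = O, expected = E, w = W)
    providers <- provider_table(df, covariates = "w",
                                family = rppclc_family("poisson"),
                                center = FALSE)
  } else {
    theta0 <- cfg$mu_star + cfg$beta * X
    E <- as.numeric(rowsum(theta0, grp))
    O <- E + n * eta_shift + rnorm(I, 0, sqrt(n * cfg$sigma2_eps))
    df <- tibble::tibble(id = sprintf("p%03d", seq_len(I)),
                         observed = O, expected = E,
                         effective_size = n, w = W)
    providers <- provider_table(df, covariates = "w",
                                family = rppclc_family("normal",
                                                       a_psi = cfg$sigma2_eps),
                                center = FALSE)
  }
  truth <- tibble::tibble(
    id = df$id, n = n, W = W, alpha = alpha, gamma_star = gamma,
    lambda = exp(gamma + cfg$nu * W + alpha), is_outlier = is_outlier
  )
  list(providers = providers, truth = truth)
}

#' Generate data from the correlated-random-effects design
#'
#' Emulates a Mundlak-type correlated-random-effects world: the cluster
#' quality effect is tied to the cluster mean of the patient risk factor,
#' \eqn{\gamma^*_i = \xi \bar X_i + \tau_i}, with
#' \eqn{\tau_i \sim N(0, \sigma^2_\tau)} contaminated by outliers (the
#' first `round(outlier_prop * I)` clusters have `outlier_c` added to
#' \eqn{\tau_i}). Patient risk factors are drawn as
#' \eqn{X_{ij} \sim N(m_{X,i}, 0.25)} with cluster means
#' \eqn{m_{X,i} \sim N(-0.4, 0.25)}; outcomes are normal
#' (\eqn{\mu^* = -6}, \eqn{\beta = 1} by default via the config).
#'
#' The summaries expose \eqn{\bar X_i} as the cluster covariate, so
#' fitting the summary-level model to them estimates the between-cluster
#' effect \eqn{\xi} without patient-level data. Expected counts are
#' computed from the risk model with the population-centered norm
#' \eqn{\mu = \mu^* + \xi E[\bar X]}, matching the convention that
#' cluster covariates have mean zero.
#'
#' @param cfg A [sim_config()]; `nu` plays the role of \eqn{\xi} and
#'   `sigma2_alpha` the role of \eqn{\sigma^2_\tau}. `x_mean`/`x_var`
#'   govern the distribution of the cluster means \eqn{m_{X,i}}; the
#'   within-cluster variance of \eqn{X_{ij}} equals `x_var`.
#' @return As [gen_estimation_data()]; the covariate column is `xbar`
#'   (centered at its sample mean during table construction).
#' @export
gen_cre_data <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$family != "normal") {
    abort("The correlated-random-effects design uses normal outcomes.")
  }
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  I <- cfg$I
  n <- cluster_sizes(cfg)
  xi <- cfg$nu
  m_X <- rnorm(I, cfg$x_mean, sqrt(cfg$x_var))
  X <- rnorm(sum(n), rep(m_X, n), sqrt(cfg$x_var))
  grp <- rep(seq_len(I), n)
  xbar <- as.numeric(rowsum(X, grp)) / n

  tau <- rnorm(I, 0, sqrt(cfg$sigma2_alpha))
  k <- round(cfg$outlier_prop * I)
  is_outlier <- seq_len(I) <= k
  if (k > 0) tau[is_outlier] <- tau[is_outlier] + cfg$outlier_c
  gamma <- xi * xbar + tau

  mu_adj <- cfg$mu_star + xi * cfg$x_mean
  theta0 <- mu_adj + cfg$beta * X
  E <- as.numeric(rowsum(theta0, grp))
  O_mean <- as.numeric(rowsum(cfg$mu_star + cfg$beta * X, grp)) + n * gamma
  O <- O_mean + rnorm(I, 0, sqrt(n * cfg$sigma2_eps))

  df <- tibble::tibble(id = sprintf("p%03d", seq_len(I)),
                       observed = O, expected = E,
                       effective_size = n, xbar = xbar)
  providers <- provider_table(df, covariates = "xbar",
                              family = rppclc_family("normal",
                                                     a_psi = cfg$sigma2_eps),
                              center = TRUE)
  truth <- tibble::tibble(
    id = df$id, n = n, xbar = xbar, tau = tau, gamma_star = gamma,
    xi = xi, is_outlier = is_outlier
  )
  list(providers = providers, truth = truth)
}
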