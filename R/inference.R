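#' Corrected Z-scores
#'
#' Standardizes each naive Z-score against its estimated conditional null
#' distribution: \eqn{z^* = (z - \hat m) / \sqrt{\hat v}}, where
#' \eqn{(\hat m, \hat v)} are the null moments evaluated at the fitted
#' confounding parameters. With \eqn{\hat\nu = 0} and
#' \eqn{\hat\sigma^2_\alpha = 0} the corrected scores equal the naive ones.
#'
#' @param z Numeric vector of naive Z-scores.
#' @param moments A tibble from [null_moments()] aligned with `z`.
#' @return Numeric vector of corrected scores.
#' @export
corrected_z <- function(z, moments) {
  if (any(moments$var <= 0)) abort("Null variances must be positive.")
  (z - moments$mean) / sqrt(moments$var)
}

#' Frequentist flagging of corrected Z-scores
#'
#' Flags a provider whose corrected score is *more extreme than* the
#' threshold (strict inequality: a score exactly at the threshold is null).
#' For transplant-rate outcomes `"low"` corresponds to under-transplanting.
#'
#' @param z_star Numeric vector of corrected Z-scores.
#' @param threshold Positive flagging threshold; the default 1.96
#'   corresponds to a two-sided 0.05-level test.
#' @return A factor with levels `low`, `null`, `high`.
#' @export
flag_frequentist <- function(z_star, threshold = 1.96) {
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0) {
    abort("`threshold` must be a single positive number.")
  }
  factor(
    dplyr::case_when(
      z_star < -threshold ~ "low",
      z_star > threshold ~ "high",
      TRUE ~ "null"
    ),
    levels = c("low", "null", "high")
  )
}

#' Posterior for the confounding effects under a normal prior
#'
#' Conjugate multivariate-normal update treating the sandwich distribution
#' \eqn{\hat\nu \sim MVN(\nu, \Sigma_{\hat\nu})} as the likelihood and
#' \eqn{\nu \sim MVN(0, \Sigma_{prior})} as the prior:
#' \deqn{m_{post} = \Sigma_{prior}(\Sigma_{prior} + \Sigma_{\hat\nu})^{-1}
#'   \hat\nu, \qquad
#'   \Sigma_{post} = (\Sigma_{prior}^{-1} + \Sigma_{\hat\nu}^{-1})^{-1}.}
#' The default prior is weakly informative: diagonal with variance 100 per
#' centered-covariate coefficient, whose flat-prior limit recovers the
#' frequentist plug-in.
#'
#' When \eqn{\Sigma_{\hat\nu}} is singular (e.g. a degenerate all-zero
#' covariate) the posterior for the affected components collapses to the
#' point estimate with zero variance.
#'
#' @param nu_hat Estimated confounding effects (length P).
#' @param cov_nu Their P-by-P sandwich covariance.
#' @param prior_cov P-by-P prior covariance; default `diag(100, P)`.
#' @return An object of class `nu_posterior`: list with `m_post`,
#'   `Sigma_post`, `Sigma_prior`.
#' @export
posterior_nu <- function(nu_hat, cov_nu, prior_cov = NULL) {
  P <- length(nu_hat)
  cov_nu <- as.matrix(cov_nu)
  if (!all(dim(cov_nu) == P)) abort("`cov_nu` must be P x P.")
  if (is.null(prior_cov)) prior_cov <- diag(100, P)
  prior_cov <- as.matrix(prior_cov)
  if (!all(dim(prior_cov) == P)) abort("`prior_cov` must be P x P.")

  if (P == 0L) {
    return(structure(list(m_post = numeric(0),
                          Sigma_post = cov_nu,
                          Sigma_prior = prior_cov),
                     class = "nu_posterior"))
  }
  tot <- prior_cov + cov_nu
  if (rcond(tot) < 1e-14) {
    abort("Prior plus sampling covariance is numerically singular; regularize the prior.")
  }
  gain <- prior_cov %*% solve(tot)
  m_post <- as.numeric(gain %*% nu_hat)
  # (Sprior^-1 + Scov^-1)^-1 written without inverting a possibly
  # singular sampling covariance: gain %*% cov_nu
  Sigma_post <- gain %*% cov_nu
  Sigma_post <- (Sigma_post + t(Sigma_post)) / 2
  structure(
    list(m_post = setNames(m_post, names(nu_hat)),
         Sigma_post = Sigma_post, Sigma_prior = prior_cov),
    class = "nu_posterior"
  )
}

#' Lognormal posterior for the total confounding factor
#'
#' For each provider, the total (observed plus unobserved) cluster-level
#' confounding factor \eqn{\Lambda_i = \exp(W_i^\top\nu + \alpha_i)} has
#' the approximate posterior
#' \eqn{\mathrm{Lognormal}(W_i^\top m_{post},\;
#' W_i^\top \Sigma_{post} W_i + \sigma^2_\alpha)}: the posterior
#' uncertainty about \eqn{\nu} and the full unobserved-heterogeneity
#' variance both enter the log-scale variance, with
#' \eqn{\sigma^2_\alpha} plugged in as a known nuisance parameter.
#'
#' @param data A `provider_tbl`.
#' @param post A `nu_posterior` from [posterior_nu()].
#' @param sigma2_alpha Plug-in unobserved-confounding variance.
#' @return A tibble with columns `id`, `mu_log`, `s2_log`.
#' @export
lambda_posterior <- function(data, post, sigma2_alpha) {
  assert_provider_tbl(data)
  W <- pt_W(data)
  mu_log <- as.numeric(W %*% post$m_post)
  s2_log <- rowSums((W %*% post$Sigma_post) * W) + sigma2_alpha
  tibble::tibble(id = data$id, mu_log = mu_log, s2_log = s2_log)
}

gh_cache <- new.env(parent = emptyenv())
gh_rule <- function(nodes) {
  key <- as.character(nodes)
  if (is.null(gh_cache[[key]])) {
    gh_cache[[key]] <- pracma::gaussHermite(nodes)
  }
  gh_cache[[key]]
}

#' Posterior for the corrected measure ratio
#'
#' Builds the posterior distribution of the corrected quality measure ratio
#' \eqn{R^*_i}, which discounts the naive observed/expected ratio by the
#' total confounding factor:
#' \deqn{f_{R^*}(r) = \int \mathrm{Gamma}(r;\, O + 2,\; E\lambda + 2)\,
#'   f_\Lambda(\lambda)\, d\lambda,}
#' with \eqn{f_\Lambda} the lognormal posterior from
#' [lambda_posterior()]. The lognormal mixture is evaluated by
#' deterministic Gauss-Hermite quadrature in \eqn{\log\lambda} (default 64
#' nodes), so densities, CDFs and quantiles are reproducible bit-for-bit.
#' With `mu_log = 0, s2_log = 0` the distribution is exactly the
#' \eqn{\mathrm{Gamma}(O + 2, E + 2)} posterior of the uncorrected ratio.
#'
#' @param O Observed outcome count (\eqn{\ge 0}).
#' @param E Expected outcome count (\eqn{> 0}).
#' @param mu_log,s2_log Log-scale mean and variance of the confounding
#'   factor posterior.
#' @param nodes Number of quadrature nodes.
#' @return An object of class `rstar_dist` supporting [rstar_density()],
#'   [rstar_cdf()] and [rstar_quantile()].
#' @examples
#' d <- rstar_posterior(18, 20, 0, 0)   # Gamma(20, 22)
#' rstar_quantile(d, 0.5)
#' @export
rstar_posterior <- function(O, E, mu_log, s2_log, nodes = 64) {
  if (length(O) != 1L || length(E) != 1L || O < 0 || E <= 0) {
    abort("`O` must be >= 0 and `E` > 0 (scalars).")
  }
  if (s2_log < 0) abort("`s2_log` must be nonnegative.")
  if (s2_log == 0) {
    lam <- exp(mu_log)
    wts <- 1
  } else {
    gh <- gh_rule(nodes)
    lam <- exp(mu_log + sqrt(2 * s2_log) * gh$x)
    wts <- gh$w / sqrt(pi)
  }
  rate <- E * lam + 2
  if (any(!is.finite(rate))) abort("Quadrature produced non-finite rates.")
  structure(
    list(O = O, E = E, mu_log = mu_log, s2_log = s2_log,
         shape = O + 2, rate = rate, wts = wts),
    class = "rstar_dist"
  )
}

#' Naive measure-ratio posterior
#'
#' The \eqn{\mathrm{Gamma}(O + 2, E + 2)} posterior for the uncorrected
#' ratio \eqn{R_i} under the standard Gamma-Poisson prior-likelihood
#' framework — the baseline that ignores cluster-level confounding.
#'
#' @inheritParams rstar_posterior
#' @return An `rstar_dist`.
#' @export
naive_posterior <- function(O, E) {
  rstar_posterior(O, E, mu_log = 0, s2_log = 0)
}

#' @rdname rstar_posterior
#' @param d An `rstar_dist`.
#' @param r Ratio values.
#' @export
rstar_density <- function(d, r) {
  vapply(r, function(ri) sum(d$wts * dgamma(ri, d$shape, rate = d$rate)),
         numeric(1))
}

#' @rdname rstar_posterior
#' @export
rstar_cdf <- function(d, r) {
  vapply(r, function(ri) sum(d$wts * pgamma(ri, d$shape, rate = d$rate)),
         numeric(1))
}

#' @rdname rstar_posterior
#' @param p Probabilities in (0, 1).
#' @export
rstar_quantile <- function(d, p) {
  vapply(p, function(pi) {
    qs <- qgamma(pi, d$shape, rate = d$rate)
    lo <- min(qs); hi <- max(qs)
    if (hi - lo < .Machine$double.eps) return(lo)
    uniroot(function(r) rstar_cdf(d, r) - pi, c(lo, hi), tol = 1e-10,
            extendInt = "upX")$root
  }, numeric(1))
}

#' @export
print.rstar_dist <- function(x, ...) {
  cat(sprintf(
    "<rstar_dist: O = %g, E = %g, lognormal(%.4g, %.4g) confounding, %d component(s)>\n",
    x$O, x$E, x$mu_log, x$s2_log, length(x$rate)))
  invisible(x)
}

#' Credible-interval flagging on the measure-ratio scale
#'
#' Computes the equal-tailed credible interval of a measure-ratio posterior
#' and flags the provider when the interval excludes 1 (the national norm):
#' `"low"` if the whole interval lies below 1, `"high"` if above.
#'
#' @param d An `rstar_dist`.
#' @param level Credible level in (0, 1); default 0.95.
#' @return A list with `ci_lo`, `ci_hi`, `flag` (factor low/null/high).
#' @export
flag_bayes <- function(d, level = 0.95) {
  if (!is.numeric(level) || length(level) != 1L || level <= 0 ||
      level >= 1) {
    abort("`level` must lie in (0, 1).")
  }
  a <- (1 - level) / 2
  q <- rstar_quantile(d, c(a, 1 - a))
  flag <- if (q[2] < 1) "low" else if (q[1] > 1) "high" else "null"
  list(ci_lo = q[1], ci_hi = q[2],
       flag = factor(flag, levels = c("low", "null", "high")))
}
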