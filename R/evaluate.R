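#' Evaluate all providers against the national norm
#'
#' The end-to-end workflow on a provider summary table: naive Z-scores, the
#' robust confounding fit, corrected frequentist flags, and pseudo-Bayesian
#' credible intervals for the corrected measure ratio of every provider.
#' With `naive_only = TRUE` the confounding adjustment is skipped entirely:
#' corrected scores equal the naive ones and the posteriors are the
#' unadjusted Gamma baselines.
#'
#' @param data A `provider_tbl`.
#' @param fit Optionally a pre-computed [fit_rppclc()] (or
#'   [fit_normal_mle()]) object for the same table; fitted fresh when
#'   `NULL`.
#' @param threshold Frequentist flagging threshold (see
#'   [flag_frequentist()]).
#' @param level Credible level for the Bayes intervals.
#' @param prior_cov Prior covariance for the confounding effects (see
#'   [posterior_nu()]).
#' @param naive_only Skip all confounding adjustment?
#' @param nodes Gauss-Hermite nodes for the ratio posteriors.
#' @inheritParams fit_rppclc
#' @return A tibble of class `rppclc_results` with columns `id`, `z_naive`,
#'   `z_corrected`, `flag_freq`, `post_median`, `ci_lo`, `ci_hi`,
#'   `flag_bayes`, `in_null_set`, and the fit attached as attribute
#'   `"fit"`.
#' @examples
#' sim <- gen_estimation_data(sim_config(I = 40, seed = 2))
#' res <- evaluate_providers(sim$providers)
#' head(res)
#' @export
evaluate_providers <- function(data, fit = NULL, threshold = 1.96,
                               level = 0.95, prior_cov = NULL,
                               naive_only = FALSE, c = 2.5, refine = TRUE,
                               nodes = 64, control = list()) {
  assert_provider_tbl(data)
  z <- compute_z(data)$z
  if (pt_family(data)$family != "poisson") {
    abort(paste(
      "Measure-ratio posteriors are defined for count (Poisson) outcomes;",
      "for other families use the fit and corrected Z-scores directly."
    ))
  }

  if (naive_only) {
    ivs <- lapply(seq_len(nrow(data)), function(i) {
      flag_bayes(naive_posterior(data$observed[i], data$expected[i]),
                 level = level)
    })
    med <- vapply(seq_len(nrow(data)), function(i) {
      rstar_quantile(naive_posterior(data$observed[i], data$expected[i]),
                     0.5)
    }, numeric(1))
    out <- tibble::tibble(
      id = data$id,
      z_naive = z,
      z_corrected = z,
      flag_freq = flag_frequentist(z, threshold),
      post_median = med,
      ci_lo = vapply(ivs, `[[`, numeric(1), "ci_lo"),
      ci_hi = vapply(ivs, `[[`, numeric(1), "ci_hi"),
      flag_bayes = factor(vapply(ivs, function(x) as.character(x$flag),
                                 character(1)),
                          levels = c("low", "null", "high")),
      in_null_set = TRUE
    )
    return(structure(out, class = c("rppclc_results", class(out))))
  }

  if (is.null(fit)) {
    fit <- fit_rppclc(data, c = c, refine = refine, control = control)
  }
  mo <- null_moments(data, fit$nu, fit$sigma2_alpha)
  zs <- corrected_z(z, mo)
  post <- posterior_nu(fit$nu, fit$cov_nu, prior_cov = prior_cov)
  lp <- lambda_posterior(data, post, fit$sigma2_alpha)

  ivs <- vector("list", nrow(data))
  med <- numeric(nrow(data))
  for (i in seq_len(nrow(data))) {
    d <- rstar_posterior(data$observed[i], data$expected[i],
                         lp$mu_log[i], lp$s2_log[i], nodes = nodes)
    ivs[[i]] <- flag_bayes(d, level = level)
    med[i] <- rstar_quantile(d, 0.5)
  }
  out <- tibble::tibble(
    id = data$id,
    z_naive = z,
    z_corrected = zs,
    flag_freq = flag_frequentist(zs, threshold),
    post_median = med,
    ci_lo = vapply(ivs, `[[`, numeric(1), "ci_lo"),
    ci_hi = vapply(ivs, `[[`, numeric(1), "ci_hi"),
    flag_bayes = factor(vapply(ivs, function(x) as.character(x$flag),
                               character(1)),
                        levels = c("low", "null", "high")),
    in_null_set = data$id %in% fit$null_set
  )
  structure(out, fit = fit, class = c("rppclc_results", class(out)))
}

#' Fit report for serialization
#'
#' Condenses an `rppclc_fit` into a plain list (coefficients with Wald 95%
#' intervals, overdispersion, null proportion, null-set size, convergence
#' metadata) suitable for JSON or text output.
#'
#' @param fit An `rppclc_fit`.
#' @return A named list.
#' @export
fit_report <- function(fit) {
  td <- tidy(fit)
  list(
    package_version = as.character(utils::packageVersion("rppclc")),
    method = fit$method,
    nu = as.list(setNames(td$estimate, td$term)),
    nu_se = as.list(setNames(td$std.error, td$term)),
    nu_ci_low = as.list(setNames(td$conf.low, td$term)),
    nu_ci_high = as.list(setNames(td$conf.high, td$term)),
    sigma2_alpha = fit$sigma2_alpha,
    pi0 = fit$pi0,
    n_null = length(fit$null_set),
    nobs = nrow(fit$data),
    loglik = fit$loglik,
    converged = fit$converged,
    n_iter = fit$n_iter,
    interval_c = fit$c,
    covariate_offsets = as.list(pt_offsets(fit$data))
  )
}
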