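#' Monte-Carlo study of the confounding-effect estimators
#'
#' Repeats generate-then-fit: each replicate draws a cohort from
#' [gen_estimation_data()] (or [gen_cre_data()] when
#' `design = "cre"`) and fits both the robust empirical-null model and the
#' non-robust normal MLE. Aggregates bias and MSE for \eqn{\hat\nu} and
#' \eqn{\hat\sigma^2_\alpha} with Monte-Carlo standard errors. Replicates
#' whose fit fails are excluded and counted.
#'
#' @param cfg A [sim_config()] (its own `seed` is ignored; pass `seed`
#'   here).
#' @param reps Number of replicates.
#' @param seed Integer seed for the whole experiment.
#' @param design `"estimation"` (default) or `"cre"`.
#' @param c Null-interval half-width for the robust fit.
#' @return A tibble with one row per (estimator, parameter): columns
#'   `estimator`, `parameter`, `truth`, `mean_estimate`, `bias`, `mse`,
#'   `mc_se` (standard error of the bias; `NA` when `reps = 1`),
#'   `reps`, `failures`.
#' @export
run_estimation_study <- function(cfg, reps = 200, seed = 1,
                                 design = c("estimation", "cre"),
                                 c = 2.5) {
  design <- match.arg(design)
  stopifnot(inherits(cfg, "sim_config"), reps >= 1)
  cfg$seed <- NULL
  set.seed(seed)
  gen_fun <- if (design == "cre") gen_cre_data else gen_estimation_data

  draws <- vector("list", reps)
  failures <- 0L
  for (r in seq_len(reps)) {
    est <- tryCatch({
      sim <- gen_fun(cfg)
      f_r <- fit_rppclc(sim$providers, c = c)
      f_m <- fit_normal_mle(sim$providers)
      tibble::tibble(
        estimator = c("rppclc", "rppclc", "normal_mle", "normal_mle"),
        parameter = c("nu", "sigma2_alpha", "nu", "sigma2_alpha"),
        estimate = c(unname(f_r$nu[1]), f_r$sigma2_alpha,
                     unname(f_m$nu[1]), f_m$sigma2_alpha)
      )
    }, error = function(e) NULL)
    if (is.null(est)) failures <- failures + 1L else draws[[r]] <- est
  }
  est <- dplyr::bind_rows(draws)
  if (!nrow(est)) abort("Every replicate failed.")
  truth_tbl <- tibble::tibble(parameter = c("nu", "sigma2_alpha"),
                              truth = c(cfg$nu, cfg$sigma2_alpha))
  est |>
    dplyr::left_join(truth_tbl, by = "parameter") |>
    dplyr::group_by(.data$estimator, .data$parameter) |>
    dplyr::summarise(
      truth = .data$truth[1],
      mean_estimate = mean(.data$estimate),
      bias = mean(.data$estimate - .data$truth),
      mse = mean((.data$estimate - .data$truth)^2),
      mc_se = if (dplyr::n() > 1) {
        sd(.data$estimate) / sqrt(dplyr::n())
      } else {
        NA_real_
      },
      .groups = "drop"
    ) |>
    dplyr::mutate(reps = reps, failures = failures)
}

#' Flagging and coverage study for the audited provider
#'
#' Evaluates provider 1 — the "audited" provider, configured through
#' `cfg$special` — under the four flagging rules: naive and adjusted
#' frequentist Z-score tests, and naive and adjusted pseudo-Bayesian
#' credible intervals. Per replicate the cohort is regenerated and (unless
#' `plug_true = TRUE`) the confounding model is refitted, which is the
#' honest pipeline; `plug_true` instead plugs the generating parameter
#' values in, for calibration checks.
#'
#' The flag rate counts, per method, flags in the direction of the audited
#' provider's effect (any direction when `gamma1 = 0`, so the rate is a
#' false-flagging probability; `"low"` flags when `gamma1 < 0`; `"high"`
#' when `gamma1 > 0`). Coverage is the fraction of credible intervals
#' containing the true measure value \eqn{\exp(\gamma^*_1)} (Bayes rules
#' only).
#'
#' @inheritParams run_estimation_study
#' @param threshold,level,prior_cov,nodes Passed to the flagging rules.
#' @param plug_true Plug the true \eqn{(\nu, \sigma^2_\alpha)} in instead
#'   of estimating them (the Bayes rule then uses a degenerate posterior at
#'   the truth).
#' @return A tibble with one row per method: `method`, `flag_rate`,
#'   `coverage` (`NA` for frequentist rules), `mc_se_flag`,
#'   `mc_se_coverage`, `gamma1`, `reps`, `failures`.
#' @export
run_inference_study <- function(cfg, reps = 200, seed = 1,
                                threshold = 1.96, level = 0.95,
                                prior_cov = NULL, nodes = 64,
                                plug_true = FALSE, c = 2.5) {
  stopifnot(inherits(cfg, "sim_config"), reps >= 1)
  if (is.null(cfg$special)) {
    abort("`cfg$special` must describe the audited provider (W1, gamma1, n1).")
  }
  cfg$seed <- NULL
  gamma1 <- cfg$special$gamma1 %||% 0
  truth1 <- exp(gamma1)
  hit_dir <- function(flag) {
    if (gamma1 == 0) flag != "null"
    else if (gamma1 < 0) flag == "low"
    else flag == "high"
  }
  set.seed(seed)

  rows <- vector("list", reps)
  failures <- 0L
  for (r in seq_len(reps)) {
    one <- tryCatch({
      sim <- gen_estimation_data(cfg)
      d <- sim$providers
      z1 <- compute_z(d)$z[1]
      O1 <- d$observed[1]; E1 <- d$expected[1]

      if (plug_true) {
        nu_hat <- setNames(cfg$nu, pt_covariates(d))
        s2_hat <- cfg$sigma2_alpha
        m_post <- nu_hat
        S_post <- matrix(0, 1, 1)
      } else {
        fit <- fit_rppclc(d, c = c)
        nu_hat <- fit$nu
        s2_hat <- fit$sigma2_alpha
        post <- posterior_nu(nu_hat, fit$cov_nu, prior_cov = prior_cov)
        m_post <- post$m_post
        S_post <- post$Sigma_post
      }
      mo1 <- null_moments(d, nu_hat, s2_hat)[1, ]
      zs1 <- (z1 - mo1$mean) / sqrt(mo1$var)
      W1 <- pt_W(d)[1, , drop = TRUE]
      mu_log <- sum(W1 * m_post)
      s2_log <- as.numeric(t(W1) %*% S_post %*% W1) + s2_hat

      fb_naive <- flag_bayes(naive_posterior(O1, E1), level = level)
      fb_adj <- flag_bayes(rstar_posterior(O1, E1, mu_log, s2_log,
                                           nodes = nodes), level = level)
      tibble::tibble(
        method = c("naive_freq", "adjusted_freq", "naive_bayes",
                   "adjusted_bayes"),
        flagged = c(hit_dir(as.character(flag_frequentist(z1, threshold))),
                    hit_dir(as.character(flag_frequentist(zs1, threshold))),
                    hit_dir(as.character(fb_naive$flag)),
                    hit_dir(as.character(fb_adj$flag))),
        covered = c(NA, NA,
                    fb_naive$ci_lo <= truth1 & truth1 <= fb_naive$ci_hi,
                    fb_adj$ci_lo <= truth1 & truth1 <= fb_adj$ci_hi)
      )
    }, error = function(e) NULL)
    if (is.null(one)) failures <- failures + 1L else rows[[r]] <- one
  }
  res <- dplyr::bind_rows(rows)
  if (!nrow(res)) abort("Every replicate failed.")
  binom_se <- function(p, n) if (n > 1) sqrt(p * (1 - p) / n) else NA_real_
  res |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(
      flag_rate = mean(.data$flagged),
      coverage = mean(.data$covered),
      mc_se_flag = binom_se(mean(.data$flagged), dplyr::n()),
      mc_se_coverage = binom_se(mean(.data$covered), dplyr::n()),
      .groups = "drop"
    ) |>
    dplyr::mutate(gamma1 = gamma1, reps = reps, failures = failures) |>
    dplyr::arrange(match(.data$method, c("naive_freq", "adjusted_freq",
                                         "naive_bayes", "adjusted_bayes")))
}

#' Coverage table over a grid of audited-provider effects
#'
#' Wraps [run_inference_study()] over a grid of quality-effect magnitudes
#' for the audited provider and tabulates the empirical frequentist
#' coverage of the naive and adjusted pseudo-Bayesian credible intervals
#' for the true measure value \eqn{\exp(\gamma^*_1)}. Grid values are
#' magnitudes; `direction = "low"` (default) audits increasingly
#' low-quality care, i.e. \eqn{\gamma^*_1 = -} magnitude.
#'
#' @inheritParams run_inference_study
#' @param gamma_grid Nonnegative effect magnitudes.
#' @param direction `"low"` or `"high"` quality deviations.
#' @return A tibble with columns `gamma_star` (magnitude),
#'   `coverage_naive`, `coverage_adjusted`, `se_naive`, `se_adjusted`,
#'   `reps`.
#' @export
run_coverage_table <- function(cfg, gamma_grid = seq(0, 3, by = 0.25),
                               reps = 500, seed = 1,
                               direction = c("low", "high"), level = 0.95,
                               prior_cov = NULL, plug_true = FALSE,
                               c = 2.5) {
  direction <- match.arg(direction)
  sgn <- if (direction == "low") -1 else 1
  purrr::map_dfr(seq_along(gamma_grid), function(k) {
    g <- gamma_grid[k]
    cfg_k <- cfg
    cfg_k$special$gamma1 <- sgn * g
    res <- run_inference_study(cfg_k, reps = reps, seed = seed + k - 1,
                               level = level, prior_cov = prior_cov,
                               plug_true = plug_true, c = c)
    tibble::tibble(
      gamma_star = g,
      coverage_naive = res$coverage[res$method == "naive_bayes"],
      coverage_adjusted = res$coverage[res$method == "adjusted_bayes"],
      se_naive = res$mc_se_coverage[res$method == "naive_bayes"],
      se_adjusted = res$mc_se_coverage[res$method == "adjusted_bayes"],
      reps = reps
    )
  })
}
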