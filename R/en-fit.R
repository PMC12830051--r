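#' Robust initial values for the empirical-null fit
#'
#' Produces starting values for the truncated-normal likelihood
#' maximization. The covariate effects come from an outlier-robust (Huber
#' M-estimation, tuning 1.345) linear regression of the naive Z-scores on
#' the design rows \eqn{\sqrt{\tilde n_i/a(\psi)}\,W_i} through the origin,
#' i.e. on the first-order approximation to the null mean. The
#' overdispersion start is a method-of-moments estimate from the residuals
#' \eqn{r_i}: the median of \eqn{\max\{0, (r_i^2 - 1)a(\psi)/\tilde n_i\}},
#' which is calibrated to the null variance \eqn{1 + \varphi\tilde n_i} and
#' robust through the median. The null-proportion start is 0.95.
#'
#' Covariate columns that are identically zero are assigned a zero
#' coefficient and dropped from the design; a genuinely rank-deficient
#' design among the remaining columns is an error naming the collinear
#' columns.
#'
#' @param data A `provider_tbl`.
#' @param z Numeric vector of naive Z-scores (defaults to [compute_z()]).
#' @return A list with elements `nu0`, `sigma2_0`, `pi0_0`.
#' @export
en_init <- function(data, z = NULL) {
  assert_provider_tbl(data)
  if (is.null(z)) z <- compute_z(data)$z
  fam <- pt_family(data)
  W <- pt_W(data)
  P <- ncol(W)
  if (nrow(data) < P + 2) {
    abort("Need at least P + 2 providers to initialize the fit.")
  }
  nu0 <- setNames(numeric(P), colnames(W))
  active <- active_columns(W)
  X <- sqrt(data$effective_size / fam$a_psi) * W[, active, drop = FALSE]
  if (length(active)) {
    check_rank(X)
    rf <- MASS::rlm(X, z, psi = MASS::psi.huber, k = 1.345, maxit = 100)
    nu0[active] <- coef(rf)
  }
  res <- z - as.numeric(W %*% nu0) * sqrt(data$effective_size / fam$a_psi)
  sigma2_0 <- median(pmax(0, (res^2 - 1) * fam$a_psi / data$effective_size))
  list(nu0 = nu0, sigma2_0 = sigma2_0, pi0_0 = 0.95)
}

active_columns <- function(W) {
  which(apply(W, 2, function(col) any(col != 0)))
}

check_rank <- function(X) {
  if (!ncol(X)) return(invisible())
  qd <- qr(X)
  if (qd$rank < ncol(X)) {
    dropped <- colnames(X)[qd$pivot[seq(qd$rank + 1, ncol(X))]]
    abort(sprintf(
      "Covariate design is rank deficient; collinear column(s): %s.",
      paste(dropped, collapse = ", ")
    ))
  }
  invisible()
}

#' Per-provider null intervals on the Z scale
#'
#' Builds the central region \eqn{[A_i, B_i]} assumed to contain every null
#' provider's Z-score: \eqn{A_i = m_i - c\,s_i}, \eqn{B_i = m_i + c\,s_i},
#' where \eqn{(m_i, s_i^2)} are the conditional null moments evaluated at
#' pilot parameter values. Providers outside their interval contribute to
#' the likelihood only through the exceedance probability. `c = Inf`
#' disables truncation (every provider is treated as null).
#'
#' @inheritParams null_moments
#' @param c Positive half-width in null standard deviations; default 2.5.
#' @return A tibble with columns `id`, `A`, `B` and attribute `c`.
#' @export
null_intervals <- function(data, nu, sigma2_alpha, c = 2.5) {
  if (!is.numeric(c) || length(c) != 1L || is.na(c) || c <= 0) {
    abort("`c` must be a single positive number (possibly Inf).")
  }
  mo <- null_moments(data, nu, sigma2_alpha)
  s <- sqrt(mo$var)
  out <- tibble::tibble(id = mo$id, A = mo$mean - c * s, B = mo$mean + c * s)
  attr(out, "c") <- c
  out
}

#' Truncated-normal empirical-null negative log-likelihood
#'
#' Evaluates \eqn{-\log L(\nu, \sigma^2_\alpha, \pi_0)} where
#' \deqn{L = \prod_{i \in S_0} \pi_0\,\phi_i(z_i)\;
#'       \prod_{i \notin S_0} \{1 - \pi_0 Q_i\},}
#' \eqn{S_0 = \{i : z_i \in [A_i, B_i]\}}, \eqn{\phi_i} is the normal
#' density with the family-specific conditional null moments, and
#' \eqn{Q_i = \int_{A_i}^{B_i} \phi_i} from the normal CDF. The outside
#' term \eqn{\log(1 - \pi_0 Q_i)} is clamped below at `log(1e-300)`.
#'
#' @inheritParams null_moments
#' @param z Naive Z-scores.
#' @param pi0 Null proportion in (0, 1].
#' @param intervals A tibble from [null_intervals()] (row order must match
#'   `data`).
#' @return A single number.
#' @export
en_negloglik <- function(data, z, nu, sigma2_alpha, pi0, intervals) {
  if (!is.numeric(pi0) || length(pi0) != 1L || pi0 <= 0 || pi0 > 1) {
    abort("`pi0` must lie in (0, 1].")
  }
  mo <- null_moments(data, nu, sigma2_alpha)
  s <- sqrt(mo$var)
  inside <- z >= intervals$A & z <= intervals$B
  ll_in <- sum(log(pi0) + dnorm(z[inside], mo$mean[inside], s[inside],
                                log = TRUE))
  ll_out <- 0
  if (any(!inside)) {
    i <- which(!inside)
    Q <- pnorm(intervals$B[i], mo$mean[i], s[i]) -
      pnorm(intervals$A[i], mo$mean[i], s[i])
    ll_out <- sum(pmax(log1p(-pi0 * Q), log(1e-300)))
  }
  -(ll_in + ll_out)
}

# parameter transforms: sigma2 = exp(s) - EPS_S2 >= 0, pi0 in (1e-4, 1]
EPS_S2 <- 1e-8
PI0_LO <- 1e-4
par_pack <- function(nu_active, sigma2, pi0) {
  c(nu_active, log(sigma2 + EPS_S2),
    qlogis(min(max((pi0 - PI0_LO) / (1 - PI0_LO), 1e-6), 1 - 1e-6)))
}
par_sigma2 <- function(s) max(exp(s) - EPS_S2, 0)
par_pi0 <- function(t) PI0_LO + (1 - PI0_LO) * plogis(t)

en_optimize <- function(data, z, intervals, nu_start, sigma2_start,
                        pi0_start, active, fix_pi0 = FALSE,
                        sigma2_fixed = NULL, control = list()) {
  P <- length(nu_start)
  nact <- length(active)
  est_s2 <- is.null(sigma2_fixed)
  nu_full <- nu_start

  # hot path: strip the tabular layer once, then evaluate the likelihood
  # on plain vectors inside the optimizer
  fam <- pt_family(data)
  W_act <- pt_W(data)[, active, drop = FALSE]
  nt <- data$effective_size
  sum_b3 <- if ("sum_b3" %in% names(data)) data$sum_b3 else NULL
  A <- intervals$A
  B <- intervals$B
  inside <- z >= A & z <= B
  out_idx <- which(!inside)

  unpack <- function(par) {
    nu <- nu_full
    nu[active] <- par[seq_len(nact)]
    k <- nact
    s2 <- if (est_s2) par_sigma2(unname(par[k + 1])) else sigma2_fixed
    if (est_s2) k <- k + 1
    p0 <- if (fix_pi0) 1 else par_pi0(unname(par[k + 1]))
    list(nu = nu, sigma2 = s2, pi0 = p0)
  }
  obj <- function(par) {
    th <- unpack(par)
    eta <- if (nact) as.numeric(W_act %*% th$nu[active]) else
      numeric(length(z))
    mo <- switch(fam$family,
      poisson = moments_poisson(eta, nt, th$sigma2, fam$a_psi),
      normal = moments_normal(eta, nt, th$sigma2, fam$a_psi),
      general = {
        m <- list(mean = sqrt(nt / fam$a_psi) * eta,
                  var = 1 + (sum_b3 / nt) * eta +
                    (th$sigma2 / fam$a_psi) * nt)
        m$var <- pmax(m$var, 1e-6)
        m
      }
    )
    s <- sqrt(mo$var)
    val <- -sum(log(th$pi0) +
                  dnorm(z[inside], mo$mean[inside], s[inside], log = TRUE))
    if (length(out_idx)) {
      Q <- pnorm(B[out_idx], mo$mean[out_idx], s[out_idx]) -
        pnorm(A[out_idx], mo$mean[out_idx], s[out_idx])
      val <- val - sum(pmax(log1p(-th$pi0 * Q), log(1e-300)))
    }
    # guard against overflow in extreme corners of the search box
    if (!is.finite(val)) val <- 1e10
    val
  }

  par0 <- nu_start[active]
  lower <- rep(-50, nact); upper <- rep(50, nact)
  if (est_s2) {
    par0 <- c(par0, log(sigma2_start + EPS_S2))
    lower <- c(lower, log(EPS_S2)); upper <- c(upper, 8)
  }
  if (!fix_pi0) {
    par0 <- c(par0, qlogis(min(max((pi0_start - PI0_LO) / (1 - PI0_LO),
                                   1e-6), 1 - 1e-6)))
    lower <- c(lower, -15); upper <- c(upper, 15)
  }
  ctrl <- modifyList(list(maxit = 500, factr = 1e4), control)

  if (!length(par0)) {
    th <- unpack(numeric(0))
    return(list(theta = th, value = obj(numeric(0)), converged = TRUE,
                n_iter = 0L))
  }
  res <- tryCatch(
    optim(par0, obj, method = "L-BFGS-B", lower = lower, upper = upper,
          control = ctrl),
    error = function(e) e
  )
  if (inherits(res, "error")) {
    th <- unpack(par0)
    return(list(theta = th, value = obj(par0), converged = FALSE,
                n_iter = 0L, message = conditionMessage(res)))
  }
  list(theta = unpack(res$par), value = res$value,
       converged = res$convergence == 0,
       n_iter = as.integer(res$counts[["function"]]),
       message = res$message)
}

#' Fit the robust privacy-preserving cluster-level confounding model
#'
#' Estimates the observed cluster-level confounding effects \eqn{\nu}, the
#' unobserved-confounding variance \eqn{\sigma^2_\alpha}, and the null
#' proportion \eqn{\pi_0} from naive provider Z-scores by maximizing the
#' truncated-normal empirical-null likelihood (see [en_negloglik()]) with a
#' bounded quasi-Newton search started at [en_init()]. Internally
#' \eqn{\log(\sigma^2_\alpha + \epsilon)} and a logit of \eqn{\pi_0} are
#' optimized so the bounds \eqn{\sigma^2_\alpha \ge 0},
#' \eqn{\pi_0 \in (10^{-4}, 1]} hold; results are reported on the natural
#' scale.
#'
#' The null intervals are fixed from the initial fit, and by default one
#' refinement pass recomputes them at the first optimum and refits
#' (`refine = FALSE` disables this). The sandwich covariance of
#' \eqn{\hat\nu} over the null set is attached (see [sandwich_cov()]).
#' Non-convergence is reported through `converged = FALSE`, not an error.
#'
#' @inheritParams en_init
#' @param c Null-interval half-width in standard deviations (default 2.5);
#'   `Inf` disables truncation, in which case the fit coincides with
#'   [fit_normal_mle()].
#' @param refine Recompute intervals at the first optimum and refit once?
#' @param sigma2_alpha Fix \eqn{\sigma^2_\alpha} at this value instead of
#'   estimating it (`NULL`, the default, estimates it).
#' @param control Passed to [stats::optim()] (`maxit`, `factr`, ...).
#' @return An object of class `rppclc_fit`; see [tidy.rppclc_fit()] and
#'   [glance.rppclc_fit()] for tidy access.
#' @examples
#' sim <- gen_estimation_data(sim_config(I = 60, seed = 1))
#' fit <- fit_rppclc(sim$providers)
#' glance(fit)
#' @export
fit_rppclc <- function(data, c = 2.5, refine = TRUE, sigma2_alpha = NULL,
                       control = list()) {
  assert_provider_tbl(data)
  z <- compute_z(data)$z
  init <- en_init(data, z)
  W <- pt_W(data)
  P <- ncol(W)
  active <- active_columns(W)

  nu <- init$nu0
  s2 <- if (is.null(sigma2_alpha)) init$sigma2_0 else sigma2_alpha
  pi0 <- init$pi0_0
  n_iter <- 0L
  converged <- TRUE
  opt <- NULL
  n_pass <- if (refine && is.finite(c)) 2L else 1L
  for (pass in seq_len(n_pass)) {
    intervals <- null_intervals(data, nu, s2, c = c)
    n0 <- sum(z >= intervals$A & z <= intervals$B)
    if (n0 < max(length(active), 1L)) {
      abort(sprintf(
        "Null set has %d provider(s), fewer than the %d needed; the null intervals exclude nearly all scores. Inspect the inputs or widen `c`.",
        n0, max(length(active), 1L)
      ))
    }
    opt <- en_optimize(data, z, intervals, nu, s2, pi0, active,
                       fix_pi0 = FALSE, sigma2_fixed = sigma2_alpha,
                       control = control)
    nu <- opt$theta$nu
    s2 <- opt$theta$sigma2
    pi0 <- opt$theta$pi0
    n_iter <- n_iter + opt$n_iter
    converged <- converged && opt$converged
  }
  new_rppclc_fit(data, z, nu, s2, pi0, intervals, opt$value, converged,
                 n_iter, method = "rppclc", c = c,
                 diagnostics = opt$message)
}

#' Fit the non-robust normal maximum-likelihood baseline
#'
#' Maximizes the product of conditional-null normal densities over *all*
#' providers — no truncation, \eqn{\pi_0} fixed at 1. This is the estimator
#' the robust fit is compared against: with normal outcomes and
#' \eqn{\sigma^2_\alpha} fixed at zero it reduces to ordinary least
#' squares, and more generally it is an iteratively reweighted
#' least-squares fit with weights \eqn{1/(1 + \varphi n_i)}. It is biased
#' when outlying providers are present.
#'
#' @inheritParams fit_rppclc
#' @return An object of class `rppclc_fit` with `method = "normal_mle"`.
#' @export
fit_normal_mle <- function(data, sigma2_alpha = NULL, control = list()) {
  assert_provider_tbl(data)
  z <- compute_z(data)$z
  init <- en_init(data, z)
  W <- pt_W(data)
  active <- active_columns(W)
  intervals <- tibble::tibble(id = data$id, A = -Inf, B = Inf)
  attr(intervals, "c") <- Inf
  s2_start <- if (is.null(sigma2_alpha)) init$sigma2_0 else sigma2_alpha
  opt <- en_optimize(data, z, intervals, init$nu0, s2_start, 1, active,
                     fix_pi0 = TRUE, sigma2_fixed = sigma2_alpha,
                     control = control)
  new_rppclc_fit(data, z, opt$theta$nu, opt$theta$sigma2, 1, intervals,
                 opt$value, opt$converged, opt$n_iter,
                 method = "normal_mle", c = Inf,
                 diagnostics = opt$message)
}

#' Sandwich covariance of the confounding-effect estimator
#'
#' Approximates \eqn{\Sigma_{\hat\nu}} by the heteroskedasticity-consistent
#' sandwich over the null providers,
#' \deqn{(W^{*\top} W^*)^{-1} W^{*\top} \Omega W^* (W^{*\top} W^*)^{-1},}
#' where \eqn{W^*} has rows \eqn{\sqrt{\tilde n_i/a(\psi)}\,W_i} for
#' \eqn{i \in S_0} and \eqn{\Omega} is diagonal with the fitted conditional
#' null variances. Covariate columns that are identically zero contribute
#' zero rows/columns.
#'
#' @inheritParams null_moments
#' @param null_ids Character ids of the providers in the null set.
#' @return A symmetric positive semi-definite P-by-P matrix.
#' @export
sandwich_cov <- function(data, nu, sigma2_alpha, null_ids) {
  assert_provider_tbl(data)
  fam <- pt_family(data)
  W <- pt_W(data)
  P <- ncol(W)
  Sigma <- matrix(0, P, P, dimnames = list(colnames(W), colnames(W)))
  active <- active_columns(W)
  if (!length(active)) return(Sigma)
  keep <- data$id %in% null_ids
  if (sum(keep) < length(active)) {
    abort("Null set smaller than the number of covariates; covariance of the confounding effects is not identified.")
  }
  mo <- null_moments(data, nu, sigma2_alpha)
  Xs <- (sqrt(data$effective_size / fam$a_psi) * W)[keep, active,
                                                    drop = FALSE]
  omega <- mo$var[keep]
  XtXi <- solve(crossprod(Xs))
  meat <- crossprod(Xs, Xs * omega)
  S <- XtXi %*% meat %*% XtXi
  Sigma[active, active] <- (S + t(S)) / 2
  Sigma
}

new_rppclc_fit <- function(data, z, nu, sigma2_alpha, pi0, intervals,
                           negll, converged, n_iter, method, c,
                           diagnostics = NULL) {
  inside <- z >= intervals$A & z <= intervals$B
  cov_nu <- sandwich_cov(data, nu, sigma2_alpha, data$id[inside])
  structure(
    list(
      nu = nu,
      sigma2_alpha = sigma2_alpha,
      pi0 = pi0,
      null_set = data$id[inside],
      intervals = intervals,
      cov_nu = cov_nu,
      loglik = -negll,
      converged = converged,
      n_iter = n_iter,
      method = method,
      c = c,
      z = tibble::tibble(id = data$id, z = z, in_null_set = inside),
      data = data,
      diagnostics = diagnostics
    ),
    class = "rppclc_fit"
  )
}

#' @export
print.rppclc_fit <- function(x, ...) {
  lab <- if (x$method == "rppclc") "robust empirical-null" else "normal MLE"
  cat(sprintf("<rppclc_fit: %s, %d providers, |S0| = %d>\n", lab,
              nrow(x$data), length(x$null_set)))
  se <- sqrt(diag(x$cov_nu))
  if (length(x$nu)) {
    cat("Confounding effects (nu):\n")
    print(tibble::tibble(term = names(x$nu),
                         estimate = round(unname(x$nu), 4),
                         std.error = round(unname(se), 4)))
  }
  cat(sprintf("sigma2_alpha = %.4g, pi0 = %.3f, loglik = %.2f%s\n",
              x$sigma2_alpha, x$pi0, x$loglik,
              if (x$converged) "" else "  [did not converge]"))
  invisible(x)
}

#' Tidy the confounding-effect estimates
#'
#' @param x An `rppclc_fit`.
#' @param conf.level Wald confidence level (default 0.95).
#' @param ... Unused.
#' @return A tibble with one row per covariate effect: `term`, `estimate`,
#'   `std.error`, `conf.low`, `conf.high`.
#' @export
tidy.rppclc_fit <- function(x, conf.level = 0.95, ...) {
  se <- sqrt(diag(x$cov_nu))
  q <- qnorm(1 - (1 - conf.level) / 2)
  tibble::tibble(
    term = names(x$nu),
    estimate = unname(x$nu),
    std.error = unname(se),
    conf.low = unname(x$nu - q * se),
    conf.high = unname(x$nu + q * se)
  )
}

#' One-row fit summary
#'
#' @param x An `rppclc_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `sigma2_alpha`, `pi0`, `n_null`, `nobs`,
#'   `logLik`, `converged`, `n_iter`, `method`.
#' @export
glance.rppclc_fit <- function(x, ...) {
  tibble::tibble(
    sigma2_alpha = x$sigma2_alpha,
    pi0 = x$pi0,
    n_null = length(x$null_set),
    nobs = nrow(x$data),
    logLik = x$loglik,
    converged = x$converged,
    n_iter = x$n_iter,
    method = x$method
  )
}
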