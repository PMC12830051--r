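#' Naive fixed-effects Z-scores
#'
#' Computes the naive standardized score statistic for each provider,
#' \deqn{Z_i = (O_i - E_i) / \sqrt{a(\psi)\,\tilde n_i},}
#' which compares the observed outcome count to its indirectly standardized
#' expectation. For Poisson outcomes with unit dispersion this is the
#' familiar \eqn{(O - E)/\sqrt{E}}. "Naive" means adjusted only for
#' patient-level case mix: the score ignores cluster-level confounding, and
#' its null distribution is *not* standard normal when such confounding is
#' present — that is precisely what the rest of the package models.
#'
#' @param data A `provider_tbl` (see [provider_table()]).
#' @return `data` with a numeric `z` column appended.
#' @examples
#' pt <- provider_table(data.frame(id = "a", observed = 12, expected = 9))
#' compute_z(pt)$z  # (12 - 9)/3 = 1
#' @export
compute_z <- function(data) {
  assert_provider_tbl(data)
  fam <- pt_family(data)
  data$z <- (data$observed - data$expected) /
    sqrt(fam$a_psi * data$effective_size)
  data
}

#' Conditional null moments of the naive Z-scores
#'
#' Evaluates the mean and variance of the naive Z-score for a provider whose
#' quality-of-care effect is null, as a function of the observed
#' cluster-level confounding effects `nu` and the unobserved-confounding
#' variance `sigma2_alpha`.
#'
#' For Poisson outcomes (canonical log link) the moments are exact:
#' \deqn{E[Z_i] = \sqrt{\tilde n_i}\,(e^{W_i^\top\nu + \sigma^2_\alpha/2} - 1),}
#' \deqn{Var[Z_i] = e^{m_i}\{1 + e^{m_i}(e^{\sigma^2_\alpha} - 1)\tilde n_i\},
#'   \quad m_i = W_i^\top\nu + \sigma^2_\alpha/2.}
#' Under a quasi-Poisson dispersion \eqn{a(\psi) > 1} the score in
#' [compute_z()] is already divided by \eqn{\sqrt{a(\psi)}}, so the mean is
#' scaled by \eqn{1/\sqrt{a(\psi)}} and \eqn{\tilde n_i} is replaced by
#' \eqn{\tilde n_i / a(\psi)} in the variance, which reduces to the exact
#' Poisson expressions at \eqn{a(\psi) = 1}.
#'
#' For normal outcomes the Z-scores follow a heteroskedastic linear model
#' exactly: \eqn{E[Z_i] = \sqrt{n_i/\sigma^2_\epsilon}\,W_i^\top\nu} and
#' \eqn{Var[Z_i] = 1 + \varphi n_i} with
#' \eqn{\varphi = \sigma^2_\alpha/\sigma^2_\epsilon}.
#'
#' For a general exponential family only first-order approximations are
#' available:
#' \eqn{E[Z_i] \approx \sqrt{\tilde n_i/a(\psi)}\,W_i^\top\nu} and
#' \eqn{Var[Z_i] \approx 1 + (\sum_j b'''(\theta^0_{ij})/\tilde n_i)
#' W_i^\top\nu + \varphi\tilde n_i}. The approximate variance can go
#' nonpositive for extreme covariates; it is floored at 1e-6 with a warning
#' (the exact Poisson/normal paths never need the floor).
#'
#' @inheritParams compute_z
#' @param nu Numeric vector of covariate effects, one per covariate column
#'   (in the column order of the table).
#' @param sigma2_alpha Nonnegative unobserved-confounding variance
#'   \eqn{\sigma^2_\alpha}.
#' @return A tibble with columns `id`, `mean`, `var`.
#' @examples
#' pt <- provider_table(data.frame(id = "a", observed = 110, expected = 100,
#'                                 w = 0.1), center = FALSE)
#' null_moments(pt, nu = 1, sigma2_alpha = 0)
#' @export
null_moments <- function(data, nu, sigma2_alpha) {
  assert_provider_tbl(data)
  fam <- pt_family(data)
  W <- pt_W(data)
  if (length(nu) != ncol(W)) {
    abort(sprintf("`nu` must have length %d (one per covariate).", ncol(W)))
  }
  if (!is.numeric(sigma2_alpha) || length(sigma2_alpha) != 1L ||
      !is.finite(sigma2_alpha) || sigma2_alpha < 0) {
    abort("`sigma2_alpha` must be a single nonnegative number.")
  }
  eta <- as.numeric(W %*% nu)
  nt <- data$effective_size
  mo <- switch(fam$family,
    poisson = moments_poisson(eta, nt, sigma2_alpha, fam$a_psi),
    normal = moments_normal(eta, nt, sigma2_alpha, fam$a_psi),
    general = moments_general(eta, nt, sigma2_alpha, fam$a_psi, data$sum_b3)
  )
  tibble::tibble(id = data$id, mean = mo$mean, var = mo$var)
}

moments_poisson <- function(eta, nt, s2, a_psi) {
  m <- exp(eta + s2 / 2)
  nt_a <- nt / a_psi
  list(
    mean = sqrt(nt_a) * (m - 1),
    var = m * (1 + m * (exp(s2) - 1) * nt_a)
  )
}

moments_normal <- function(eta, nt, s2, a_psi) {
  list(
    mean = sqrt(nt / a_psi) * eta,
    var = 1 + (s2 / a_psi) * nt
  )
}

moments_general <- function(eta, nt, s2, a_psi, sum_b3) {
  if (is.null(sum_b3)) {
    abort("Family \"general\" requires the `sum_b3` column.")
  }
  v <- 1 + (sum_b3 / nt) * eta + (s2 / a_psi) * nt
  if (any(v < 1e-6)) {
    warn(paste(
      "First-order null variance was nonpositive for some providers;",
      "flooring at 1e-6. The linear approximation is unreliable there."
    ))
    v <- pmax(v, 1e-6)
  }
  list(mean = sqrt(nt / a_psi) * eta, var = v)
}
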