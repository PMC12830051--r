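#' Outcome family for provider summary models
#'
#' Describes the patient-level outcome distribution that generated the
#' provider summaries. The family determines which null-moment formulas are
#' used for the naive Z-scores: exact expressions for `"poisson"` (canonical
#' log link) and `"normal"` (identity link), and first-order approximations
#' for `"general"` exponential-family outcomes.
#'
#' @param family One of `"poisson"`, `"normal"`, `"general"`.
#' @param a_psi Positive dispersion \eqn{a(\psi)}: the residual variance
#'   \eqn{\sigma^2_\epsilon} for normal outcomes, 1 for Poisson counts.
#'   Values other than 1 with `family = "poisson"` declare a quasi-Poisson
#'   model and are flagged as such. The dispersion is supplied, never
#'   estimated: the patient-level model is assumed to be fitted externally.
#'
#' @return An object of class `rppclc_family`: a list with elements
#'   `family`, `a_psi` and `quasi`.
#' @examples
#' rppclc_family("poisson")
#' rppclc_family("normal", a_psi = 2)
#' @export
rppclc_family <- function(family = c("poisson", "normal", "general"),
                          a_psi = 1) {
  family <- match.arg(family)
  if (!is.numeric(a_psi) || length(a_psi) != 1L || !is.finite(a_psi) ||
      a_psi <= 0) {
    abort("`a_psi` must be a single positive number.")
  }
  structure(
    list(
      family = family,
      a_psi = as.numeric(a_psi),
      quasi = family == "poisson" && abs(a_psi - 1) > 1e-12
    ),
    class = "rppclc_family"
  )
}

#' @export
print.rppclc_family <- function(x, ...) {
  lab <- if (x$quasi) "quasi-poisson" else x$family
  cat(sprintf("<rppclc_family: %s, a(psi) = %g>\n", lab, x$a_psi))
  invisible(x)
}

is_rppclc_family <- function(x) inherits(x, "rppclc_family")

as_rppclc_family <- function(x) {
  if (is_rppclc_family(x)) return(x)
  if (is.character(x) && length(x) == 1L) return(rppclc_family(x))
  abort("`family` must be an `rppclc_family` object or a family name.")
}
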