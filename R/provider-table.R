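#' Build a validated provider summary table
#'
#' Assembles the per-cluster public summary statistics used throughout the
#' package into a validated tibble: observed outcome count \eqn{O_i},
#' expected count under national norms \eqn{E_i}, effective size
#' \eqn{\tilde n_i = \sum_j b''(\theta^0_{ij})}, and cluster-level
#' covariates \eqn{W_i}. No patient-level data are involved.
#'
#' Covariates are mean-centered by default because all null-moment formulas
#' assume \eqn{E[W_i] = 0}; the subtracted offsets are recorded in the
#' `"offsets"` attribute so that fitted effects can be reported on the
#' original scale. For Poisson outcomes \eqn{\tilde n_i = E_i} (both equal
#' \eqn{\sum_j \exp\theta^0_{ij}}): a missing `effective_size` is filled
#' with `expected`, and a supplied one must agree with `expected` to
#' relative tolerance 1e-8.
#'
#' @param data A data frame with one row per provider.
#' @param id,observed,expected,effective_size,sum_b3 Column names (strings).
#'   `effective_size` and `sum_b3` may be absent from `data`; `sum_b3`
#'   (\eqn{\sum_j b'''(\theta^0_{ij})}) is only needed for
#'   `family = "general"`.
#' @param covariates Character vector of covariate column names. Default
#'   (`NULL`): all remaining numeric columns.
#' @param family An [rppclc_family()] or family name.
#' @param center Center covariate columns at their means? Default `TRUE`.
#'
#' @return A `provider_tbl`: a tibble with columns `id`, `observed`,
#'   `expected`, `effective_size`, optionally `sum_b3`, and the covariate
#'   columns; attributes `family`, `covariates`, `offsets`.
#' @examples
#' df <- data.frame(id = c("a", "b"), observed = c(12, 20),
#'                  expected = c(9, 25), donor_rate = c(0.3, -0.1))
#' provider_table(df)
#' @export
provider_table <- function(data,
                           id = "id",
                           observed = "observed",
                           expected = "expected",
                           effective_size = "effective_size",
                           sum_b3 = "sum_b3",
                           covariates = NULL,
                           family = rppclc_family("poisson"),
                           center = TRUE) {
  family <- as_rppclc_family(family)
  data <- tibble::as_tibble(data)

  for (col in c(id, observed, expected)) {
    if (!col %in% names(data)) {
      abort(sprintf("Required column `%s` is missing from the input table.",
                    col))
    }
  }

  out <- tibble::tibble(
    id = as.character(data[[id]]),
    observed = as.numeric(data[[observed]]),
    expected = as.numeric(data[[expected]])
  )

  if (effective_size %in% names(data)) {
    out$effective_size <- as.numeric(data[[effective_size]])
  } else if (family$family %in% c("poisson")) {
    out$effective_size <- out$expected
  } else {
    abort(sprintf(
      "Column `%s` is required for family \"%s\".",
      effective_size, family$family
    ))
  }
  has_b3 <- sum_b3 %in% names(data)
  if (has_b3) out$sum_b3 <- as.numeric(data[[sum_b3]])
  if (family$family == "general" && !has_b3) {
    abort(sprintf("Column `%s` is required for family \"general\".", sum_b3))
  }

  if (is.null(covariates)) {
    used <- c(id, observed, expected, effective_size, sum_b3)
    covariates <- names(data)[vapply(data, is.numeric, logical(1))]
    covariates <- setdiff(covariates, used)
  } else {
    missing_w <- setdiff(covariates, names(data))
    if (length(missing_w)) {
      abort(sprintf("Covariate column(s) not found: %s.",
                    paste(missing_w, collapse = ", ")))
    }
  }

  # expected must be positive for count outcomes; for normal (identity
  # link) outcomes the sum of linear predictors can be any real number
  bad <- if (family$family == "normal") {
    which(!is.finite(out$expected))
  } else {
    which(!is.finite(out$expected) | out$expected <= 0)
  }
  if (length(bad)) {
    abort(sprintf(
      "`expected` must be %sfinite; offending row(s): %s.",
      if (family$family == "normal") "" else "positive and ",
      paste(head(bad, 5), collapse = ", ")
    ))
  }
  bad <- which(!is.finite(out$effective_size) | out$effective_size <= 0)
  if (length(bad)) {
    abort(sprintf(
      "`effective_size` must be positive and finite; offending row(s): %s.",
      paste(head(bad, 5), collapse = ", ")
    ))
  }
  bad <- which(!is.finite(out$observed) | out$observed < 0)
  if (length(bad) && family$family == "poisson") {
    abort(sprintf(
      "`observed` must be a nonnegative count; offending row(s): %s.",
      paste(head(bad, 5), collapse = ", ")
    ))
  }
  if (family$family == "poisson") {
    rel <- abs(out$effective_size - out$expected) /
      pmax(out$expected, .Machine$double.eps)
    if (any(rel > 1e-8)) {
      abort(paste(
        "For Poisson outcomes the effective size must equal the expected",
        "count (both are the sum of exp(theta0)); they disagree beyond",
        "relative tolerance 1e-8."
      ))
    }
    out$effective_size <- out$expected
  }

  offsets <- setNames(numeric(length(covariates)), covariates)
  for (w in covariates) {
    wv <- as.numeric(data[[w]])
    if (anyNA(wv) || any(!is.finite(wv))) {
      abort(sprintf(
        "Covariate `%s` contains missing or non-finite values; row(s): %s.",
        w, paste(head(which(is.na(wv) | !is.finite(wv)), 5), collapse = ", ")
      ))
    }
    if (center) {
      offsets[[w]] <- mean(wv)
      wv <- wv - offsets[[w]]
    }
    out[[w]] <- wv
  }

  if (anyDuplicated(out$id)) abort("Provider `id` values must be unique.")

  structure(
    out,
    family = family,
    covariates = covariates,
    offsets = offsets,
    class = c("provider_tbl", class(out))
  )
}

#' Read a provider summary table from CSV
#'
#' Thin wrapper around [readr::read_csv()] + [provider_table()]: reads a
#' comma-separated, UTF-8 table with a header row and validates it. Column
#' naming is configurable because published summary tables vary; defaults
#' are `id`, `observed`, `expected`, `effective_size`, with every remaining
#' numeric column treated as a cluster-level covariate.
#'
#' @inheritParams provider_table
#' @param path Path to a CSV file.
#' @param ... Passed on to [provider_table()].
#' @return A `provider_tbl`.
#' @export
read_provider_table <- function(path, ...) {
  data <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  provider_table(data, ...)
}

#' Write a results table to CSV
#'
#' Writes a provider evaluation table (see [evaluate_providers()]) with full
#' numeric precision so that the file round-trips: reading it back
#' reproduces the written values to 1e-12.
#'
#' @param rows A nonempty data frame of results.
#' @param path Output file path.
#' @return `rows`, invisibly.
#' @export
write_results <- function(rows, path) {
  if (!is.data.frame(rows) || nrow(rows) == 0L) {
    abort("`rows` must be a nonempty data frame.")
  }
  readr::write_csv(tibble::as_tibble(rows), path)
  invisible(rows)
}

pt_family <- function(x) attr(x, "family", exact = TRUE)
pt_covariates <- function(x) attr(x, "covariates", exact = TRUE)
pt_offsets <- function(x) attr(x, "offsets", exact = TRUE)

# covariate matrix (I x P); P = 0 gives a zero-column matrix
pt_W <- function(x) {
  covs <- pt_covariates(x)
  if (!length(covs)) {
    return(matrix(numeric(0), nrow = nrow(x), ncol = 0))
  }
  as.matrix(x[, covs, drop = FALSE])
}

assert_provider_tbl <- function(x) {
  if (!inherits(x, "provider_tbl") || is.null(pt_family(x))) {
    abort("Expected a `provider_tbl` built by `provider_table()`.")
  }
  invisible(x)
}
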