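# small deterministic provider tables used across tests

# table whose naive z-scores are exactly sqrt(E) * w * nu_star (no noise)
exact_score_table <- function(nu_star = 0.4, E = c(40, 60, 80, 100, 150),
                              w = c(-1, -0.5, 0, 0.5, 1)) {
  z <- sqrt(E) * w * nu_star
  tibble::tibble(
    id = sprintf("c%d", seq_along(E)),
    observed = E + sqrt(E) * z,
    expected = E,
    w = w
  ) |>
    provider_table(covariates = "w", center = FALSE)
}

# one-provider poisson table with a fixed covariate value
one_provider <- function(O, E, w = 0) {
  provider_table(
    tibble::tibble(id = "p1", observed = O, expected = E, w = w),
    covariates = "w", center = FALSE
  )
}
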