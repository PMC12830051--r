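#' Funnel-style diagnostic plot of a confounding fit
#'
#' Naive Z-scores against effective size with the fitted null intervals;
#' providers outside their interval (the presumed outliers) are
#' highlighted. With a confounder present the intervals vary across
#' providers, so they are drawn per provider as segments.
#'
#' @param object An `rppclc_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rppclc_fit <- function(object, ...) {
  df <- dplyr::left_join(object$z, object$intervals, by = "id")
  df$effective_size <- object$data$effective_size
  ggplot2::ggplot(df, ggplot2::aes(x = .data$effective_size)) +
    ggplot2::geom_linerange(
      ggplot2::aes(ymin = .data$A, ymax = .data$B),
      colour = "grey70", alpha = 0.6
    ) +
    ggplot2::geom_point(
      ggplot2::aes(y = .data$z, colour = .data$in_null_set), size = 1.4
    ) +
    ggplot2::scale_colour_manual(
      values = c(`TRUE` = "#2c7fb8", `FALSE` = "#d95f02"),
      labels = c(`TRUE` = "null set", `FALSE` = "outside"),
      name = NULL
    ) +
    ggplot2::labs(
      x = "effective size",
      y = "naive Z-score",
      title = "Empirical-null fit",
      subtitle = sprintf(
        "sigma2_alpha = %.3g, pi0 = %.2f, |S0| = %d of %d",
        object$sigma2_alpha, object$pi0, length(object$null_set),
        nrow(object$data))
    ) +
    ggplot2::theme_minimal()
}

#' Caterpillar plot of provider evaluations
#'
#' Posterior medians and credible intervals of the corrected measure ratio
#' for every provider, ordered by median, coloured by flag. The horizontal
#' line at 1 is the national norm.
#'
#' @param object An `rppclc_results` table from [evaluate_providers()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rppclc_results <- function(object, ...) {
  df <- dplyr::arrange(tibble::as_tibble(object), .data$post_median)
  df$rank <- seq_len(nrow(df))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank)) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2, colour = "grey40") +
    ggplot2::geom_linerange(
      ggplot2::aes(ymin = .data$ci_lo, ymax = .data$ci_hi,
                   colour = .data$flag_bayes), alpha = 0.7
    ) +
    ggplot2::geom_point(
      ggplot2::aes(y = .data$post_median, colour = .data$flag_bayes),
      size = 0.9
    ) +
    ggplot2::scale_colour_manual(
      values = c(low = "#d95f02", null = "grey55", high = "#1b9e77"),
      drop = FALSE, name = "flag"
    ) +
    ggplot2::labs(
      x = "providers (ordered by posterior median)",
      y = "corrected measure ratio",
      title = "Provider evaluations with confounding adjustment"
    ) +
    ggplot2::theme_minimal()
}
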