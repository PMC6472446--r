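#' Plot posterior and prior probabilities of the number of events
#'
#' Bar chart of the posterior distribution of the number of divergence
#' events; when a prior is supplied the prior bars are drawn alongside
#' and each `k` is annotated with its Bayes factor against all other
#' values.
#'
#' @param object A `codiv_summary`.
#' @param prior Optional tibble with columns `k`, `prob` (e.g. from
#'   [dp_prior_k_probs()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.codiv_summary <- function(object, prior = NULL, ...) {
  df <- dplyr::mutate(object$p_k, distribution = "posterior")
  if (!is.null(prior)) {
    bf <- bayes_factors_k(object$p_k, prior)
    df <- dplyr::bind_rows(
      df, dplyr::mutate(prior, distribution = "prior")
    )
    lab <- tibble(
      k = bf$k,
      y = pmax(bf$posterior, bf$prior) + 0.03,
      text = sprintf("BF = %.3g", bf$bf)
    )
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$k),
                                        y = .data$prob,
                                        fill = .data$distribution)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::scale_fill_manual(
      values = c(posterior = "grey25", prior = "grey70")) +
    ggplot2::labs(x = "number of divergence events",
                  y = "probability", fill = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(prior)) {
    p <- p + ggplot2::geom_text(
      data = lab, inherit.aes = FALSE, size = 3,
      ggplot2::aes(x = factor(.data$k), y = .data$y, label = .data$text))
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Marginal posterior densities of divergence times
#'
#' Overlaid density estimates of the post-burn-in divergence-time samples
#' for every pair.
#'
#' @param trace A `codiv_chain`.
#' @param burn_in Samples to discard per chain.
#' @return A ggplot object.
#' @export
plot_divergence_times <- function(trace, burn_in = 0) {
  df <- as_tibble(trace)
  if (!".chain" %in% names(df)) df$.chain <- 1L
  df <- dplyr::group_by(df, .data$.chain)
  df <- dplyr::filter(df, dplyr::row_number() > burn_in)
  df <- dplyr::ungroup(df)
  cols <- grep("^t_", names(df), value = TRUE)
  long <- tidyr::pivot_longer(df[, cols], dplyr::all_of(cols),
                              names_to = "pair", values_to = "t")
  long$pair <- sub("^t_", "", long$pair)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t, fill = .data$pair)) +
    ggplot2::geom_density(alpha = 0.5, colour = NA) +
    ggplot2::labs(x = "divergence time (expected substitutions per site)",
                  y = "posterior density", fill = "pair") +
    ggplot2::theme_minimal()
}

#' Calibration plot for posterior model probabilities
#'
#' @param bins Output of [calibration_bins()].
#' @return A ggplot object.
#' @export
plot_calibration <- function(bins) {
  ggplot2::ggplot(bins, ggplot2::aes(x = .data$mean_posterior,
                                     y = .data$empirical_freq)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(size = .data$count)) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "mean posterior probability of one event",
                  y = "empirical frequency of one event",
                  size = "data sets") +
    ggplot2::theme_minimal()
}
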