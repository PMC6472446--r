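#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a posterior summary
#'
#' Returns the per-pair divergence-time summaries (posterior mean, median
#' and equal-tailed credible interval), one row per pair.
#'
#' @param x A `codiv_summary`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.codiv_summary <- function(x, ...) {
  x$t_summary
}

#' One-row summary of a fitted divergence-model posterior
#'
#' @param x A `codiv_summary`.
#' @param ... Unused.
#' @return A tibble with the MAP model and its probability, the MAP
#'   number of events, the credible-set size, and sampling metadata.
#' @export
glance.codiv_summary <- function(x, ...) {
  tibble(
    map_model = x$map_model,
    map_model_prob = x$map_model_prob,
    map_k = x$map_k,
    p_map_k = x$p_k$prob[x$map_k],
    k_credible_set = paste(x$k_credible_set, collapse = ","),
    n_samples = x$n_samples,
    n_chains = x$n_chains
  )
}

#' Tidy an MCMC trace
#'
#' Long format: one row per retained sample and continuous parameter.
#'
#' @param x A `codiv_chain`.
#' @param ... Unused.
#' @return A tibble with columns `.chain`, `generation`, `parameter`,
#'   `value`.
#' @export
tidy.codiv_chain <- function(x, ...) {
  df <- as_tibble(x)
  if (!".chain" %in% names(df)) df$.chain <- 1L
  cols <- c("lnl", "lnp", "alpha",
            grep("^(t_|N_|R_root_|pi_)", names(df), value = TRUE))
  tidyr::pivot_longer(df[, c(".chain", "generation", cols)],
                      dplyr::all_of(cols),
                      names_to = "parameter", values_to = "value")
}
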