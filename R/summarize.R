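#' Summarize posterior samples of divergence models
#'
#' Pools the post-burn-in samples of one or more chains and reports the
#' posterior distribution of the number of divergence events, the
#' maximum a posteriori divergence model, 95% credible sets of models and
#' of `k`, per-pair divergence-time summaries (posterior mean and
#' equal-tailed 95% interval), and, when at least two chains are present,
#' the potential scale reduction factor and effective sample size of the
#' continuous parameters.
#'
#' @param trace A `codiv_chain` (single- or multi-chain) or a list of
#'   them.
#' @param burn_in Samples to discard from the start of each chain.
#' @param level Credible level (default 0.95).
#' @return A `codiv_summary` list.
#' @export
summarize_trace <- function(trace, burn_in = 0, level = 0.95) {
  if (is.list(trace) && !inherits(trace, "codiv_chain")) {
    trace <- lapply(seq_along(trace), function(j) {
      tr <- trace[[j]]
      if (!".chain" %in% names(tr)) tr$.chain <- j
      tr
    })
    labels <- attr(trace[[1]], "labels")
    trace <- structure(dplyr::bind_rows(trace),
                       class = c("codiv_chain", "tbl_df", "tbl",
                                 "data.frame"),
                       labels = labels)
  }
  if (!".chain" %in% names(trace)) trace$.chain <- 1L
  labels <- attr(trace, "labels")
  if (is.null(labels)) {
    labels <- sub("^t_", "", grep("^t_", names(trace), value = TRUE))
  }
  chains <- split(as.data.frame(trace), trace$.chain)
  chain_len <- vapply(chains, nrow, 0L)
  if (any(burn_in >= chain_len)) stop("burn_in >= chain length")
  post <- dplyr::bind_rows(lapply(chains, function(x) {
    x[(burn_in + 1):nrow(x), , drop = FALSE]
  }))
  n <- nrow(post)
  np <- length(labels)

  p_k <- tibble(k = seq_len(np),
                prob = tabulate(post$k, nbins = np) / n)
  p_model <- dplyr::count(post, .data$partition, name = "count")
  p_model$prob <- p_model$count / n
  p_model <- dplyr::arrange(p_model, dplyr::desc(.data$prob),
                            .data$partition)
  map_tie <- sum(p_model$prob == max(p_model$prob)) > 1

  cs <- function(values, probs) {
    ord <- order(probs, decreasing = TRUE)
    take <- ord[seq_len(which(cumsum(probs[ord]) >= level)[1])]
    values[take]
  }
  k_credible <- sort(cs(p_k$k, p_k$prob))
  model_credible <- cs(p_model$partition, p_model$prob)

  lo <- (1 - level) / 2
  t_summary <- dplyr::bind_rows(lapply(labels, function(lb) {
    x <- post[[paste0("t_", lb)]]
    tibble(pair = lb, mean = mean(x), median = median(x),
           lower = quantile(x, lo, names = FALSE),
           upper = quantile(x, 1 - lo, names = FALSE))
  }))

  diag <- NULL
  scalar_cols <- c("lnl", grep("^(t_|N_|R_root_|pi_)", names(post),
                               value = TRUE))
  scalar_cols <- scalar_cols[vapply(scalar_cols, function(cl) {
    var(post[[cl]]) > 0
  }, TRUE)]
  per_chain <- split(post, post$.chain)
  diag <- dplyr::bind_rows(lapply(scalar_cols, function(cl) {
    xs <- lapply(per_chain, `[[`, cl)
    ok_psrf <- length(xs) >= 2 && length(unique(lengths(xs))) == 1 &&
      all(lengths(xs) >= 10)
    tibble(parameter = cl,
           psrf = if (ok_psrf) psrf(xs) else NA_real_,
           ess = if (n >= 10) ess(unlist(xs)) else NA_real_)
  }))

  structure(list(
    p_k = p_k, p_model = p_model,
    map_model = p_model$partition[1], map_model_prob = p_model$prob[1],
    map_tie = map_tie,
    map_k = p_k$k[which.max(p_k$prob)],
    k_credible_set = k_credible, model_credible_set = model_credible,
    t_summary = t_summary, diagnostics = diag,
    n_samples = n, n_chains = length(per_chain), burn_in = burn_in,
    level = level, labels = labels
  ), class = "codiv_summary")
}

#' @export
print.codiv_summary <- function(x, ...) {
  cat("<codiv_summary> ", x$n_samples, " samples (", x$n_chains,
      " chain(s), burn-in ", x$burn_in, " each)\n", sep = "")
  cat("posterior number of divergence events:\n")
  print(as.data.frame(x$p_k), row.names = FALSE)
  cat("MAP model:", x$map_model,
      sprintf("(p = %.3f)%s", x$map_model_prob,
              if (x$map_tie) " [tie]" else ""), "\n")
  cat(sprintf("%d%% credible set of k: {%s}\n", round(100 * x$level),
              paste(x$k_credible_set, collapse = ", ")))
  cat("divergence times:\n")
  print(as.data.frame(x$t_summary), row.names = FALSE)
  invisible(x)
}

#' Bayes factors for each number of divergence events
#'
#' Compares each `k` against all other values: the ratio of posterior to
#' prior odds. A posterior (or prior) lumping all mass on one `k` yields
#' an infinite (or undefined) Bayes factor, reported as `Inf`.
#'
#' @param posterior Tibble with columns `k`, `prob` (e.g. `p_k` from
#'   [summarize_trace()]).
#' @param prior Tibble with columns `k`, `prob` (e.g. from
#'   [dp_prior_k_probs()]).
#' @return A tibble with columns `k`, `posterior`, `prior`, `bf`.
#' @export
bayes_factors_k <- function(posterior, prior) {
  if (!setequal(posterior$k, prior$k)) {
    stop("posterior and prior must cover the same numbers of events")
  }
  tb <- dplyr::inner_join(
    dplyr::rename(posterior, posterior = "prob"),
    dplyr::rename(prior, prior = "prob"), by = "k"
  )
  if (any(tb$prior <= 0)) stop("prior probabilities must be positive")
  post_odds <- tb$posterior / (1 - tb$posterior)
  prior_odds <- tb$prior / (1 - tb$prior)
  tb$bf <- post_odds / prior_odds
  tb
}

#' Potential scale reduction factor
#'
#' The square root of the ratio of the pooled variance estimate (weighted
#' within- and between-chain variance) to the mean within-chain variance,
#' computed across two or more equal-length chains of one scalar
#' parameter. Values near 1 indicate the chains are sampling the same
#' distribution.
#'
#' @param chains List (or matrix columns) of equal-length numeric
#'   vectors, one per chain.
#' @return The PSRF statistic.
#' @export
psrf <- function(chains) {
  if (is.matrix(chains)) chains <- asplit(chains, 2)
  m <- length(chains)
  if (m < 2) stop("psrf requires at least two chains")
  len <- lengths(chains)
  if (length(unique(len)) != 1) stop("chains must have equal lengths")
  n <- len[1]
  if (n < 10) stop("chains too short")
  means <- vapply(chains, mean, 0.0)
  W <- mean(vapply(chains, var, 0.0))
  B_over_n <- var(means)
  if (W == 0) return(if (B_over_n == 0) 1.0 else Inf)
  sqrt(((n - 1) / n * W + B_over_n) / W)
}

#' Effective sample size of an autocorrelated sequence
#'
#' `n / (1 + 2 * sum(rho))`, truncating the autocorrelation sum with
#' Geyer's initial positive sequence rule.
#'
#' @param x Numeric vector of at least 10 samples.
#' @return Estimated effective sample size (0 for a constant sequence).
#' @export
ess <- function(x) {
  n <- length(x)
  if (n < 10) stop("need at least 10 samples")
  if (var(x) == 0) return(0)
  rho <- acf(x, lag.max = min(n - 1, 2000), plot = FALSE)$acf[-1]
  # sum pairs rho[2t]+rho[2t+1] while positive
  npair <- floor(length(rho) / 2)
  s <- 0
  for (t in seq_len(npair)) {
    pair <- rho[2 * t - 1] + rho[2 * t]
    if (pair < 0) break
    s <- s + pair
  }
  max(1, min(n, n / (1 + 2 * s)))
}

#' Calibration of posterior probabilities across simulated data sets
#'
#' Bins data sets by their estimated posterior probability of a single,
#' shared divergence event and compares each bin's mean posterior
#' probability with the empirical frequency at which one event is truly
#' the generating model.
#'
#' @param p_one Per-data-set posterior probabilities that `k = 1`.
#' @param truth Per-data-set logical (or 0/1) indicator that `k = 1` is
#'   true.
#' @param bin_width Width of the probability bins (default 0.2).
#' @return A tibble with columns `bin`, `mean_posterior`,
#'   `empirical_freq`, `count` (empty bins omitted).
#' @export
calibration_bins <- function(p_one, truth, bin_width = 0.2) {
  stopifnot(length(p_one) == length(truth), bin_width > 0, bin_width <= 1)
  breaks <- seq(0, 1, by = bin_width)
  if (breaks[length(breaks)] < 1) breaks <- c(breaks, 1)
  bin <- cut(p_one, breaks, include.lowest = TRUE)
  tb <- tibble(bin = bin, p = p_one, truth = as.logical(truth))
  out <- dplyr::summarise(
    dplyr::group_by(tb, .data$bin),
    mean_posterior = mean(.data$p),
    empirical_freq = mean(.data$truth),
    count = dplyr::n(), .groups = "drop"
  )
  out[order(out$bin), ]
}

credible_interval_covers <- function(x, true_value, level = 0.95) {
  lo <- (1 - level) / 2
  q <- quantile(x, c(lo, 1 - lo), names = FALSE)
  true_value >= q[1] & true_value <= q[2]
}

#' Write a posterior summary as YAML plus tab-separated tables
#'
#' @param summary A `codiv_summary`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_summary <- function(summary, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(list(
    n_samples = summary$n_samples, n_chains = summary$n_chains,
    burn_in = summary$burn_in,
    map_model = summary$map_model,
    map_model_prob = summary$map_model_prob,
    map_k = summary$map_k,
    k_credible_set = summary$k_credible_set,
    model_credible_set = summary$model_credible_set
  ), file.path(dir, "summary.yml"))
  write.table(summary$p_k, file.path(dir, "number_of_events.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(summary$p_model, file.path(dir, "models.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(summary$t_summary, file.path(dir, "divergence_times.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(summary$diagnostics)) {
    write.table(summary$diagnostics, file.path(dir, "diagnostics.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
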