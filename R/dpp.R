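#' Partition combinatorics for divergence models
#'
#' With `N` population pairs and `k` divergence events, the number of ways
#' of assigning pairs to events is the Stirling number of the second kind
#' `S2(N, k)`; summing over `k` gives the total number of divergence
#' models, the Bell number.
#'
#' @param n Number of population pairs.
#' @param k Number of divergence events (`1 <= k <= n`).
#' @return A count (numeric; exact for the sizes used here).
#' @examples
#' stirling2(3, 2) # 3
#' bell_number(3)  # 5 divergence models for three pairs
#' @export
stirling2 <- function(n, k) {
  stopifnot(n >= 1, k >= 1, k <= n)
  s <- matrix(0, n + 1, k + 1)
  s[1, 1] <- 1
  for (i in seq_len(n)) {
    for (j in seq_len(min(i, k))) {
      s[i + 1, j + 1] <- j * s[i, j + 1] + s[i, j]
    }
  }
  s[n + 1, k + 1]
}

#' @rdname stirling2
#' @export
bell_number <- function(n) {
  stopifnot(n >= 1)
  sum(vapply(seq_len(n), function(k) stirling2(n, k), 0.0))
}

#' Enumerate all set partitions of n items
#'
#' Partitions are returned in canonical restricted-growth form: item 1 is
#' always in block 0, and each new block label is one more than the
#' largest label used so far.
#'
#' @param n Number of items.
#' @return A list of integer vectors (0-based block labels).
#' @export
enumerate_partitions <- function(n) {
  stopifnot(n >= 1)
  out <- list(0L)
  for (i in seq_len(n - 1)) {
    out <- unlist(lapply(out, function(p) {
      lapply(0:(max(p) + 1L), function(b) c(p, b))
    }), recursive = FALSE)
  }
  out
}

canonical_partition <- function(z) {
  match(z, unique(z)) - 1L
}

partition_string <- function(z) {
  paste(canonical_partition(z), collapse = ",")
}

#' Chinese-restaurant-process probability of a partition
#'
#' The Dirichlet-process prior on the assignment of pairs to divergence
#' events induces the Chinese restaurant process on unordered partitions:
#' two pairs share an event with prior probability `1 / (1 + alpha)`.
#'
#' @param partition Integer vector assigning each pair to an event (any
#'   labelling).
#' @param alpha Concentration parameter (> 0).
#' @return Log prior probability of the (unordered) partition.
#' @examples
#' exp(crp_partition_log_prob(c(0, 0), alpha = 1)) # 1 / (1 + 1)
#' @export
crp_partition_log_prob <- function(partition, alpha) {
  stopifnot(length(partition) >= 1, alpha > 0)
  n <- length(partition)
  counts <- table(partition)
  k <- length(counts)
  k * log(alpha) + sum(lgamma(as.numeric(counts))) -
    sum(log(alpha + 0:(n - 1)))
}

#' Prior expectation of the number of divergence events
#'
#' @param n Number of population pairs.
#' @param alpha Concentration parameter.
#' @return `sum(alpha / (alpha + i - 1))` over `i = 1..n`.
#' @examples
#' expected_num_events(3, 1.414216) # ~2 events a priori
#' @export
expected_num_events <- function(n, alpha) {
  stopifnot(n >= 1, alpha > 0)
  sum(alpha / (alpha + seq_len(n) - 1))
}

#' Monte Carlo prior probabilities of the number of events
#'
#' Simulates partitions from the Chinese restaurant process (marginalizing
#' the concentration parameter over its gamma hyperprior when one is
#' given) and tabulates the number of divergence events.
#'
#' @param n Number of population pairs.
#' @param alpha Fixed concentration parameter (or `NULL` to use the
#'   hyperprior).
#' @param alpha_shape,alpha_mean Gamma hyperprior for `alpha` when free.
#' @param n_sims Number of simulated partitions.
#' @param seed Optional RNG seed.
#' @return A tibble with columns `k` and `prob` (summing to one) and a
#'   `mean_k` attribute.
#' @examples
#' dp_prior_k_probs(4, alpha = 0.44, n_sims = 1e4, seed = 1)
#' @export
dp_prior_k_probs <- function(n, alpha = NULL, alpha_shape = 2,
                             alpha_mean = 2, n_sims = 1e5, seed = NULL) {
  stopifnot(n >= 1, n_sims >= 1)
  if (!is.null(seed)) set.seed(seed)
  a <- if (is.null(alpha)) {
    rgamma(n_sims, shape = alpha_shape, scale = alpha_mean / alpha_shape)
  } else {
    rep(alpha, n_sims)
  }
  # sequential CRP: pair i starts a new event w.p. alpha / (alpha + i - 1)
  k <- rep(1L, n_sims)
  if (n > 1) {
    for (i in 2:n) {
      k <- k + (runif(n_sims) < a / (a + i - 1))
    }
  }
  tab <- tabulate(k, nbins = n)
  out <- tibble(k = seq_len(n), prob = tab / n_sims)
  attr(out, "mean_k") <- mean(k)
  out
}

#' Log prior density of a full parameter state
#'
#' Sums the Chinese-restaurant-process partition probability, the gamma
#' log-densities of the event times, descendant sizes and relative root
#' sizes, and (when free) the beta log-density of the state frequencies
#' and the gamma log-density of the concentration parameter. States
#' outside the support return `-Inf`.
#'
#' @param state List with elements `partition` (integer vector),
#'   `tau` (one time per event), `N_d1`, `N_d2`, `R_root` (per pair),
#'   and optionally `pi` (per pair) and `alpha`.
#' @param config A [prior_config()].
#' @return Log prior density.
#' @export
log_prior_density <- function(state, config) {
  alpha <- state$alpha %||% config$alpha
  k <- length(state$tau)
  if (k != length(unique(state$partition))) {
    stop("tau must hold one time per event in the partition")
  }
  if (any(state$tau <= 0) || alpha <= 0) return(-Inf)
  lp <- crp_partition_log_prob(state$partition, alpha)
  lp <- lp + sum(dgamma(state$tau, shape = config$tau_shape,
                        scale = config$tau_mean / config$tau_shape,
                        log = TRUE))
  if (is.null(config$size_fixed)) {
    lp <- lp + sum(dgamma(c(state$N_d1, state$N_d2),
                          shape = config$size_shape,
                          scale = config$size_mean / config$size_shape,
                          log = TRUE))
  }
  if (is.null(config$root_rel_fixed)) {
    lp <- lp + sum(dgamma(state$R_root, shape = config$root_rel_shape,
                          scale = config$root_rel_mean / config$root_rel_shape,
                          log = TRUE))
  }
  if (length(config$pi) == 2 && !is.null(state$pi)) {
    lp <- lp + sum(dbeta(state$pi, config$pi[1], config$pi[2], log = TRUE))
  }
  if (is.null(config$alpha)) {
    lp <- lp + dgamma(alpha, shape = config$alpha_shape,
                      scale = config$alpha_mean / config$alpha_shape,
                      log = TRUE)
  }
  lp
}
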