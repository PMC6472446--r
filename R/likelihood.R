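#' Two-state mutation model
#'
#' Characters mutate between a "red" and a "green" state along gene-tree
#' branches. `pi` is the stationary frequency of the green state; the
#' relative rates are normalized so the stationary substitution flux
#' equals the overall rate `mu` (`u = mu / (2 (1 - pi))` for red to green
#' and `v = mu / (2 pi)` for green to red, so `pi = 0.5` reduces to the
#' symmetric two-state model with `u = v = mu`).
#'
#' @param pi Stationary frequency of the green state, in (0, 1).
#' @param mu Overall mutation rate; with `mu = 1` times are measured in
#'   expected substitutions per site.
#' @return A `codiv_mutation_model`.
#' @examples
#' mutation_model(pi = 0.5)
#' @export
mutation_model <- function(pi = 0.5, mu = 1) {
  stopifnot(pi > 0, pi < 1, mu > 0)
  structure(list(pi = pi, mu = mu,
                 u = mu / (2 * (1 - pi)), v = mu / (2 * pi)),
            class = "codiv_mutation_model")
}

#' @export
print.codiv_mutation_model <- function(x, ...) {
  cat(sprintf("<codiv_mutation_model> pi = %g, mu = %g (u = %g, v = %g)\n",
              x$pi, x$mu, x$u, x$v))
  invisible(x)
}

#' Species-tree parameters for one population pair
#'
#' The species tree of a pair comprises the divergence time `t` and three
#' effective-size parameters (each the product of effective population
#' size and mutation rate): the root and the two descendants. The root
#' size can be given directly (`N_root`) or relative to the mean of the
#' descendant sizes (`R_root`).
#'
#' @param t Divergence time in expected substitutions per site.
#' @param N_d1,N_d2 Descendant-population size parameters.
#' @param N_root Root size parameter (or give `R_root`).
#' @param R_root Root size relative to `(N_d1 + N_d2) / 2`.
#' @return A `codiv_demography`.
#' @examples
#' pair_demography(t = 0.01, N_d1 = 0.002, N_d2 = 0.002, R_root = 1)
#' @export
pair_demography <- function(t, N_d1, N_d2, N_root = NULL, R_root = NULL) {
  if (is.null(N_root) && is.null(R_root)) {
    stop("give one of N_root or R_root")
  }
  mean_d <- (N_d1 + N_d2) / 2
  if (is.null(N_root)) N_root <- R_root * mean_d
  if (is.null(R_root)) R_root <- N_root / mean_d
  stopifnot(t >= 0, N_root > 0, N_d1 > 0, N_d2 > 0)
  structure(list(t = t, N_root = N_root, N_d1 = N_d1, N_d2 = N_d2,
                 R_root = R_root),
            class = "codiv_demography")
}

#' @export
print.codiv_demography <- function(x, ...) {
  cat(sprintf(
    "<codiv_demography> t = %g, N_root = %g (R = %g), N_d = (%g, %g)\n",
    x$t, x$N_root, x$R_root, x$N_d1, x$N_d2))
  invisible(x)
}

state_tibble <- function(values, n_max) {
  n <- rep.int(0:n_max, 0:n_max + 1)
  n <- n[-1]  # single empty state
  r <- sequence(1:n_max + 1) - 1
  tibble(n = c(0L, n), r = c(0L, r), value = as.numeric(values))
}

#' Partial-likelihood table at the bottom of a branch
#'
#' Encodes an observed unordered sample of `n` gene copies, `r` of them
#' red, as a partial-likelihood table over lineage-count/red-count states.
#'
#' @param n,r Observed copies and red copies.
#' @param n_max State-space bound (defaults to `n`).
#' @return A tibble with columns `n`, `r`, `value` over all states up to
#'   `n_max` (plus the empty state).
#' @export
leaf_partials <- function(n, r, n_max = n) {
  stopifnot(n >= 0, r >= 0, r <= n, n_max >= n)
  d <- 1 + n_max * (n_max + 3) / 2
  v <- numeric(d)
  v[state_index_r(n, r)] <- 1
  state_tibble(v, n_max)
}

state_index_r <- function(n, r) {
  i <- 1L + (n - 1L) * (n + 2L) / 2L + r + 1L
  i[n == 0] <- 1L
  as.integer(i)
}

#' Propagate a partial-likelihood table along a branch
#'
#' Applies the exponential of the combined coalescent (rate `1 / (2 N)`
#' per lineage pair) and mutation generator to a partial-likelihood table
#' for a branch of the given duration.
#'
#' @param partials Table from [leaf_partials()] (or a previous
#'   propagation).
#' @param N Effective-size parameter of the branch.
#' @param model A [mutation_model()].
#' @param duration Branch length in expected substitutions per site.
#' @return The propagated table.
#' @export
branch_propagate <- function(partials, N, model, duration) {
  stopifnot(duration >= 0, N > 0)
  n_max <- max(partials$n)
  A <- build_generator_cpp(n_max, 1 / (2 * N), model$u, model$v)
  v <- as.numeric(expm_action(A * duration, partials$value))
  state_tibble(v, n_max)
}

expm_action <- function(A, x) {
  # expmat is exported at the C++ level through pattern probability
  # computations; here a dense exponential suffices (small state spaces)
  E <- expm_cpp(A)
  E %*% x
}

#' Exact probability matrix of all allele-count patterns
#'
#' One evaluation covers every pattern with sample sizes up to
#' `(n1_max, n2_max)`; entry `[i, j]` is the probability of the pattern
#' whose per-population states are in rows/columns named `"n:r"`.
#'
#' @param n1_max,n2_max Maximum sampled copies per population.
#' @param demography A [pair_demography()].
#' @param model A [mutation_model()].
#' @return A named matrix of pattern probabilities.
#' @export
pattern_prob_matrix <- function(n1_max, n2_max, demography, model) {
  M <- pattern_prob_matrix_cpp(n1_max, n2_max, demography$t,
                               demography$N_root, demography$N_d1,
                               demography$N_d2, model$u, model$v)
  lab <- function(n_max) {
    c("0:0", unlist(lapply(1:n_max, function(n) paste0(n, ":", 0:n))))
  }
  dimnames(M) <- list(lab(n1_max), lab(n2_max))
  M
}

#' Exact probability of allele-count patterns
#'
#' @param patterns Pattern tibble (columns `n1 r1 n2 r2`, optional
#'   `weight`).
#' @param demography A [pair_demography()].
#' @param model A [mutation_model()].
#' @return The pattern tibble with a `prob` column appended.
#' @examples
#' d <- pair_demography(t = 0.01, N_d1 = 0.002, N_d2 = 0.002, R_root = 1)
#' pattern_probability(allele_patterns(1, 1, 1, 0), d, mutation_model())
#' @export
pattern_probability <- function(patterns, demography, model) {
  if (any(patterns$n1 + patterns$n2 < 1)) {
    stop("pattern with no sampled copies")
  }
  M <- pattern_prob_matrix_cpp(max(patterns$n1), max(patterns$n2),
                               demography$t, demography$N_root,
                               demography$N_d1, demography$N_d2,
                               model$u, model$v)
  patterns$prob <- M[cbind(state_index_r(patterns$n1, patterns$r1),
                           state_index_r(patterns$n2, patterns$r2))]
  patterns
}

#' Probability of a constant character
#'
#' @inheritParams pattern_probability
#' @param n1,n2 Sampled copies per population.
#' @return A tibble with columns `n1`, `n2`, `p_all_red`, `p_all_green`.
#' @export
constant_probability <- function(n1, n2, demography, model) {
  stopifnot(all(n1 + n2 >= 1))
  M <- pattern_prob_matrix_cpp(max(n1), max(n2), demography$t,
                               demography$N_root, demography$N_d1,
                               demography$N_d2, model$u, model$v)
  tibble(
    n1 = n1, n2 = n2,
    p_all_red = M[cbind(state_index_r(n1, n1), state_index_r(n2, n2))],
    p_all_green = M[cbind(state_index_r(n1, 0L), state_index_r(n2, 0L))]
  )
}

#' Log-likelihood of one population pair
#'
#' Sums `weight * log p` over the pair's patterns. When constant
#' characters were excluded from the data, the probabilities are
#' conditioned on the character being variable: `"per_site"` divides each
#' pattern's probability by the probability of a variable character at
#' that pattern's own sample sizes, while `"max_copies"` divides the
#' product by the variable-character probability at the maximum sample
#' sizes (the SNAPP-style correction). The two are identical when every
#' site has complete sampling.
#'
#' @param data A `codiv_comparison`.
#' @param demography A [pair_demography()].
#' @param model A [mutation_model()].
#' @param correction `"none"`, `"per_site"`, or `"max_copies"`.
#' @return Log-likelihood (scalar).
#' @export
pair_log_likelihood <- function(data, demography, model,
                                correction = c("none", "per_site",
                                               "max_copies")) {
  correction <- match.arg(correction)
  if (correction != "none" && !data$constant_removed) {
    if (any(is_constant_pattern(data$patterns))) {
      stop("constant patterns present; correction requires variable-only data")
    }
  }
  code <- match(correction, c("none", "per_site", "max_copies")) - 1L
  pair_loglik_cpp(as.matrix(data$patterns[, c("n1", "r1", "n2", "r2",
                                              "weight")]),
                  demography$t, demography$N_root, demography$N_d1,
                  demography$N_d2, model$u, model$v, code)
}

#' Log-likelihood of a collection of pairs
#'
#' The pairs are unconnected, so the joint log-likelihood is the sum of
#' the per-pair log-likelihoods.
#'
#' @param collection A `codiv_collection`.
#' @param demographies List of [pair_demography()], one per pair.
#' @param models A single [mutation_model()] or a list, one per pair.
#' @inheritParams pair_log_likelihood
#' @return Log-likelihood (scalar).
#' @export
collection_log_likelihood <- function(collection, demographies, models,
                                      correction = "none") {
  if (length(demographies) != length(collection)) {
    stop("need one demography per pair")
  }
  if (inherits(models, "codiv_mutation_model")) {
    models <- rep(list(models), length(collection))
  }
  sum(vapply(seq_along(collection), function(i) {
    pair_log_likelihood(collection[[i]], demographies[[i]], models[[i]],
                        correction)
  }, 0.0))
}
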