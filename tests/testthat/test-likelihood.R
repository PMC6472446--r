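test_that("pattern probabilities are normalized over all patterns", {
  set.seed(42)
  for (rep in 1:4) {
    t <- runif(1, 0, 0.05)
    d <- pair_demography(t = t, N_d1 = runif(1, 5e-4, 5e-3),
                         N_d2 = runif(1, 5e-4, 5e-3),
                         N_root = runif(1, 5e-4, 5e-3))
    m <- mutation_model(pi = runif(1, 0.2, 0.8))
    M <- pattern_prob_matrix(5, 5, d, m)
    for (n1 in 0:5) {
      for (n2 in 0:5) {
        if (n1 + n2 == 0) next
        s <- sum(M[state_idx(n1, 0:n1), state_idx(n2, 0:n2)])
        expect_equal(s, 1, tolerance = 1e-8)
      }
    }
  }
})

test_that("leaf partials put mass only on the observed configuration", {
  lp <- leaf_partials(2, 1)
  expect_equal(lp$value[lp$n == 2 & lp$r == 1], 1)
  expect_equal(sum(lp$value), 1)
  lp1 <- leaf_partials(1, 1)
  expect_equal(lp1$value, c(0, 0, 1))
  expect_error(leaf_partials(2, 3), "r")
})

test_that("branch propagation matches identity and closed forms", {
  m <- mutation_model()
  lp <- leaf_partials(3, 1)
  expect_equal(branch_propagate(lp, 0.002, m, 0)$value, lp$value)
  # single lineage: two-state CTMC transition closed form
  lp1 <- leaf_partials(1, 1)
  dur <- 0.37
  out <- branch_propagate(lp1, 0.002, m, dur)
  # symmetric rates u = v = 1: P(stay) = (1 + exp(-2 dur)) / 2
  expect_equal(out$value[out$n == 1 & out$r == 1],
               (1 + exp(-2 * dur)) / 2, tolerance = 1e-9)
  expect_equal(out$value[out$n == 1 & out$r == 0],
               (1 - exp(-2 * dur)) / 2, tolerance = 1e-9)
})

test_that("branch propagation agrees with explicit ODE integration", {
  skip_if_not_installed("deSolve")
  m <- mutation_model(pi = 0.3)
  N <- 0.0015
  A <- codiv:::build_generator_cpp(4, 1 / (2 * N), m$u, m$v)
  lp <- leaf_partials(4, 2)
  dur <- 0.02
  sol <- deSolve::ode(
    y = lp$value, times = c(0, dur),
    func = function(t, y, parms) list(as.numeric(A %*% y)),
    method = "lsoda", rtol = 1e-10, atol = 1e-12
  )
  out <- branch_propagate(lp, N, m, dur)
  expect_equal(out$value, unname(sol[2, -1]), tolerance = 1e-6)
})

test_that("two-copy pattern probability matches a gene-tree Monte Carlo oracle", {
  d <- demog_default(t = 0.01, N = 0.002)
  m <- mutation_model()
  pats <- allele_patterns(n1 = 1, r1 = c(0, 0, 1, 1), n2 = 1,
                          r2 = c(0, 1, 0, 1))
  pr <- pattern_probability(pats, d, m)
  expect_equal(sum(pr$prob), 1, tolerance = 1e-10)
  set.seed(7)
  n_sim <- 2e6
  mc <- mc_prob_two_copies_differ(0.01, d$N_root, n_sim = n_sim)
  p_diff <- sum(pr$prob[pr$r1 != pr$r2])
  se <- sqrt(mc * (1 - mc) / n_sim)
  expect_lt(abs(p_diff - mc), 3 * se + 1e-5)
})

test_that("color and label symmetries hold", {
  m <- mutation_model(pi = 0.5)
  da <- pair_demography(t = 0.02, N_d1 = 0.001, N_d2 = 0.003,
                        N_root = 0.002)
  db <- pair_demography(t = 0.02, N_d1 = 0.003, N_d2 = 0.001,
                        N_root = 0.002)
  pa <- pattern_probability(allele_patterns(4, 1, 3, 2), da, m)$prob
  # swapping colors (red <-> green) at pi = 0.5
  expect_equal(pa, pattern_probability(allele_patterns(4, 3, 3, 1),
                                       da, m)$prob, tolerance = 1e-12)
  # swapping populations together with their sizes
  expect_equal(pa, pattern_probability(allele_patterns(3, 2, 4, 1),
                                       db, m)$prob, tolerance = 1e-12)
})

test_that("zero divergence reduces to one pooled population", {
  m <- mutation_model(pi = 0.35)
  d0 <- pair_demography(t = 0, N_d1 = 0.001, N_d2 = 0.005,
                        N_root = 0.003)
  dp <- pair_demography(t = 0, N_d1 = 0.003, N_d2 = 0.003,
                        N_root = 0.003)
  for (r1 in 0:3) {
    for (r2 in 0:2) {
      r <- r1 + r2
      pooled <- pattern_probability(allele_patterns(5, r, 0, 0), dp,
                                    m)$prob
      split <- pattern_probability(allele_patterns(3, r1, 2, r2), d0,
                                   m)$prob
      expect_equal(split,
                   pooled * choose(3, r1) * choose(2, r2) / choose(5, r),
                   tolerance = 1e-10)
    }
  }
})

test_that("constant-character probabilities behave as expected", {
  m <- mutation_model()
  d <- demog_default(t = 0.005)
  cp <- constant_probability(10, 10, d, m)
  expect_lt(cp$p_all_red + cp$p_all_green, 1)
  expect_equal(cp$p_all_red, cp$p_all_green, tolerance = 1e-10)
  # more time on the tree, more variation
  ts <- c(0.001, 0.005, 0.02, 0.08)
  pc <- vapply(ts, function(t) {
    cc <- constant_probability(10, 10, demog_default(t = t), m)
    cc$p_all_red + cc$p_all_green
  }, 0.0)
  expect_true(all(diff(pc) < 0))
})

test_that("per-site and max-copies corrections coincide under complete sampling", {
  set.seed(11)
  cfg <- prior_config()
  sim <- simulate_dataset(cfg, n_pairs = 1, n_sites = 3000,
                          drop_constant = TRUE)
  cd <- sim$collection[[1]]
  d <- truth_demographies(sim$truth)[[1]]
  m <- mutation_model()
  l1 <- pair_log_likelihood(cd, d, m, correction = "per_site")
  l2 <- pair_log_likelihood(cd, d, m, correction = "max_copies")
  expect_equal(l1, l2, tolerance = 1e-10)
  # with missing copies they deviate
  set.seed(12)
  cdm <- apply_missingness(cd, 0.8)
  pat <- cdm$patterns
  con <- (pat$r1 == 0 & pat$r2 == 0) | (pat$r1 == pat$n1 & pat$r2 == pat$n2)
  cdm <- comparison_data(pat[!con, ], label = cdm$label,
                         constant_removed = TRUE)
  expect_false(isTRUE(all.equal(
    pair_log_likelihood(cdm, d, m, "per_site"),
    pair_log_likelihood(cdm, d, m, "max_copies"))))
})

test_that("pair log-likelihood is log-linear in pattern weight", {
  d <- demog_default()
  m <- mutation_model()
  w1 <- comparison_data(allele_patterns(4, 1, 4, 2, weight = 1))
  w5 <- comparison_data(allele_patterns(4, 1, 4, 2, weight = 5))
  expect_equal(5 * pair_log_likelihood(w1, d, m),
               pair_log_likelihood(w5, d, m), tolerance = 1e-12)
})

test_that("correction demands variable-only data", {
  d <- demog_default()
  m <- mutation_model()
  with_const <- comparison_data(allele_patterns(c(2, 2), c(0, 1), 2,
                                                c(0, 1)))
  expect_error(pair_log_likelihood(with_const, d, m, "per_site"),
               "constant")
})

test_that("collection log-likelihood sums over independent pairs", {
  set.seed(3)
  cfg <- prior_config()
  sim <- simulate_dataset(cfg, n_pairs = 2, n_sites = 500)
  demos <- truth_demographies(sim$truth)
  m <- mutation_model()
  ll <- collection_log_likelihood(sim$collection, demos, m)
  l1 <- pair_log_likelihood(sim$collection[[1]], demos[[1]], m)
  l2 <- pair_log_likelihood(sim$collection[[2]], demos[[2]], m)
  expect_equal(ll, l1 + l2)
  # permutation invariance
  perm <- comparison_collection(list(sim$collection[[2]],
                                     sim$collection[[1]]))
  expect_equal(collection_log_likelihood(perm, demos[c(2, 1)], m), ll)
  # identical pairs double the log-likelihood
  dup <- sim$collection[[1]]
  dup$label <- "copy"
  both <- comparison_collection(list(sim$collection[[1]], dup))
  expect_equal(collection_log_likelihood(both, demos[c(1, 1)], m), 2 * l1)
  expect_error(collection_log_likelihood(both, demos[1], m), "demography")
})

test_that("empty pattern table gives zero log-likelihood", {
  m <- matrix(integer(0), 0, 5)
  expect_equal(codiv:::pair_loglik_cpp(m, 0.01, 0.002, 0.002, 0.002, 1, 1,
                                       0L), 0)
})
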