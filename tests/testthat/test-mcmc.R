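empty_collection <- function(n_pairs, labels = paste0("p", seq_len(n_pairs))) {
  comparison_collection(lapply(labels, function(lb) {
    comparison_data(allele_patterns(2, 1, 2, 1), label = lb)
  }))
}

test_that("chains are exactly reproducible from the seed", {
  set.seed(1)
  cfg <- prior_config()
  sim <- simulate_dataset(cfg, n_pairs = 2, n_sites = 300)
  a <- run_chain(sim$collection, cfg, n_generations = 50,
                 sample_every = 5, seed = 77)
  b <- run_chain(sim$collection, cfg, n_generations = 50,
                 sample_every = 5, seed = 77)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c <- run_chain(sim$collection, cfg, n_generations = 50,
                 sample_every = 5, seed = 78)
  expect_false(identical(as.data.frame(a), as.data.frame(c)))
})

test_that("sampling every 50th of 75,000 generations keeps 1501 samples", {
  cfg <- prior_config(size_fixed = 0.002, root_rel_fixed = 1)
  tr <- run_chain(empty_collection(2), cfg, n_generations = 75000,
                  sample_every = 50, seed = 3, ignore_data = TRUE)
  expect_equal(nrow(tr), 1501)
  expect_equal(tr$generation[1], 0)
})

test_that("prior-only chains sample every marginal from its prior", {
  # the standard operator validation: with the data ignored, the chain
  # must reproduce the joint prior
  cfg <- prior_config(tau_shape = 1, tau_mean = 0.01, size_shape = 5,
                      size_mean = 0.002, root_rel_shape = 100,
                      root_rel_mean = 1, alpha = 1.414216)
  tr <- run_chain(empty_collection(3), cfg, n_generations = 30000,
                  sample_every = 10, seed = 11, ignore_data = TRUE)
  post <- tr[-(1:500), ]
  # number of events against the exact partition distribution
  exact <- crp_exact_k_probs(3, 1.414216)
  counts <- tabulate(post$k, 3)
  expect_gt(chisq.test(counts, p = exact)$p.value, 0.01)
  # two pairs share an event with probability 1 / (1 + alpha)
  shared <- mean(post$t_p1 == post$t_p2)
  expect_lt(abs(shared - 1 / (1 + 1.414216)), 0.03)
  # continuous marginals: thin to roughly independent draws for KS tests
  thin <- post[seq(1, nrow(post), by = 10), ]
  expect_gt(ks.test(thin$t_p1, pexp, rate = 100)$p.value, 0.01)
  expect_gt(ks.test(thin$N_d1_p2, pgamma, shape = 5,
                    scale = 0.002 / 5)$p.value, 0.01)
  expect_gt(ks.test(thin$R_root_p3, pgamma, shape = 100,
                    scale = 0.01)$p.value, 0.01)
})

test_that("a free concentration parameter samples its hyperprior", {
  cfg <- prior_config(alpha = NULL, alpha_shape = 2, alpha_mean = 2,
                      size_fixed = 0.002, root_rel_fixed = 1)
  tr <- run_chain(empty_collection(3), cfg, n_generations = 20000,
                  sample_every = 10, seed = 13, ignore_data = TRUE)
  thin <- tr[seq(300, nrow(tr), by = 10), ]
  expect_gt(ks.test(thin$alpha, pgamma, shape = 2, scale = 1)$p.value,
            0.01)
  # a nearly degenerate hyperprior pins alpha at its mean
  cfg2 <- prior_config(alpha = NULL, alpha_shape = 1e4, alpha_mean = 2,
                       size_fixed = 0.002, root_rel_fixed = 1)
  tr2 <- run_chain(empty_collection(2), cfg2, n_generations = 2000,
                   sample_every = 10, seed = 14, ignore_data = TRUE)
  expect_lt(abs(mean(tr2$alpha) - 2), 0.1)
})

test_that("fixed parameters never move and one pair keeps a trivial partition", {
  cfg <- prior_config(size_fixed = 0.002, root_rel_fixed = 1)
  set.seed(15)
  sim <- simulate_dataset(cfg, n_pairs = 1, n_sites = 200)
  tr <- run_chain(sim$collection, cfg, n_generations = 200,
                  sample_every = 5, seed = 16)
  expect_true(all(tr$k == 1))
  expect_true(all(tr$partition == "0"))
  expect_true(all(tr$N_d1_pair1 == 0.002))
  expect_true(all(tr$R_root_pair1 == 1))
  expect_true(all(tr$pi_pair1 == 0.5))
  # tau still mixes
  expect_gt(length(unique(tr$t_pair1)), 10)
})

test_that("cached log-likelihood and log-prior match fresh evaluations", {
  set.seed(17)
  cfg <- prior_config()
  sim <- simulate_dataset(cfg, n_pairs = 2, n_sites = 2000)
  tr <- run_chain(sim$collection, cfg, n_generations = 60,
                  sample_every = 20, seed = 18)
  m <- mutation_model()
  for (row in seq_len(nrow(tr))) {
    demos <- lapply(1:2, function(i) {
      pair_demography(t = tr[[paste0("t_pair", i)]][row],
                      N_d1 = tr[[paste0("N_d1_pair", i)]][row],
                      N_d2 = tr[[paste0("N_d2_pair", i)]][row],
                      R_root = tr[[paste0("R_root_pair", i)]][row])
    })
    fresh <- collection_log_likelihood(sim$collection, demos, m)
    expect_equal(tr$lnl[row], fresh, tolerance = 1e-6)
    z <- as.integer(strsplit(tr$partition[row], ",")[[1]])
    st <- list(partition = z,
               tau = unique(c(tr$t_pair1[row], tr$t_pair2[row]))[
                 seq_len(length(unique(z)))],
               N_d1 = c(tr$N_d1_pair1[row], tr$N_d1_pair2[row]),
               N_d2 = c(tr$N_d2_pair1[row], tr$N_d2_pair2[row]),
               R_root = c(tr$R_root_pair1[row], tr$R_root_pair2[row]))
    expect_equal(tr$lnp[row], log_prior_density(st, cfg),
                 tolerance = 1e-8)
  }
})

test_that("identical informative data raise the posterior odds of sharing", {
  cfg <- prior_config(alpha = 1.414216, size_fixed = 0.002,
                      root_rel_fixed = 1)
  d <- demog_default(t = 0.01)
  m <- mutation_model()
  set.seed(19)
  cd <- simulate_pair(d, m, n_sites = 20000, method = "multinomial",
                      label = "a")
  cd2 <- cd
  cd2$label <- "b"
  coll <- comparison_collection(list(cd, cd2))
  tr <- run_chain(coll, cfg, n_generations = 1500, sample_every = 5,
                  seed = 20)
  p_shared_post <- mean(tr$k[-(1:50)] == 1)
  p_shared_prior <- 1 / (1 + 1.414216)
  expect_gt(p_shared_post, p_shared_prior)
})

test_that("constant characters and variable-only configs are cross-checked", {
  cfg_var <- prior_config(use_constant_characters = FALSE)
  set.seed(21)
  sim <- simulate_dataset(cfg_var, n_pairs = 1, n_sites = 500)
  expect_error(run_chain(sim$collection, cfg_var, n_generations = 10,
                         sample_every = 5, seed = 1),
               "constant")
  cfg_all <- prior_config(use_constant_characters = TRUE)
  sim2 <- simulate_dataset(cfg_all, n_pairs = 1, n_sites = 500,
                           drop_constant = TRUE)
  expect_error(run_chain(sim2$collection, cfg_all, n_generations = 10,
                         sample_every = 5, seed = 1),
               "variable-only")
})

test_that("variable-only analysis with the per-site correction runs", {
  cfg <- prior_config(use_constant_characters = FALSE,
                      correction = "per_site")
  set.seed(22)
  sim <- simulate_dataset(cfg, n_pairs = 2, n_sites = 5000,
                          drop_constant = TRUE)
  tr <- run_chain(sim$collection, cfg, n_generations = 100,
                  sample_every = 5, seed = 23)
  expect_true(all(is.finite(tr$lnl)))
})

test_that("traces round-trip through the tab-separated log format", {
  cfg <- prior_config()
  tr <- run_chain(empty_collection(2), cfg, n_generations = 100,
                  sample_every = 10, seed = 24, ignore_data = TRUE)
  path <- tempfile(fileext = ".tsv")
  write_trace(tr, path)
  back <- read_trace(path)
  expect_equal(back$lnl, tr$lnl)
  expect_equal(back$partition, tr$partition)
  expect_equal(attr(back, "labels"), attr(tr, "labels"))
})
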