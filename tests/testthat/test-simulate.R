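test_that("prior draws of the divergence model follow the CRP", {
  cfg <- prior_config(alpha = 1.414216)
  set.seed(30)
  ks <- replicate(4000, {
    length(unique(draw_model_from_prior(cfg, 3)$partition))
  })
  exact <- crp_exact_k_probs(3, 1.414216)
  counts <- tabulate(ks, 3)
  expect_gt(chisq.test(counts, p = exact)$p.value, 0.001)
  # tiny concentration collapses to one event
  cfg0 <- prior_config(alpha = 1e-9)
  set.seed(31)
  expect_true(all(replicate(50, {
    length(unique(draw_model_from_prior(cfg0, 4)$partition)) == 1
  })))
  # fixed-size configuration is honored
  cfgf <- prior_config(size_fixed = 0.002, root_rel_fixed = 1)
  tr <- draw_model_from_prior(cfgf, 3)
  expect_equal(tr$N_d1, rep(0.002, 3))
  expect_equal(tr$N_root, rep(0.002, 3))
})

test_that("gene trees respect the species-tree constraints", {
  d <- demog_default(t = 0.01)
  set.seed(40)
  tr <- simulate_gene_tree(d, 1, 0)
  expect_equal(length(tr$tip.label), 1)
  # two copies from different populations never coalesce before t
  tmrcas <- replicate(200, {
    g <- simulate_gene_tree(d, 1, 1)
    sum(g$edge.length) / 2
  })
  expect_true(all(tmrcas >= d$t))
  # mean within-population pairwise coalescence time is 2N
  d1 <- pair_demography(t = 10, N_d1 = 0.002, N_d2 = 0.002, R_root = 1)
  set.seed(41)
  tm <- replicate(3000, sum(simulate_gene_tree(d1, 2, 0)$edge.length) / 2)
  expect_equal(mean(tm), 2 * 0.002, tolerance = 0.06)
})

test_that("locus simulation produces one column per site on a shared tree", {
  d <- demog_default()
  m <- mutation_model()
  set.seed(42)
  g <- simulate_gene_tree(d, 3, 3)
  loc <- simulate_locus(g, 25, m)
  expect_equal(dim(loc), c(6, 25))
  expect_true(all(loc %in% 0:1))
  # zero-length branches: every copy inherits the root state
  g0 <- g
  g0$edge.length[] <- 0
  loc0 <- simulate_locus(g0, 10, m)
  expect_true(all(apply(loc0, 2, function(x) length(unique(x)) == 1)))
})

test_that("unlinked simulation frequencies match the exact pattern probabilities", {
  # cross-module oracle: generative coalescent simulation against the
  # analytic likelihood
  d <- pair_demography(t = 0.008, N_d1 = 0.0015, N_d2 = 0.003,
                       N_root = 0.002)
  m <- mutation_model()
  set.seed(50)
  cd <- simulate_pair(d, m, n_sites = 3e5, n1 = 4, n2 = 3,
                      method = "tree")
  pr <- pattern_probability(cd$patterns, d, m)
  expected <- pr$prob * sum(cd$patterns$weight)
  # chi-square over the observed support plus the unobserved remainder
  chisq <- sum((cd$patterns$weight - expected)^2 / expected)
  df <- nrow(cd$patterns) - 1
  expect_gt(pchisq(chisq, df, lower.tail = FALSE), 0.001)
})

test_that("multinomial shortcut and gene-tree simulation agree", {
  d <- demog_default(t = 0.01)
  m <- mutation_model()
  set.seed(51)
  a <- simulate_pair(d, m, n_sites = 2e5, n1 = 5, n2 = 5, method = "tree")
  b <- simulate_pair(d, m, n_sites = 2e5, n1 = 5, n2 = 5,
                     method = "multinomial")
  key <- function(x) paste(x$n1, x$r1, x$n2, x$r2)
  all_keys <- union(key(a$patterns), key(b$patterns))
  wa <- setNames(rep(0, length(all_keys)), all_keys)
  wb <- wa
  wa[key(a$patterns)] <- a$patterns$weight
  wb[key(b$patterns)] <- b$patterns$weight
  keep <- wa + wb > 20
  tab <- rbind(wa[keep], wb[keep])
  expect_gt(chisq.test(tab)$p.value, 0.001)
})

test_that("linked loci change covariance, not per-site marginals", {
  d <- demog_default(t = 0.01)
  m <- mutation_model()
  set.seed(52)
  unl <- simulate_pair(d, m, n_sites = 2e5, n1 = 4, n2 = 4,
                       method = "tree")
  lnk <- simulate_pair(d, m, n_sites = 2e5, n1 = 4, n2 = 4,
                       locus_length = 100, method = "tree")
  # compare marginal pattern frequencies; linked counts are overdispersed
  # relative to multinomial, so test against the exact probabilities with
  # a generous tolerance instead of a chi-square
  pr <- pattern_probability(lnk$patterns, d, m)
  freq <- lnk$patterns$weight / sum(lnk$patterns$weight)
  expect_true(all(abs(freq - pr$prob) < 0.01 + 0.3 * pr$prob))
  expect_equal(sum(unl$patterns$weight), sum(lnk$patterns$weight))
})

test_that("missingness thins gene copies per site", {
  set.seed(60)
  cfg <- prior_config()
  sim <- simulate_dataset(cfg, n_pairs = 1, n_sites = 5000)
  cd <- sim$collection[[1]]
  expect_identical(apply_missingness(cd, 1), cd)
  thin <- apply_missingness(cd, 0.75)
  n_before <- sum((cd$patterns$n1 + cd$patterns$n2) * cd$patterns$weight)
  n_after <- sum((thin$patterns$n1 + thin$patterns$n2) *
                   thin$patterns$weight)
  expect_equal(n_after / n_before, 0.75, tolerance = 0.02)
  expect_true(all(thin$patterns$n1 <= 10 & thin$patterns$n2 <= 10))
})

test_that("singleton acquisition bias removes only singleton sites", {
  set.seed(61)
  cfg <- prior_config()
  sim <- simulate_dataset(cfg, n_pairs = 1, n_sites = 50000)
  cd <- sim$collection[[1]]
  expect_identical(apply_singleton_bias(cd, 1), cd)
  pat <- cd$patterns
  tot <- pat$r1 + pat$r2
  singleton <- tot == 1 | tot == pat$n1 + pat$n2 - 1
  n_singleton <- sum(pat$weight[singleton])
  thin <- apply_singleton_bias(cd, 0.4)
  pat2 <- thin$patterns
  tot2 <- pat2$r1 + pat2$r2
  singleton2 <- tot2 == 1 | tot2 == pat2$n1 + pat2$n2 - 1
  # non-singleton sites untouched
  expect_equal(sum(pat2$weight[!singleton2]), sum(pat$weight[!singleton]))
  # singletons thinned to ~40% (binomial mean)
  kept <- sum(pat2$weight[singleton2])
  se <- sqrt(n_singleton * 0.4 * 0.6)
  expect_lt(abs(kept - 0.4 * n_singleton), 4 * se)
  # a data set without singletons is untouched
  ns <- comparison_data(allele_patterns(c(4, 4), c(0, 2), 4, c(0, 2)))
  set.seed(62)
  expect_equal(as.data.frame(apply_singleton_bias(ns, 0.5)$patterns),
               as.data.frame(ns$patterns))
})

test_that("dataset simulation is reproducible and conserves site counts", {
  cfg <- prior_config()
  set.seed(70)
  a <- simulate_dataset(cfg, n_pairs = 3, n_sites = 100)
  set.seed(70)
  b <- simulate_dataset(cfg, n_pairs = 3, n_sites = 100)
  expect_equal(a$truth$t, b$truth$t)
  expect_equal(lapply(a$collection, function(x) as.data.frame(x$patterns)),
               lapply(b$collection, function(x) as.data.frame(x$patterns)))
  for (cd in a$collection) expect_equal(sum(cd$patterns$weight), 100)
})
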