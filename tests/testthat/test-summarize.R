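toy_trace <- function(k, partition, t1, t2 = t1, chain = 1L) {
  structure(
    tibble::tibble(
      generation = seq_along(k), lnl = 0, lnp = 0, alpha = 1,
      k = k, partition = partition, t_a = t1, t_b = t2,
      .chain = chain
    ),
    class = c("codiv_chain", "tbl_df", "tbl", "data.frame"),
    labels = c("a", "b")
  )
}

test_that("posterior summaries match hand counts on a toy trace", {
  tr <- toy_trace(
    k = c(1, 1, 1, 2, 2, 1, 1, 1, 2, 1),
    partition = c(rep("0,0", 3), "0,1", "0,1", rep("0,0", 3), "0,1",
                  "0,0"),
    t1 = seq(0.01, 0.1, by = 0.01)
  )
  sm <- summarize_trace(tr, burn_in = 0)
  expect_equal(sm$p_k$prob, c(0.7, 0.3))
  expect_equal(sm$map_model, "0,0")
  expect_equal(sm$map_model_prob, 0.7)
  expect_equal(sm$map_k, 1)
  expect_equal(sort(sm$k_credible_set), c(1, 2))
  expect_equal(sm$t_summary$mean[1], mean(tr$t_a))
  # burn-in removes leading samples
  sm2 <- summarize_trace(tr, burn_in = 5)
  expect_equal(sm2$p_k$prob, c(0.8, 0.2))
  expect_error(summarize_trace(tr, burn_in = 10), "burn_in")
})

test_that("chain order does not change pooled summaries", {
  a <- toy_trace(c(1, 1, 2, 1), c("0,0", "0,0", "0,1", "0,0"),
                 c(.01, .02, .03, .04), chain = 1L)
  b <- toy_trace(c(2, 2, 1, 2), c("0,1", "0,1", "0,0", "0,1"),
                 c(.05, .06, .07, .08), chain = 2L)
  s1 <- summarize_trace(list(a, b))
  s2 <- summarize_trace(list(b, a))
  expect_equal(s1$p_k, s2$p_k)
  expect_equal(sort(s1$t_summary$mean), sort(s2$t_summary$mean))
  # two chains pooled equal one concatenated chain
  ab <- dplyr::bind_rows(a, b)
  ab$.chain <- 1L
  s3 <- summarize_trace(structure(ab, class = class(a),
                                  labels = c("a", "b")))
  expect_equal(s1$p_k, s3$p_k)
})

test_that("credible sets are the smallest sets reaching the level", {
  tr <- toy_trace(
    k = rep(c(1, 2), c(97, 3)),
    partition = rep(c("0,0", "0,1"), c(97, 3)),
    t1 = runif(100)
  )
  sm <- summarize_trace(tr)
  expect_equal(sm$k_credible_set, 1)
  expect_equal(sm$model_credible_set, "0,0")
  expect_gte(sum(sm$p_k$prob[sm$p_k$k %in% sm$k_credible_set]), 0.95)
})

test_that("Bayes factors follow the odds-ratio formula", {
  post <- tibble::tibble(k = 1:2, prob = c(0.8, 0.2))
  prior <- tibble::tibble(k = 1:2, prob = c(0.5, 0.5))
  bf <- bayes_factors_k(post, prior)
  expect_equal(bf$bf, c(4, 0.25))
  # posterior equal to the prior gives unit Bayes factors
  bf1 <- bayes_factors_k(prior, prior)
  expect_equal(bf1$bf, c(1, 1))
  # all mass on one k is reported as infinite
  post2 <- tibble::tibble(k = 1:2, prob = c(1, 0))
  expect_equal(bayes_factors_k(post2, prior)$bf[1], Inf)
  expect_error(bayes_factors_k(post, tibble::tibble(k = 1:3,
                                                    prob = rep(1 / 3, 3))),
               "same numbers")
  # raw-count recomputation matches the formula
  ks <- rep(c(1, 2, 3), c(60, 30, 10))
  pk <- tibble::tibble(k = 1:3, prob = tabulate(ks, 3) / length(ks))
  pr <- tibble::tibble(k = 1:3, prob = c(0.5, 0.3, 0.2))
  bf3 <- bayes_factors_k(pk, pr)
  for (kk in 1:3) {
    o_post <- sum(ks == kk) / sum(ks != kk)
    o_prior <- pr$prob[kk] / (1 - pr$prob[kk])
    expect_equal(bf3$bf[kk], o_post / o_prior)
  }
})

test_that("the potential scale reduction factor diagnoses disagreement", {
  set.seed(80)
  x <- rnorm(500)
  expect_equal(psrf(list(x, x)), 1, tolerance = 2e-3)
  long <- lapply(1:3, function(i) rnorm(5000))
  expect_lt(abs(psrf(long) - 1), 0.01)
  apart <- list(rnorm(200), rnorm(200) + 50)
  expect_gt(psrf(apart), 10)
  expect_error(psrf(list(x)), "two chains")
  expect_error(psrf(list(x, x[-1])), "equal lengths")
})

test_that("effective sample size tracks autocorrelation", {
  set.seed(81)
  x <- rnorm(4000)
  expect_equal(ess(x), 4000, tolerance = 0.15)
  # AR(1): ESS ~ n (1 - rho) / (1 + rho)
  rho <- 0.9
  ar <- as.numeric(arima.sim(list(ar = rho), 8000))
  expect_equal(ess(ar), 8000 * (1 - rho) / (1 + rho), tolerance = 0.3)
  expect_equal(ess(rep(1, 100)), 0)
  expect_error(ess(1:5), "at least 10")
})

test_that("calibration bins compare posterior mass with empirical truth", {
  out <- calibration_bins(rep(1, 8), rep(TRUE, 8))
  expect_equal(nrow(out), 1)
  expect_equal(out$mean_posterior, 1)
  expect_equal(out$empirical_freq, 1)
  # perfectly calibrated construction: truth drawn from the stated prob
  set.seed(82)
  p <- runif(6000)
  truth <- runif(6000) < p
  cb <- calibration_bins(p, truth, bin_width = 0.2)
  expect_equal(sum(cb$count), 6000)
  expect_true(all(abs(cb$mean_posterior - cb$empirical_freq) < 0.04))
})

test_that("summaries write YAML plus tab-separated tables", {
  tr <- toy_trace(c(1, 2, 1, 1), c("0,0", "0,1", "0,0", "0,0"),
                  c(.01, .02, .03, .04))
  sm <- summarize_trace(tr)
  dir <- tempfile()
  write_summary(sm, dir)
  expect_true(file.exists(file.path(dir, "summary.yml")))
  expect_true(file.exists(file.path(dir, "number_of_events.tsv")))
  y <- yaml::read_yaml(file.path(dir, "summary.yml"))
  expect_equal(y$map_model, "0,0")
})

test_that("tidiers expose the summary and trace as tibbles", {
  tr <- toy_trace(c(1, 2, 1, 1), c("0,0", "0,1", "0,0", "0,0"),
                  c(.01, .02, .03, .04))
  sm <- summarize_trace(tr)
  td <- tidy(sm)
  expect_equal(td$pair, c("a", "b"))
  gl <- glance(sm)
  expect_equal(gl$map_k, 1)
  long <- tidy(tr)
  expect_true(all(c("parameter", "value") %in% names(long)))
  p <- autoplot(sm, prior = tibble::tibble(k = 1:2, prob = c(.6, .4)))
  expect_s3_class(p, "ggplot")
  p2 <- plot_divergence_times(tr)
  expect_s3_class(p2, "ggplot")
})
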