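# shared driver for the simulation-study checks: simulate data sets under
# matched priors, run the sampler, and collect calibration summaries

run_inference_study <- function(n_reps, cfg, n_sites, locus_length = 1,
                                singleton_p_retain = 1,
                                method = "tree", n_generations = 1500,
                                sample_every = 5, burn_in = 60,
                                seed0 = 5000) {
  res <- lapply(seq_len(n_reps), function(r) {
    set.seed(seed0 + r)
    sim <- simulate_dataset(cfg, n_pairs = 3, n_sites = n_sites,
                            locus_length = locus_length,
                            singleton_p_retain = singleton_p_retain,
                            method = method)
    tr <- run_chain(sim$collection, cfg, n_generations = n_generations,
                    sample_every = sample_every,
                    seed = seed0 + 100000 + r)
    sm <- summarize_trace(tr, burn_in = burn_in)
    tru <- sim$truth
    ktrue <- length(unique(tru$partition))
    truemod <- paste(tru$partition, collapse = ",")
    covered <- vapply(1:3, function(i) {
      x <- tr[[paste0("t_pair", i)]][-seq_len(burn_in)]
      q <- quantile(x, c(0.025, 0.975), names = FALSE)
      tru$t[i] >= q[1] && tru$t[i] <= q[2]
    }, TRUE)
    pmod <- sm$p_model$prob[match(truemod, sm$p_model$partition)]
    list(covered = covered,
         k_in_cs = ktrue %in% sm$k_credible_set,
         p_correct_k = sm$p_k$prob[ktrue],
         p_correct_model = ifelse(is.na(pmod), 0, pmod),
         map_correct = sm$map_k == ktrue,
         p_k1 = sm$p_k$prob[1],
         k1_true = ktrue == 1)
  })
  list(
    coverage = mean(unlist(lapply(res, `[[`, "covered"))),
    k_in_cs = mean(vapply(res, `[[`, TRUE, "k_in_cs")),
    median_p_k = median(vapply(res, `[[`, 0.0, "p_correct_k")),
    median_p_model = median(vapply(res, `[[`, 0.0, "p_correct_model")),
    p_map_correct = mean(vapply(res, `[[`, TRUE, "map_correct")),
    p_k1 = vapply(res, `[[`, 0.0, "p_k1"),
    k1_true = vapply(res, `[[`, TRUE, "k1_true"),
    p_correct_k = vapply(res, `[[`, 0.0, "p_correct_k")
  )
}

# bootstrap Monte Carlo standard error of a sample median
median_boot_se <- function(x, B = 2000, seed = 1) {
  set.seed(seed)
  sd(vapply(seq_len(B), function(b) {
    median(sample(x, length(x), replace = TRUE))
  }, 0.0))
}

validation_config <- function() {
  prior_config(tau_shape = 1, tau_mean = 0.01, size_shape = 5,
               size_mean = 0.002, root_rel_shape = 100, root_rel_mean = 1,
               pi = 0.5, alpha = 1.414216)
}
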