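# shared fixtures and independent oracles

demog_default <- function(t = 0.01, N = 0.002, R = 1) {
  pair_demography(t = t, N_d1 = N, N_d2 = N, R_root = R)
}

# index of state (n, r) in the partial-likelihood state vector
state_idx <- function(n, r) {
  i <- 1L + (n - 1L) * (n + 2L) / 2L + r + 1L
  i[n == 0] <- 1L
  as.integer(i)
}

# Monte Carlo oracle for the two-copy (one per population) pattern:
# the lineages cannot coalesce before the divergence time, then coalesce
# at pair rate 1/(2*N_root); the tip states differ with the two-state
# closed-form probability for the total separating path length.
mc_prob_two_copies_differ <- function(t, N_root, mu = 1, n_sim = 2e6) {
  Tc <- rexp(n_sim, rate = 1 / (2 * N_root))
  L <- 2 * t + 2 * Tc
  mean((1 - exp(-2 * mu * L)) / 2)
}

# exact prior distribution of the number of events under the CRP:
# p(k) = |s(N, k)| alpha^k / rising_factorial(alpha, N), with unsigned
# Stirling numbers of the first kind from their recurrence
crp_exact_k_probs <- function(n, alpha) {
  s <- matrix(0, n + 1, n + 1)
  s[1, 1] <- 1
  for (i in seq_len(n)) {
    for (k in seq_len(i)) {
      s[i + 1, k + 1] <- s[i, k] + (i - 1) * s[i, k + 1]
    }
  }
  num <- s[n + 1, 2:(n + 1)] * alpha^seq_len(n)
  num / prod(alpha + 0:(n - 1))
}

# brute-force enumeration of set partitions grouped by block count
enumerate_partition_count <- function(n, k) {
  sum(vapply(enumerate_partitions(n), function(p) {
    length(unique(p)) == k
  }, TRUE))
}

truth_demographies <- function(truth) {
  lapply(seq_along(truth$t), function(i) {
    pair_demography(t = truth$t[i], N_d1 = truth$N_d1[i],
                    N_d2 = truth$N_d2[i], R_root = truth$R_root[i])
  })
}

variable_weight <- function(cd) {
  pat <- cd$patterns
  con <- (pat$r1 == 0 & pat$r2 == 0) |
    (pat$r1 == pat$n1 & pat$r2 == pat$n2)
  sum(pat$weight[!con])
}

write_test_nexus <- function(path, seqs) {
  nt <- length(seqs)
  nc <- nchar(seqs[[1]])
  lines <- c("#NEXUS", "BEGIN DATA;",
             sprintf("    DIMENSIONS NTAX=%d NCHAR=%d;", nt, nc),
             "    FORMAT DATATYPE=DNA MISSING=? GAP=-;",
             "    MATRIX",
             paste0("    ", names(seqs), "  ", unlist(seqs)),
             "    ;", "END;")
  writeLines(lines, path)
  path
}

write_test_fasta <- function(path, seqs) {
  writeLines(unlist(lapply(names(seqs), function(nm) {
    c(paste0(">", nm), seqs[[nm]])
  })), path)
  path
}
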