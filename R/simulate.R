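#' Draw a divergence model and nuisance parameters from the prior
#'
#' The partition of pairs to events comes from the Chinese restaurant
#' process, each event time from the gamma base distribution, and the
#' size parameters from their gamma priors (or the configured fixed
#' values).
#'
#' @param config A [prior_config()].
#' @param n_pairs Number of population pairs.
#' @param labels Optional pair labels.
#' @return A `codiv_truth` list: `partition` (canonical 0-based), `tau`
#'   (one time per event), per-pair `t`, `N_d1`, `N_d2`, `R_root`,
#'   `N_root`, `pi`, and `alpha`.
#' @export
draw_model_from_prior <- function(config, n_pairs,
                                  labels = paste0("pair", seq_len(n_pairs))) {
  alpha <- config$alpha
  if (is.null(alpha)) {
    alpha <- rgamma(1, shape = config$alpha_shape,
                    scale = config$alpha_mean / config$alpha_shape)
  }
  z <- integer(n_pairs)
  for (i in seq_len(n_pairs)) {
    counts <- tabulate(z[seq_len(i - 1)], nbins = max(z, 1))
    probs <- c(counts, alpha)
    z[i] <- sample.int(length(probs), 1, prob = probs)
  }
  z <- canonical_partition(z)
  k <- length(unique(z))
  tau <- rgamma(k, shape = config$tau_shape,
                scale = config$tau_mean / config$tau_shape)
  draw_size <- function(m) {
    if (!is.null(config$size_fixed)) rep(config$size_fixed, m)
    else rgamma(m, shape = config$size_shape,
                scale = config$size_mean / config$size_shape)
  }
  N_d1 <- draw_size(n_pairs)
  N_d2 <- draw_size(n_pairs)
  R_root <- if (!is.null(config$root_rel_fixed)) {
    rep(config$root_rel_fixed, n_pairs)
  } else {
    rgamma(n_pairs, shape = config$root_rel_shape,
           scale = config$root_rel_mean / config$root_rel_shape)
  }
  pi <- if (length(config$pi) == 2) {
    rbeta(n_pairs, config$pi[1], config$pi[2])
  } else {
    rep(config$pi, n_pairs)
  }
  structure(list(
    labels = labels, partition = z, tau = tau, t = tau[z + 1],
    N_d1 = N_d1, N_d2 = N_d2, R_root = R_root,
    N_root = R_root * (N_d1 + N_d2) / 2, pi = pi, alpha = alpha,
    mu = config$mu
  ), class = "codiv_truth")
}

truth_demography <- function(truth, i) {
  pair_demography(t = truth$t[i], N_d1 = truth$N_d1[i],
                  N_d2 = truth$N_d2[i], R_root = truth$R_root[i])
}

#' Simulate a coalescent gene tree within a pair's species tree
#'
#' Standard coalescent within each descendant population (each lineage
#' pair coalescing at rate `1 / (2 N)`) truncated at the divergence time;
#' the surviving lineages then coalesce to a single root in the ancestral
#' population. Copies from different populations therefore never coalesce
#' more recently than the divergence time.
#'
#' @param demography A [pair_demography()].
#' @param n1,n2 Gene copies sampled per population.
#' @return An [ape::phylo] tree with tip labels `p1_1, ..., p2_1, ...`
#'   and branch lengths in expected substitutions per site.
#' @export
simulate_gene_tree <- function(demography, n1, n2) {
  stopifnot(n1 + n2 >= 1)
  tr <- sim_gene_tree_cpp(n1, n2, demography$t, demography$N_root,
                          demography$N_d1, demography$N_d2)
  ntip <- n1 + n2
  tips <- c(if (n1 > 0) paste0("p1_", seq_len(n1)),
            if (n2 > 0) paste0("p2_", seq_len(n2)))
  if (ntip == 1) {
    return(structure(list(edge = matrix(c(2L, 1L), 1, 2),
                          edge.length = 0, tip.label = tips,
                          Nnode = 1L), class = "phylo"))
  }
  parent <- tr$parent + 1L
  nodetime <- tr$time
  nn <- length(parent)
  # ape numbering: tips 1..ntip, root ntip+1, then remaining internals.
  # simulator numbering: tips first, internals in creation order with the
  # root created last (= nn).
  remap <- integer(nn)
  remap[seq_len(ntip)] <- seq_len(ntip)
  internals <- (ntip + 1L):nn
  remap[nn] <- ntip + 1L
  if (nn > ntip + 1L) {
    remap[internals[-length(internals)]] <- (ntip + 2L):nn
  }
  child <- seq_len(nn)[-nn]
  edge <- cbind(remap[parent[child]], remap[child])
  edge.length <- nodetime[parent[child]] - nodetime[child]
  structure(list(edge = edge, edge.length = edge.length,
                 tip.label = tips, Nnode = nn - ntip,
                 node.time = nodetime[order(remap)]),
            class = "phylo")
}

#' Simulate linked binary characters along one gene tree
#'
#' All sites of the locus evolve independently down the same gene tree
#' under the two-state mutation model, with the root state drawn from the
#' stationary frequencies.
#'
#' @param tree An [ape::phylo] gene tree.
#' @param length Number of sites.
#' @param model A [mutation_model()].
#' @return Integer 0/1 matrix, tips in rows (named), sites in columns.
#' @export
simulate_locus <- function(tree, length, model) {
  stopifnot(length >= 1)
  ntip <- base::length(tree$tip.label)
  nn <- ntip + tree$Nnode
  states <- matrix(NA_integer_, nn, length)
  root <- ntip + 1L
  pi_red <- model$v / (model$u + model$v)
  states[root, ] <- as.integer(runif(length) < pi_red)
  if (ntip > 1) {
    # root-to-tip edge order so a parent state exists before its children
    rt <- ape::reorder.phylo(tree, "cladewise")
    ec <- rt$edge
    el <- rt$edge.length
    pi_green <- 1 - pi_red
    for (e in seq_len(nrow(ec))) {
      decay <- 1 - exp(-(model$u + model$v) * el[e])
      ps <- states[ec[e, 1], ]
      pf <- ifelse(ps == 1, pi_green * decay, pi_red * decay)
      flip <- runif(length) < pf
      states[ec[e, 2], ] <- ifelse(flip, 1L - ps, ps)
    }
  }
  out <- states[seq_len(ntip), , drop = FALSE]
  rownames(out) <- tree$tip.label
  out
}

#' Simulate a character data set for one pair
#'
#' In `"tree"` mode each locus gets an independent gene tree and its
#' sites share that tree (unlinked characters are loci of length one). In
#' `"multinomial"` mode, available for unlinked characters only, the site
#' pattern counts are drawn directly from the exact stationary pattern
#' distribution computed by the likelihood machinery; the two modes
#' target the same distribution of pattern counts.
#'
#' @param demography A [pair_demography()].
#' @param model A [mutation_model()].
#' @param n_sites Total characters.
#' @param n1,n2 Gene copies per population.
#' @param locus_length Linked sites per gene tree (1 = unlinked).
#' @param method `"tree"` or `"multinomial"`.
#' @param label Pair label.
#' @return A `codiv_comparison`; in tree mode the per-locus variable-site
#'   counts are attached as attribute `locus_variable`.
#' @export
simulate_pair <- function(demography, model, n_sites, n1 = 10, n2 = 10,
                          locus_length = 1,
                          method = c("tree", "multinomial"),
                          label = "pair") {
  method <- match.arg(method)
  stopifnot(n_sites >= 1, locus_length >= 1,
            n_sites %% locus_length == 0)
  if (method == "multinomial" && locus_length != 1) {
    stop("multinomial simulation is only exact for unlinked characters")
  }
  if (method == "tree") {
    n_loci <- n_sites %/% locus_length
    sim <- sim_pair_counts_cpp(n1, n2, demography$t, demography$N_root,
                               demography$N_d1, demography$N_d2,
                               model$u, model$v, n_loci, locus_length)
    counts <- sim$counts
    lv <- sim$locus_variable
  } else {
    M <- pattern_prob_matrix_cpp(n1, n2, demography$t, demography$N_root,
                                 demography$N_d1, demography$N_d2,
                                 model$u, model$v)
    probs <- M[state_index_r(n1, 0:n1), state_index_r(n2, 0:n2)]
    counts <- matrix(rmultinom(1, n_sites, as.vector(probs)),
                     n1 + 1, n2 + 1)
    lv <- NULL
  }
  idx <- which(counts > 0, arr.ind = TRUE)
  pat <- allele_patterns(n1 = n1, r1 = idx[, 1] - 1L,
                         n2 = n2, r2 = idx[, 2] - 1L,
                         weight = counts[idx])
  loci <- if (locus_length > 1) {
    tibble(locus = seq_len(n_sites %/% locus_length),
           sites = locus_length)
  } else {
    NULL
  }
  cd <- comparison_data(pat, label = label, loci = loci)
  attr(cd, "locus_variable") <- lv
  cd
}

#' Thin sampled gene copies to emulate missing data
#'
#' Every gene copy of every site is independently retained with
#' probability `p_sample`; the allele counts are recomputed from the
#' retained copies. Sites losing all copies in both populations are
#' dropped (their number is reported in a message).
#'
#' @param data A `codiv_comparison` or `codiv_collection`.
#' @param p_sample Retention probability in (0, 1].
#' @return The thinned object.
#' @export
apply_missingness <- function(data, p_sample) {
  stopifnot(p_sample > 0, p_sample <= 1)
  if (inherits(data, "codiv_collection")) {
    return(comparison_collection(lapply(data, apply_missingness,
                                        p_sample = p_sample)))
  }
  if (p_sample == 1) return(data)
  pat <- data$patterns
  i <- rep.int(seq_len(nrow(pat)), pat$weight)
  n1 <- pat$n1[i]; r1 <- pat$r1[i]; n2 <- pat$n2[i]; r2 <- pat$r2[i]
  ns <- length(i)
  n1p <- rbinom(ns, n1, p_sample)
  n2p <- rbinom(ns, n2, p_sample)
  r1p <- rhyper(ns, m = r1, n = n1 - r1, k = n1p)
  r2p <- rhyper(ns, m = r2, n = n2 - r2, k = n2p)
  keep <- n1p + n2p > 0
  if (any(!keep)) {
    message(sum(!keep), " site(s) lost all sampled copies and were dropped")
  }
  newpat <- tibble(n1 = n1p[keep], r1 = r1p[keep],
                   n2 = n2p[keep], r2 = r2p[keep])
  newpat <- dplyr::count(newpat, .data$n1, .data$r1, .data$n2, .data$r2,
                         name = "weight")
  newpat$weight <- as.integer(newpat$weight)
  constant_removed <- data$constant_removed
  if (constant_removed && any(is_constant_pattern(newpat))) {
    message("thinning made some sites constant; clearing the ",
            "variable-only flag")
    constant_removed <- FALSE
  }
  comparison_data(newpat, label = data$label, loci = data$loci,
                  constant_removed = constant_removed,
                  polyallelic_policy = data$polyallelic_policy)
}

#' Thin singleton sites to emulate acquisition bias
#'
#' A singleton site has exactly one gene copy (pooling both populations)
#' carrying a different allele from all the others. Each singleton site is
#' independently retained with probability `p_retain`; all other sites are
#' untouched.
#'
#' @param data A `codiv_comparison` or `codiv_collection`.
#' @param p_retain Retention probability in (0, 1].
#' @return The thinned object.
#' @export
apply_singleton_bias <- function(data, p_retain) {
  stopifnot(p_retain > 0, p_retain <= 1)
  if (inherits(data, "codiv_collection")) {
    return(comparison_collection(lapply(data, apply_singleton_bias,
                                        p_retain = p_retain)))
  }
  if (p_retain == 1) return(data)
  pat <- data$patterns
  total <- pat$r1 + pat$r2
  n_tot <- pat$n1 + pat$n2
  singleton <- (total == 1 & n_tot > 1) | (total == n_tot - 1 & n_tot > 1)
  w <- pat$weight
  w[singleton] <- rbinom(sum(singleton), w[singleton], p_retain)
  pat$weight <- as.integer(w)
  pat <- pat[pat$weight > 0, , drop = FALSE]
  comparison_data(pat, label = data$label, loci = data$loci,
                  constant_removed = data$constant_removed,
                  polyallelic_policy = data$polyallelic_policy)
}

#' Simulate a full multi-pair data set under the model
#'
#' Draws a divergence model and nuisance parameters from the prior (or
#' uses a supplied truth), simulates the requested characters for every
#' pair, and applies the optional perturbations in the order missingness,
#' then singleton acquisition bias.
#'
#' @param config A [prior_config()].
#' @param n_pairs Number of population pairs.
#' @param n_sites Characters per pair.
#' @param n1,n2 Gene copies per population.
#' @param locus_length Linked sites per gene tree (1 = unlinked).
#' @param p_sample Gene-copy sampling probability (1 = complete).
#' @param singleton_p_retain Singleton-site retention probability.
#' @param method Simulation method, see [simulate_pair()].
#' @param drop_constant Remove constant characters from the output (the
#'   truth is unaffected; the likelihood correction then applies).
#' @param truth Optional `codiv_truth` to reuse instead of drawing one.
#' @return A list with elements `collection` (a `codiv_collection`) and
#'   `truth` (a `codiv_truth`).
#' @export
simulate_dataset <- function(config, n_pairs = 3, n_sites = 1000,
                             n1 = 10, n2 = 10, locus_length = 1,
                             p_sample = 1, singleton_p_retain = 1,
                             method = c("tree", "multinomial"),
                             drop_constant = FALSE, truth = NULL) {
  method <- match.arg(method)
  if (is.null(truth)) truth <- draw_model_from_prior(config, n_pairs)
  comps <- lapply(seq_len(n_pairs), function(i) {
    simulate_pair(truth_demography(truth, i),
                  mutation_model(pi = truth$pi[i], mu = truth$mu),
                  n_sites = n_sites, n1 = n1, n2 = n2,
                  locus_length = locus_length, method = method,
                  label = truth$labels[i])
  })
  coll <- comparison_collection(comps)
  if (p_sample < 1) coll <- apply_missingness(coll, p_sample)
  if (singleton_p_retain < 1) {
    coll <- apply_singleton_bias(coll, singleton_p_retain)
  }
  if (drop_constant) {
    coll <- comparison_collection(lapply(coll, function(cd) {
      pat <- cd$patterns[!is_constant_pattern(cd$patterns), , drop = FALSE]
      comparison_data(pat, label = cd$label, loci = cd$loci,
                      constant_removed = TRUE,
                      polyallelic_policy = cd$polyallelic_policy)
    }))
  }
  list(collection = coll, truth = truth)
}

#' Write a simulated pair as a binary NEXUS alignment
#'
#' Expands the pattern table into per-sequence binary characters (copies
#' beyond a site's sampled count are written as missing) so simulated
#' data can round-trip through [read_alignment()].
#'
#' @param data A `codiv_comparison`.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_comparison_nexus <- function(data, path) {
  pat <- data$patterns
  n1max <- max(pat$n1); n2max <- max(pat$n2)
  i <- rep.int(seq_len(nrow(pat)), pat$weight)
  site_col <- function(n, r, nmax) {
    vapply(seq_along(n), function(s) {
      c(rep("1", r[s]), rep("0", n[s] - r[s]), rep("?", nmax - n[s]))
    }, character(nmax))
  }
  m <- rbind(site_col(pat$n1[i], pat$r1[i], n1max),
             site_col(pat$n2[i], pat$r2[i], n2max))
  ids <- c(paste0(data$label, "_pop1_", seq_len(n1max)),
           paste0(data$label, "_pop2_", seq_len(n2max)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#NEXUS", "BEGIN DATA;",
               sprintf("    DIMENSIONS NTAX=%d NCHAR=%d;",
                       length(ids), ncol(m)),
               "    FORMAT DATATYPE=STANDARD SYMBOLS=\"01\" MISSING=?;",
               "    MATRIX"), con)
  writeLines(paste0("    ", ids, "  ",
                    apply(m, 1, paste, collapse = "")), con)
  writeLines(c("    ;", "END;"), con)
  invisible(path)
}

#' Write the generating parameters of a simulation as YAML
#'
#' @param truth A `codiv_truth`.
#' @param path Output file.
#' @export
write_truth_yaml <- function(truth, path) {
  yaml::write_yaml(list(
    labels = truth$labels,
    partition = paste(truth$partition, collapse = ","),
    event_times = truth$tau,
    divergence_times = truth$t,
    N_d1 = truth$N_d1, N_d2 = truth$N_d2,
    R_root = truth$R_root, N_root = truth$N_root,
    pi = truth$pi, alpha = truth$alpha, mu = truth$mu
  ), path)
  invisible(path)
}
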