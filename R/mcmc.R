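#' Sample the joint posterior by Markov chain Monte Carlo
#'
#' Runs one chain of the Gibbs-within-Metropolis sampler: every
#' generation applies a multiplicative scale move to each free size
#' parameter of each pair, a scale move to each event time, a joint
#' event-time/root-size mixing move per event, one Gibbs sweep over the
#' pair-to-event assignments (Neal's Algorithm 8 with `n_aux` auxiliary
#' events), and an auxiliary-variable Gibbs update of the concentration
#' parameter when it is free. With `ignore_data = TRUE` the chain samples
#' from the joint prior, which is the standard validation that every
#' operator targets its intended distribution.
#'
#' @param collection A `codiv_collection` (may contain empty pattern
#'   tables when `ignore_data = TRUE`).
#' @param config A [prior_config()].
#' @param n_generations Number of sweeps.
#' @param sample_every Thinning interval (must divide `n_generations`).
#' @param seed RNG seed; the trace is a deterministic function of
#'   `(collection, config, seed)`.
#' @param ignore_data Sample from the prior instead of the posterior.
#' @param n_aux Auxiliary events for the partition Gibbs update.
#' @param tuning Named list overriding proposal windows (`size`, `tau`,
#'   `mixer`, `pi`).
#' @return A `codiv_chain`: a tibble with one row per retained generation
#'   (including generation 0) holding the log-likelihood, log-prior,
#'   concentration parameter, number of events `k`, the canonical
#'   partition string, and per-pair divergence times and size parameters;
#'   the configuration and seed are attached as attributes.
#' @export
run_chain <- function(collection, config, n_generations = 2000,
                      sample_every = 5, seed = 1, ignore_data = FALSE,
                      n_aux = 2, tuning = list()) {
  stopifnot(n_generations >= 1, sample_every >= 1,
            n_generations %% sample_every == 0)
  if (config$use_constant_characters) {
    correction <- 0L
    for (cd in collection) {
      if (cd$constant_removed) {
        stop("config expects constant characters but pair '", cd$label,
             "' is variable-only; set use_constant_characters = FALSE")
      }
    }
  } else {
    correction <- match(config$correction, c("per_site", "max_copies"))
    for (cd in collection) {
      if (!ignore_data && any(is_constant_pattern(cd$patterns))) {
        stop("variable-only analysis requested but pair '", cd$label,
             "' contains constant patterns")
      }
    }
  }
  tun <- utils::modifyList(list(size = 0.5, tau = 0.6, mixer = 0.4,
                                pi = 0.1), tuning)
  cfg <- list(
    tau_shape = config$tau_shape,
    tau_rate = config$tau_shape / config$tau_mean,
    size_free = is.null(config$size_fixed),
    size_shape = config$size_shape,
    size_rate = config$size_shape / config$size_mean,
    size_fixed = config$size_fixed %||% 0.0,
    rr_free = is.null(config$root_rel_fixed),
    rr_shape = config$root_rel_shape,
    rr_rate = config$root_rel_shape / config$root_rel_mean,
    rr_fixed = config$root_rel_fixed %||% 1.0,
    pi_free = length(config$pi) == 2,
    pi_a = if (length(config$pi) == 2) config$pi[1] else 1,
    pi_b = if (length(config$pi) == 2) config$pi[2] else 1,
    pi_fixed = if (length(config$pi) == 1) config$pi else 0.5,
    alpha_free = is.null(config$alpha),
    alpha_shape = config$alpha_shape,
    alpha_rate = config$alpha_shape / config$alpha_mean,
    alpha_fixed = config$alpha %||% 1.0,
    mu = config$mu,
    correction = correction,
    ignore_data = ignore_data,
    n_aux = as.integer(n_aux),
    generations = as.numeric(n_generations),
    sample_every = as.integer(sample_every),
    win_size = tun$size, win_tau = tun$tau, win_mixer = tun$mixer,
    win_pi = tun$pi
  )
  pats <- lapply(collection, function(cd) {
    m <- as.matrix(cd$patterns[, c("n1", "r1", "n2", "r2", "weight")])
    storage.mode(m) <- "integer"
    m
  })
  set.seed(seed)
  tr <- run_chain_cpp(unname(pats), cfg)
  labels <- unname(vapply(collection, `[[`, "", "label"))
  np <- length(labels)
  cn <- c("generation", "lnl", "lnp", "alpha", "k",
          paste0("event_", labels), paste0("t_", labels),
          paste0("N_d1_", labels), paste0("N_d2_", labels),
          paste0("N_root_", labels), paste0("R_root_", labels),
          paste0("pi_", labels))
  colnames(tr) <- cn
  out <- as_tibble(tr)
  zcols <- as.matrix(out[, paste0("event_", labels)])
  out$partition <- apply(zcols, 1, partition_string)
  out <- out[, c("generation", "lnl", "lnp", "alpha", "k", "partition",
                 setdiff(cn, c("generation", "lnl", "lnp", "alpha", "k",
                               paste0("event_", labels))))]
  structure(out, class = c("codiv_chain", class(out)),
            labels = labels, config = config, seed = seed)
}

#' Run several independent chains
#'
#' Chain `j` uses seed `seed + j - 1`; traces are concatenated with a
#' `.chain` identifier column.
#'
#' @inheritParams run_chain
#' @param n_chains Number of independent chains.
#' @return A `codiv_chains` tibble (one row per retained sample across
#'   chains).
#' @export
run_chains <- function(collection, config, n_chains = 3, seed = 1, ...) {
  traces <- lapply(seq_len(n_chains), function(j) {
    tr <- run_chain(collection, config, seed = seed + j - 1, ...)
    tr$.chain <- j
    tr
  })
  out <- dplyr::bind_rows(traces)
  structure(out, class = c("codiv_chain", class(out)),
            labels = attr(traces[[1]], "labels"),
            config = attr(traces[[1]], "config"), seed = seed)
}

#' Write or read an MCMC trace as tab-separated text
#'
#' @param trace A `codiv_chain` tibble.
#' @param path File path (one file per chain is conventional).
#' @return `read_trace` returns the trace tibble.
#' @export
write_trace <- function(trace, path) {
  write.table(trace, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  tb <- as_tibble(read.table(path, header = TRUE, sep = "\t",
                             check.names = FALSE,
                             colClasses = list(partition = "character")))
  labels <- sub("^t_", "", grep("^t_", names(tb), value = TRUE))
  structure(tb, class = c("codiv_chain", class(tb)), labels = labels)
}
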