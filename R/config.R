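#' Prior and sampler configuration
#'
#' Gamma distributions are parameterized by shape and mean (scale =
#' mean / shape); an exponential prior is a gamma with shape 1. The event
#' times receive the gamma base distribution of the Dirichlet process; the
#' descendant effective sizes (as the product of effective size and
#' mutation rate) receive a gamma prior; the root size is parameterized
#' relative to the mean of the two descendant sizes and receives its own
#' gamma prior. The state frequency `pi` of the green allele is either
#' fixed (recommended 0.5 for recoded nucleotide data) or free with a beta
#' prior, and the concentration parameter `alpha` is either fixed or free
#' with a gamma hyperprior.
#'
#' @param tau_shape,tau_mean Gamma prior on each divergence-event time (in
#'   expected substitutions per site).
#' @param size_shape,size_mean Gamma prior on descendant population sizes,
#'   or `size_fixed` to pin them.
#' @param root_rel_shape,root_rel_mean Gamma prior on the relative root
#'   size, or `root_rel_fixed` to pin it.
#' @param size_fixed,root_rel_fixed Fixed values (use `NULL` to estimate).
#' @param pi Fixed green-state frequency, or `c(a, b)` beta parameters to
#'   estimate it per pair.
#' @param alpha Fixed concentration parameter, or `NULL` to use the
#'   hyperprior.
#' @param alpha_shape,alpha_mean Gamma hyperprior on `alpha` when free.
#' @param mu Overall mutation rate (default 1: time in units of expected
#'   substitutions per site).
#' @param use_constant_characters Does the analysis include constant
#'   characters? If `FALSE`, `correction` conditions the likelihood on
#'   variability.
#' @param correction Constant-character correction for variable-only
#'   data: `"per_site"` (each pattern conditioned at its own sample
#'   sizes) or `"max_copies"` (the SNAPP-style correction at the maximum
#'   sample sizes).
#' @return A `codiv_config` list.
#' @export
prior_config <- function(tau_shape = 1, tau_mean = 0.01,
                         size_shape = 5, size_mean = 0.002,
                         size_fixed = NULL,
                         root_rel_shape = 100, root_rel_mean = 1,
                         root_rel_fixed = NULL,
                         pi = 0.5,
                         alpha = 1.414216,
                         alpha_shape = 2, alpha_mean = 2,
                         mu = 1,
                         use_constant_characters = TRUE,
                         correction = c("per_site", "max_copies")) {
  correction <- match.arg(correction)
  stopifnot(tau_shape > 0, tau_mean > 0, size_shape > 0, size_mean > 0,
            root_rel_shape > 0, root_rel_mean > 0, mu > 0)
  if (length(pi) == 1) stopifnot(pi > 0, pi < 1)
  if (!is.null(alpha)) stopifnot(alpha > 0)
  structure(list(
    tau_shape = tau_shape, tau_mean = tau_mean,
    size_shape = size_shape, size_mean = size_mean,
    size_fixed = size_fixed,
    root_rel_shape = root_rel_shape, root_rel_mean = root_rel_mean,
    root_rel_fixed = root_rel_fixed,
    pi = pi,
    alpha = alpha, alpha_shape = alpha_shape, alpha_mean = alpha_mean,
    mu = mu,
    use_constant_characters = use_constant_characters,
    correction = correction
  ), class = "codiv_config")
}

#' @export
print.codiv_config <- function(x, ...) {
  fmt <- function(s, m) sprintf("Gamma(shape = %g, mean = %g)", s, m)
  cat("<codiv_config>\n")
  cat("  event times tau ~", fmt(x$tau_shape, x$tau_mean), "\n")
  cat("  descendant sizes ~",
      if (is.null(x$size_fixed)) fmt(x$size_shape, x$size_mean)
      else paste("fixed at", x$size_fixed), "\n")
  cat("  relative root size ~",
      if (is.null(x$root_rel_fixed)) fmt(x$root_rel_shape, x$root_rel_mean)
      else paste("fixed at", x$root_rel_fixed), "\n")
  cat("  pi:", if (length(x$pi) == 2)
    sprintf("Beta(%g, %g)", x$pi[1], x$pi[2]) else
      paste("fixed at", x$pi), "  mu:", x$mu, "\n")
  cat("  concentration alpha:",
      if (is.null(x$alpha)) fmt(x$alpha_shape, x$alpha_mean)
      else paste("fixed at", x$alpha), "\n")
  cat("  characters:", if (x$use_constant_characters) "all (no correction)"
      else paste0("variable-only (", x$correction, " correction)"), "\n")
  invisible(x)
}

#' Read or write a run configuration as YAML
#'
#' The YAML schema follows the prior names used throughout the package:
#' `event_time_prior`, `leaf_population_size_prior`,
#' `root_relative_population_size_prior`, `freq_1`, `concentration`, and
#' an `mcmc` block (`generations`, `sample_every`, `chains`, `seed`).
#'
#' @param path YAML file path.
#' @return `read_run_config` returns a list with elements `config` (a
#'   `codiv_config`) and `mcmc` (sampler settings).
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  gp <- function(block, default_shape, default_mean) {
    if (is.null(block)) list(shape = default_shape, mean = default_mean)
    else list(shape = block$shape %||% default_shape,
              mean = block$mean %||% default_mean,
              fixed = block$fixed)
  }
  tau <- gp(y$event_time_prior, 1, 0.01)
  size <- gp(y$leaf_population_size_prior, 5, 0.002)
  rr <- gp(y$root_relative_population_size_prior, 100, 1)
  pi <- y$freq_1 %||% 0.5
  if (is.list(pi)) pi <- c(pi$a, pi$b)
  conc <- y$concentration
  alpha <- NULL; ash <- 2; amn <- 2
  if (is.null(conc)) {
    alpha <- 1.414216
  } else if (!is.null(conc$fixed)) {
    alpha <- conc$fixed
  } else {
    ash <- conc$shape %||% 2; amn <- conc$mean %||% 2
  }
  cfg <- prior_config(
    tau_shape = tau$shape, tau_mean = tau$mean,
    size_shape = size$shape, size_mean = size$mean,
    size_fixed = size$fixed,
    root_rel_shape = rr$shape, root_rel_mean = rr$mean,
    root_rel_fixed = rr$fixed,
    pi = pi, alpha = alpha, alpha_shape = ash, alpha_mean = amn,
    mu = y$mu %||% 1,
    use_constant_characters = y$use_constant_characters %||% TRUE,
    correction = y$correction %||% "per_site"
  )
  mc <- y$mcmc %||% list()
  mcmc <- list(generations = mc$generations %||% 2000L,
               sample_every = mc$sample_every %||% 5L,
               chains = mc$chains %||% 1L,
               seed = mc$seed %||% 1L)
  si <- mcmc$generations %% mcmc$sample_every
  if (si != 0) stop("sample_every must divide generations")
  list(config = cfg, mcmc = mcmc, data = y$data)
}

#' @rdname read_run_config
#' @param config A `codiv_config`.
#' @param mcmc Optional list of sampler settings to embed.
#' @param data Optional list of data file paths to embed.
#' @export
write_run_config <- function(config, path, mcmc = NULL, data = NULL) {
  y <- list(
    event_time_prior = list(shape = config$tau_shape,
                            mean = config$tau_mean),
    leaf_population_size_prior =
      if (is.null(config$size_fixed))
        list(shape = config$size_shape, mean = config$size_mean)
      else list(fixed = config$size_fixed),
    root_relative_population_size_prior =
      if (is.null(config$root_rel_fixed))
        list(shape = config$root_rel_shape, mean = config$root_rel_mean)
      else list(fixed = config$root_rel_fixed),
    freq_1 = if (length(config$pi) == 2)
      list(a = config$pi[1], b = config$pi[2]) else config$pi,
    concentration = if (is.null(config$alpha))
      list(shape = config$alpha_shape, mean = config$alpha_mean)
    else list(fixed = config$alpha),
    mu = config$mu,
    use_constant_characters = config$use_constant_characters,
    correction = config$correction
  )
  if (!is.null(mcmc)) y$mcmc <- mcmc
  if (!is.null(data)) y$data <- data
  yaml::write_yaml(y, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
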