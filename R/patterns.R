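#' Build a table of allele-count patterns
#'
#' An allele-count pattern records, for one site of one population pair,
#' the number of gene copies sampled from each population (`n1`, `n2`) and
#' how many of them carry the "red" allele (`r1`, `r2`). Identical site
#' patterns are collapsed with an integer multiplicity `weight`.
#'
#' @param n1,r1 Sampled gene copies and red-allele copies in population 1.
#' @param n2,r2 Same for population 2.
#' @param weight Positive integer site multiplicities (recycled).
#' @return A tibble with columns `n1`, `r1`, `n2`, `r2`, `weight`.
#' @examples
#' allele_patterns(n1 = 4, r1 = c(1, 2), n2 = 4, r2 = 0)
#' @export
allele_patterns <- function(n1, r1, n2, r2, weight = 1L) {
  pat <- tibble(
    n1 = as.integer(n1), r1 = as.integer(r1),
    n2 = as.integer(n2), r2 = as.integer(r2),
    weight = as.integer(weight)
  )
  validate_patterns(pat)
  pat
}

validate_patterns <- function(pat) {
  stopifnot(all(c("n1", "r1", "n2", "r2", "weight") %in% names(pat)))
  if (any(pat$r1 < 0 | pat$r1 > pat$n1 | pat$r2 < 0 | pat$r2 > pat$n2)) {
    stop("invalid pattern: need 0 <= r <= n in both populations")
  }
  if (any(pat$n1 + pat$n2 < 1)) {
    stop("invalid pattern: no gene copies sampled in either population")
  }
  if (any(pat$weight < 1)) stop("pattern weights must be >= 1")
  invisible(pat)
}

is_constant_pattern <- function(pat) {
  (pat$r1 == 0 & pat$r2 == 0) | (pat$r1 == pat$n1 & pat$r2 == pat$n2)
}

#' Bundle the patterns of one population pair
#'
#' @param patterns A pattern tibble (see [allele_patterns()]).
#' @param label Pair identifier.
#' @param loci Optional tibble with columns `locus` and `sites` recording
#'   the linkage structure of the original data.
#' @param constant_removed Were constant characters excluded upstream? If
#'   so the likelihood must be conditioned on variability (see
#'   [pair_log_likelihood()]).
#' @param polyallelic_policy One of `"none"`, `"recode"`, `"remove"`:
#'   how sites with more than two nucleotides were handled.
#' @return A `codiv_comparison` object.
#' @export
comparison_data <- function(patterns, label = "pair",
                            loci = NULL, constant_removed = FALSE,
                            polyallelic_policy = c("none", "recode",
                                                   "remove")) {
  validate_patterns(patterns)
  polyallelic_policy <- match.arg(polyallelic_policy)
  if (constant_removed && any(is_constant_pattern(patterns))) {
    stop("constant patterns present but constant_removed = TRUE")
  }
  structure(
    list(
      label = label,
      patterns = as_tibble(patterns),
      loci = loci,
      constant_removed = constant_removed,
      polyallelic_policy = polyallelic_policy,
      max_copies = c(n1 = max(patterns$n1), n2 = max(patterns$n2))
    ),
    class = "codiv_comparison"
  )
}

#' @export
print.codiv_comparison <- function(x, ...) {
  cat("<codiv_comparison> pair '", x$label, "': ",
      sum(x$patterns$weight), " sites, ",
      nrow(x$patterns), " distinct patterns, max copies (",
      x$max_copies[1], ", ", x$max_copies[2], ")",
      if (x$constant_removed) ", variable-only" else "", "\n", sep = "")
  invisible(x)
}

#' An ordered collection of population-pair data sets
#'
#' @param ... `codiv_comparison` objects (or a single list of them).
#' @return A `codiv_collection` object.
#' @export
comparison_collection <- function(...) {
  comps <- list(...)
  if (length(comps) == 1 && !inherits(comps[[1]], "codiv_comparison")) {
    comps <- comps[[1]]
  }
  stopifnot(length(comps) >= 1,
            all(vapply(comps, inherits, TRUE, "codiv_comparison")))
  labels <- vapply(comps, `[[`, "", "label")
  if (anyDuplicated(labels)) stop("pair labels must be unique")
  names(comps) <- labels
  structure(comps, class = "codiv_collection")
}

#' @export
print.codiv_collection <- function(x, ...) {
  cat("<codiv_collection> of", length(x), "population pairs:\n")
  for (cd in x) print(cd)
  invisible(x)
}

#' @export
length.codiv_collection <- function(x) length(unclass(x))

#' Collapse a binary site matrix into allele-count patterns
#'
#' Site columns with identical allele counts `(n1, r1, n2, r2)` collapse
#' into one pattern with summed weight; the counts, not the identities of
#' the sampled copies, determine the pattern (gene copies are exchangeable
#' under the coalescent). Missing cells reduce the sampled count `n` at
#' that site. Sites with no sampled copies in either population cannot
#' contribute and are dropped with a warning.
#'
#' @param x Binary matrix (sequences in rows, sites in columns) with
#'   values 0, 1, or `NA` for missing cells.
#' @param populations Vector assigning each row to one of two populations.
#' @param label Pair label.
#' @param drop_constant Remove constant patterns (all red or all green
#'   across both populations) and flag the result as variable-only.
#' @param loci Optional locus structure passed through.
#' @return A `codiv_comparison`.
#' @export
aggregate_patterns <- function(x, populations, label = "pair",
                               drop_constant = FALSE, loci = NULL) {
  stopifnot(is.matrix(x), nrow(x) == length(populations))
  pops <- unique(populations)
  if (length(pops) != 2) stop("exactly two population labels required")
  in1 <- populations == pops[1]
  cnt <- function(rows) {
    n <- colSums(!is.na(x[rows, , drop = FALSE]))
    r <- colSums(x[rows, , drop = FALSE] == 1, na.rm = TRUE)
    list(n = as.integer(n), r = as.integer(r))
  }
  c1 <- cnt(in1); c2 <- cnt(!in1)
  keep <- c1$n + c2$n > 0
  if (any(!keep)) {
    warning(sum(!keep), " site(s) with no sampled copies dropped")
  }
  pat <- tibble(n1 = c1$n[keep], r1 = c1$r[keep],
                n2 = c2$n[keep], r2 = c2$r[keep])
  pat <- dplyr::count(pat, .data$n1, .data$r1, .data$n2, .data$r2,
                      name = "weight")
  pat$weight <- as.integer(pat$weight)
  if (drop_constant) pat <- pat[!is_constant_pattern(pat), , drop = FALSE]
  if (nrow(pat) == 0) stop("no usable sites remain")
  comparison_data(pat, label = label, loci = loci,
                  constant_removed = drop_constant)
}

#' Read or write an allele-count pattern table
#'
#' Pattern tables are tab-separated text files with columns
#' `n1 r1 n2 r2 weight`, one row per distinct pattern.
#'
#' @param path File path.
#' @return For `read_pattern_table`, a pattern tibble.
#' @export
read_pattern_table <- function(path) {
  tb <- as_tibble(read.table(path, header = TRUE, sep = "\t"))
  allele_patterns(tb$n1, tb$r1, tb$n2, tb$r2, tb$weight)
}

#' @rdname read_pattern_table
#' @param patterns Pattern tibble to write.
#' @export
write_pattern_table <- function(patterns, path) {
  validate_patterns(patterns)
  write.table(patterns, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
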