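MISSING_SYMBOLS <- c("-", "?", "n", "N", ".", "x", "X")
IUPAC_OK <- c("a", "c", "g", "t", "u", "r", "y", "s", "w", "k", "m",
              "b", "d", "h", "v", "0", "1")

#' Read an alignment with a population map
#'
#' Reads a NEXUS or FASTA alignment (binary or nucleotide characters) and
#' tags every sequence with its population. Gaps and ambiguity codes are
#' recorded as missing cells; at such sites the population simply
#' contributes fewer sampled gene copies.
#'
#' @param path Alignment file.
#' @param population_map Either a named character vector mapping sequence
#'   ids to population labels, a two-column data frame (sequence id,
#'   population), or the path of a two-column tab-separated file.
#' @param format `"nexus"` or `"fasta"` (default guessed from the file
#'   extension).
#' @return A character matrix (sequences in rows, sites in columns) with
#'   `NA` for missing cells and a `populations` attribute giving each
#'   row's population label.
#' @export
read_alignment <- function(path, population_map, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.(nex|nexus)$", path, ignore.case = TRUE)) {
      "nexus"
    } else {
      "fasta"
    }
  }
  format <- match.arg(format, c("nexus", "fasta"))
  seqs <- switch(format,
    nexus = ape::read.nexus.data(path),
    fasta = {
      dn <- ape::read.dna(path, format = "fasta", as.character = TRUE)
      lapply(seq_len(nrow(dn)), function(i) unname(dn[i, ])) |>
        setNames(rownames(dn))
    }
  )
  if (length(seqs) == 0) stop("empty alignment: ", path)
  map <- normalize_population_map(population_map)
  unknown <- setdiff(names(seqs), names(map))
  if (length(unknown) > 0) {
    stop("sequence id(s) missing from population map: ",
         paste(unknown, collapse = ", "))
  }
  pops <- unname(map[names(seqs)])
  if (length(unique(pops)) != 2) {
    stop("exactly two population labels required, got: ",
         paste(unique(pops), collapse = ", "))
  }
  m <- do.call(rbind, lapply(seqs, tolower))
  rownames(m) <- names(seqs)
  bad <- !(m %in% c(IUPAC_OK, MISSING_SYMBOLS))
  if (any(bad)) {
    stop("non-IUPAC symbol(s) in alignment: ",
         paste(unique(m[bad]), collapse = " "))
  }
  m[m %in% MISSING_SYMBOLS | !(m %in% c("a", "c", "g", "t", "u", "0", "1"))] <- NA
  attr(m, "populations") <- pops
  m
}

normalize_population_map <- function(population_map) {
  if (is.character(population_map) && length(population_map) == 1 &&
      file.exists(population_map)) {
    tb <- read.table(population_map, header = FALSE, sep = "\t",
                     col.names = c("id", "population"),
                     colClasses = "character")
    population_map <- tb
  }
  if (is.data.frame(population_map)) {
    map <- setNames(as.character(population_map[[2]]),
                    as.character(population_map[[1]]))
  } else {
    map <- population_map
  }
  if (is.null(names(map))) stop("population map must carry sequence ids")
  map
}

#' Recode nucleotide site columns as binary characters
#'
#' Under `"recode_first_as_green"` the first non-missing nucleotide
#' reading down each column becomes the green state (0) and every other
#' nucleotide becomes red (1). Under `"remove_polyallelic"`, columns with
#' more than two distinct nucleotides are removed instead; biallelic
#' columns are coded with the first nucleotide as green. Binary input
#' passes through unchanged (the recoding is idempotent).
#'
#' @param x A character matrix from [read_alignment()] (or a single site
#'   column).
#' @param policy `"recode_first_as_green"` or `"remove_polyallelic"`.
#' @return An integer matrix of 0/1/`NA` with the `populations` attribute
#'   preserved; removed columns are dropped and their count is reported in
#'   the `n_removed` attribute.
#' @export
recode_to_binary <- function(x, policy = c("recode_first_as_green",
                                           "remove_polyallelic")) {
  policy <- match.arg(policy)
  if (!is.matrix(x)) x <- matrix(x, ncol = 1)
  pops <- attr(x, "populations")
  out <- matrix(NA_integer_, nrow(x), ncol(x))
  removed <- logical(ncol(x))
  for (j in seq_len(ncol(x))) {
    col <- x[, j]
    col[col %in% MISSING_SYMBOLS] <- NA
    obs <- col[!is.na(col)]
    if (length(obs) == 0) next
    states <- unique(obs)
    if (all(states %in% c("0", "1"))) {
      out[, j] <- as.integer(col)
      next
    }
    if (length(states) > 2 && policy == "remove_polyallelic") {
      removed[j] <- TRUE
      next
    }
    out[, j] <- ifelse(col == obs[1], 0L, 1L)
  }
  out <- out[, !removed, drop = FALSE]
  rownames(out) <- rownames(x)
  attr(out, "populations") <- pops
  attr(out, "n_removed") <- sum(removed)
  out
}

#' Read an alignment straight into a pattern table
#'
#' Convenience wrapper: [read_alignment()], [recode_to_binary()] and
#' [aggregate_patterns()] in one step.
#'
#' @inheritParams read_alignment
#' @inheritParams recode_to_binary
#' @inheritParams aggregate_patterns
#' @return A `codiv_comparison`.
#' @export
read_comparison <- function(path, population_map, label = "pair",
                            format = NULL,
                            policy = "recode_first_as_green",
                            drop_constant = FALSE) {
  aln <- read_alignment(path, population_map, format)
  bin <- recode_to_binary(aln, policy)
  cd <- aggregate_patterns(bin, attr(bin, "populations"), label = label,
                           drop_constant = drop_constant)
  cd$polyallelic_policy <-
    if (policy == "remove_polyallelic") "remove" else "recode"
  cd
}
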