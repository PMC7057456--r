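#' Discretize a log2 test-over-control expression ratio
#'
#' Maps a continuous log2 ratio onto the three-state expression alphabet the
#' scoring model consumes: `+1` (up-regulated) when the ratio is positive,
#' `-1` (down-regulated) when negative, and `NA` (missing) when the ratio is
#' exactly zero or itself missing. A zero log ratio carries no direction, so
#' it falls into the missing state together with absent measurements.
#'
#' @param x numeric vector of log2 ratios (may contain `NA`).
#' @return Integer vector in `{+1L, -1L, NA}` of the same length.
#' @examples
#' discretize_log_ratio(c(1.5, -0.7, 0, NA))
#' @export
discretize_log_ratio <- function(x) {
  if (!is.numeric(x)) stop("log ratios must be numeric", call. = FALSE)
  out <- rep(NA_integer_, length(x))
  out[!is.na(x) & x > 0] <- 1L
  out[!is.na(x) & x < 0] <- -1L
  out
}

#' Construct a single-sample observation
#'
#' Bundles the per-gene expression states `r` (`+1`, `-1`, `NA` = missing)
#' and mutation states `m` (`+1` = function gain, `-1` = function loss,
#' `NA` = no mutation evidence) for one sample. Gene ids are upper-cased to
#' match pathway graphs.
#'
#' @param sample_id sample identifier.
#' @param r named integer vector of expression states.
#' @param m named integer vector of mutation states; genes absent from `m`
#'   have no mutation evidence.
#' @return An object of class `sample_observation`.
#' @export
sample_observation <- function(sample_id, r, m = integer()) {
  r <- check_state_vector(r, "expression")
  m <- check_state_vector(m, "mutation")
  structure(list(sample_id = as.character(sample_id), r = r, m = m),
            class = "sample_observation")
}

check_state_vector <- function(x, what) {
  if (length(x) == 0L) return(stats::setNames(integer(), character()))
  if (is.null(names(x)) || any(!nzchar(names(x)))) {
    stop(sprintf("%s states must be named by gene id", what), call. = FALSE)
  }
  v <- as.integer(x)
  if (any(!is.na(v) & !v %in% c(1L, -1L))) {
    stop(sprintf("%s states must be +1, -1 or NA", what), call. = FALSE)
  }
  stats::setNames(v, toupper(names(x)))
}

#' @export
print.sample_observation <- function(x, ...) {
  cat(sprintf("<sample_observation> %s: %d genes (%d up, %d down, %d missing), %d mutation state(s)\n",
              x$sample_id, length(x$r),
              sum(x$r == 1L, na.rm = TRUE), sum(x$r == -1L, na.rm = TRUE),
              sum(is.na(x$r)), sum(!is.na(x$m))))
  invisible(x)
}

#' Construct an observation set
#'
#' An ordered collection of [sample_observation()] objects over a common
#' gene universe.
#'
#' @param samples list of [sample_observation()] objects with unique ids.
#' @param gene_universe optional character vector; defaults to the union of
#'   genes seen in the samples.
#' @return An object of class `observation_set` with fields `samples`
#'   (named list) and `genes`.
#' @export
observation_set <- function(samples, gene_universe = NULL) {
  stopifnot(is.list(samples),
            all(vapply(samples, inherits, logical(1), "sample_observation")))
  ids <- vapply(samples, `[[`, character(1), "sample_id")
  if (anyDuplicated(ids)) stop("sample ids must be unique", call. = FALSE)
  seen <- unique(unlist(lapply(samples, function(s) c(names(s$r),
                                                      names(s$m)))))
  genes <- if (is.null(gene_universe)) seen else
    union(toupper(gene_universe), seen)
  structure(list(samples = stats::setNames(samples, ids),
                 genes = sort(genes)),
            class = "observation_set")
}

#' @export
print.observation_set <- function(x, ...) {
  cat(sprintf("<observation_set> %d sample(s) x %d gene(s)\n",
              length(x$samples), length(x$genes)))
  invisible(x)
}

#' Load a gene-by-sample expression table
#'
#' Reads a TSV whose first column holds gene ids and remaining columns hold
#' one sample each. In `log_ratio` mode cells are continuous log2
#' test-over-control ratios passed through [discretize_log_ratio()]; in
#' `discrete` mode cells must already be `+1`, `-1` or `NA`.
#'
#' @param path file path.
#' @param mode `"log_ratio"` or `"discrete"`.
#' @return An [observation_set()] (no mutation evidence; see
#'   [load_mutation_table()]).
#' @export
load_expression_table <- function(path, mode = c("log_ratio", "discrete")) {
  mode <- match.arg(mode)
  tab <- read_matrix_tsv(path)
  if (ncol(tab$values) == 0L) {
    stop(sprintf("%s: no sample columns", path), call. = FALSE)
  }
  samples <- lapply(seq_len(ncol(tab$values)), function(j) {
    col <- tab$values[, j]
    states <- if (mode == "log_ratio") {
      num <- suppressWarnings(as.numeric(col))
      bad <- which(!is.na(col) & is.na(num) & toupper(col) != "NA")
      if (length(bad)) {
        stop(sprintf("%s: non-numeric value '%s' for gene %s, sample %s",
                     path, col[bad[1L]], tab$genes[bad[1L]],
                     colnames(tab$values)[j]), call. = FALSE)
      }
      discretize_log_ratio(num)
    } else {
      parse_discrete_states(col, tab$genes, colnames(tab$values)[j], path)
    }
    sample_observation(colnames(tab$values)[j],
                       stats::setNames(states, tab$genes))
  })
  observation_set(samples, gene_universe = tab$genes)
}

parse_discrete_states <- function(col, genes, sample, path) {
  tok <- toupper(trimws(col))
  out <- rep(NA_integer_, length(tok))
  out[tok %in% c("+1", "1")] <- 1L
  out[tok == "-1"] <- -1L
  bad <- which(!is.na(col) & is.na(out) & !tok %in% c("NA", ""))
  if (length(bad)) {
    stop(sprintf("%s: value '%s' outside {+1,-1,NA} for gene %s, sample %s",
                 path, col[bad[1L]], genes[bad[1L]], sample), call. = FALSE)
  }
  out
}

read_matrix_tsv <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                           colClasses = "character", check.names = FALSE,
                           comment.char = "#")
  if (ncol(tab) < 1L) stop(sprintf("%s: empty table", path), call. = FALSE)
  genes <- toupper(trimws(tab[[1L]]))
  if (anyDuplicated(genes)) {
    stop(sprintf("%s: duplicate gene row '%s'", path,
                 genes[duplicated(genes)][1L]), call. = FALSE)
  }
  values <- as.matrix(tab[, -1L, drop = FALSE])
  list(genes = genes, values = values)
}

#' Load a gene-by-sample mutation table
#'
#' Entries must be `+1` (function gain), `-1` (function loss) or `NA`
#' (no mutation). Genes absent from the table have no mutation evidence.
#' A table with a single value column is treated as applying uniformly to
#' every sample (the common case of a known constitutive mutation such as a
#' TP53 loss shared by all test samples). An empty table (header only, or
#' zero rows) yields no mutation evidence at all.
#'
#' @param path file path.
#' @return A named list of mutation-state vectors, one per sample column,
#'   with attribute `uniform = TRUE` when a single column applies to all
#'   samples.
#' @export
load_mutation_table <- function(path) {
  tab <- read_matrix_tsv(path)
  if (nrow(tab$values) == 0L || ncol(tab$values) == 0L) {
    out <- list()
    attr(out, "uniform") <- TRUE
    return(out)
  }
  cols <- lapply(seq_len(ncol(tab$values)), function(j) {
    states <- parse_discrete_states(tab$values[, j], tab$genes,
                                    colnames(tab$values)[j], path)
    v <- stats::setNames(states, tab$genes)
    v[!is.na(v)]
  })
  out <- stats::setNames(cols, colnames(tab$values))
  attr(out, "uniform") <- ncol(tab$values) == 1L
  out
}

#' Attach mutation evidence to an observation set
#'
#' @param obs_set an [observation_set()].
#' @param mutations result of [load_mutation_table()], or a single named
#'   mutation vector applied to every sample.
#' @return The observation set with per-sample `m` filled in.
#' @export
set_mutations <- function(obs_set, mutations) {
  stopifnot(inherits(obs_set, "observation_set"))
  if (!is.list(mutations)) {
    mutations <- stats::setNames(
      rep(list(check_state_vector(mutations, "mutation")),
          length(obs_set$samples)),
      names(obs_set$samples))
  } else if (isTRUE(attr(mutations, "uniform")) && length(mutations) == 1L) {
    mutations <- stats::setNames(rep(mutations[1L],
                                     length(obs_set$samples)),
                                 names(obs_set$samples))
  }
  for (id in names(obs_set$samples)) {
    m <- mutations[[id]]
    if (!is.null(m)) {
      obs_set$samples[[id]]$m <- check_state_vector(m, "mutation")
    }
  }
  obs_set$genes <- sort(union(obs_set$genes,
                              unlist(lapply(mutations, names))))
  obs_set
}

#' Write an observation set as a discrete expression TSV
#'
#' Round-trip companion of `load_expression_table(mode = "discrete")`.
#'
#' @param obs_set an [observation_set()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(obs_set, path) {
  stopifnot(inherits(obs_set, "observation_set"))
  genes <- obs_set$genes
  mat <- vapply(obs_set$samples, function(s) {
    v <- s$r[genes]
    ifelse(is.na(v), "NA", ifelse(v == 1L, "+1", "-1"))
  }, character(length(genes)))
  mat <- matrix(mat, nrow = length(genes),
                dimnames = list(NULL, names(obs_set$samples)))
  out <- data.frame(gene = genes, mat, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
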