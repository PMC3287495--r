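#' Discretize a time-series expression table
#'
#' Converts continuous expression values to per-gene discrete levels for
#' multinomial dynamic-Bayesian-network learning. Thresholds are computed per
#' gene over that gene's values pooled across all time points and replicates;
#' a value's level is the number of thresholds strictly below it, so values
#' equal to a threshold fall in the lower bin. Each replicate becomes one
#' complete observation sequence.
#'
#' @param data Long expression tibble (`gene`, `time`, `replicate`, `value`).
#' @param n_levels Number of discrete levels per gene (default 3:
#'   low/medium/high).
#' @param method `"quantile"` (equal-frequency bins; the default) or
#'   `"interval"` (equal-width bins over the gene's observed range).
#' @return A [dbn_data] object: one integer sequence per replicate, with
#'   `n_seq` equal to the replicate count and `n` (total transitions) equal
#'   to `n_seq * (timepoints - 1)`.
#' @examples
#' expr <- tidyr::expand_grid(gene = "g1", time = 0:5, replicate = 1L) |>
#'   dplyr::mutate(value = dplyr::row_number())
#' discretize(expr, n_levels = 3)
#' @export
discretize <- function(data, n_levels = 3L, method = c("quantile", "interval")) {
  method <- match.arg(method)
  data <- validate_expression(data)
  if (n_levels < 2L) stop("n_levels must be at least 2", call. = FALSE)
  genes <- expression_genes(data)
  times <- sort(unique(data$time))
  reps <- sort(unique(data$replicate))
  if (length(times) < 2L)
    stop("need at least two time points to form transitions", call. = FALSE)

  thresholds <- lapply(genes, function(g) {
    x <- data$value[data$gene == g]
    if (method == "quantile") {
      if (length(unique(x)) < n_levels)
        stop(sprintf(paste0("gene '%s' has fewer than %d distinct values; quantile ",
                            "binning is degenerate. Use method = \"interval\" or fewer levels."),
                     g, n_levels), call. = FALSE)
      stats::quantile(x, probs = seq_len(n_levels - 1L) / n_levels, names = FALSE, type = 7)
    } else {
      lo <- min(x); hi <- max(x)
      lo + (hi - lo) * seq_len(n_levels - 1L) / n_levels
    }
  })
  names(thresholds) <- genes

  # level = number of thresholds strictly below the value
  lev <- data
  lev$level <- NA_integer_
  for (g in genes) {
    idx <- lev$gene == g
    th <- thresholds[[g]]
    lev$level[idx] <- vapply(lev$value[idx], function(v) sum(v > th), integer(1))
  }

  sequences <- lapply(reps, function(r) {
    sub <- lev[lev$replicate == r, c("gene", "time", "level")]
    wide <- tidyr::pivot_wider(sub, names_from = "gene", values_from = "level")
    wide <- wide[order(wide$time), , drop = FALSE]
    m <- as.matrix(wide[, genes, drop = FALSE])
    storage.mode(m) <- "integer"
    rownames(m) <- NULL
    m
  })
  arities <- stats::setNames(rep.int(as.integer(n_levels), length(genes)), genes)
  dbn_data(sequences, arities = arities)
}

#' Discrete multi-sequence dataset
#'
#' Container for complete discrete observation sequences over a common gene
#' set: `sequences` is a list of integer matrices (rows = time slices,
#' columns = genes, values in `[0, arity)`); `arities` gives each gene's
#' number of levels. `n_seq` is the number of sequences and `n` the total
#' number of slice-to-slice transitions pooled across sequences, the two
#' sample sizes that weight the initial-network and transition-network parts
#' of the BIC score.
#'
#' @param sequences List of integer matrices with identical column names.
#' @param arities Named integer vector of per-gene level counts (>= 2).
#' @return An object of class `dbn_data`.
#' @export
dbn_data <- function(sequences, arities) {
  stopifnot(is.list(sequences), length(sequences) >= 1L)
  genes <- colnames(sequences[[1]])
  if (is.null(genes)) stop("sequence matrices must have gene column names", call. = FALSE)
  if (is.null(names(arities)) || !setequal(names(arities), genes))
    stop("arities must be named by the same genes as the sequences", call. = FALSE)
  arities <- as.integer(arities[genes])
  names(arities) <- genes
  if (any(arities < 2L)) stop("all arities must be >= 2", call. = FALSE)
  for (i in seq_along(sequences)) {
    m <- sequences[[i]]
    if (!is.matrix(m) || !identical(colnames(m), genes))
      stop("sequence ", i, " has mismatched gene columns", call. = FALSE)
    if (nrow(m) < 2L)
      stop("sequence ", i, " has fewer than 2 slices (no transitions)", call. = FALSE)
    storage.mode(m) <- "integer"
    if (anyNA(m) || any(m < 0L) || any(m >= rep(arities, each = nrow(m))))
      stop("sequence ", i, " has levels outside [0, arity)", call. = FALSE)
    sequences[[i]] <- m
  }
  structure(
    list(genes = genes, arities = arities, sequences = sequences,
         n_seq = length(sequences),
         n = sum(vapply(sequences, nrow, integer(1)) - 1L)),
    class = "dbn_data")
}

#' @export
print.dbn_data <- function(x, ...) {
  cat(sprintf("<dbn_data> %d genes, %d sequence(s), %d pooled transitions\n",
              length(x$genes), x$n_seq, x$n))
  cat("  arities:", paste0(x$genes, "=", x$arities, collapse = ", "), "\n")
  invisible(x)
}

#' Tidy a discrete dataset into long form
#'
#' @param x A [dbn_data] object.
#' @param ... Unused.
#' @return Tibble with columns `sequence`, `time`, `gene`, `level`.
#' @exportS3Method generics::tidy
tidy.dbn_data <- function(x, ...) {
  purrr::map2_dfr(x$sequences, seq_along(x$sequences), function(m, s) {
    tibble::tibble(sequence = s,
                   time = rep(seq_len(nrow(m)) - 1L, times = ncol(m)),
                   gene = rep(colnames(m), each = nrow(m)),
                   level = as.integer(m))
  })
}

#' @exportS3Method generics::glance
glance.dbn_data <- function(x, ...) {
  tibble::tibble(n_genes = length(x$genes), n_seq = x$n_seq, n = x$n,
                 max_arity = max(x$arities))
}

#' Write / read a discrete dataset as TSV plus sidecar metadata
#'
#' The levels file is tab-separated with columns `sequence`, `time` and one
#' integer column per gene; the sidecar (same path + `.meta`) records arities
#' and sequence boundaries as flat `key=value` lines.
#'
#' @param x A [dbn_data] object.
#' @param path Levels file path.
#' @return `path` invisibly (write) or a [dbn_data] (read).
#' @export
write_dbn_data <- function(x, path) {
  long <- tidy.dbn_data(x)
  wide <- tidyr::pivot_wider(long, names_from = "gene", values_from = "level")
  readr::write_tsv(wide, path, progress = FALSE)
  meta <- c(sprintf("genes=%s", paste(x$genes, collapse = ",")),
            sprintf("arities=%s", paste(x$arities, collapse = ",")),
            sprintf("lengths=%s",
                    paste(vapply(x$sequences, nrow, integer(1)), collapse = ",")))
  writeLines(meta, paste0(path, ".meta"))
  invisible(path)
}

#' @rdname write_dbn_data
#' @export
read_dbn_data <- function(path) {
  meta <- readLines(paste0(path, ".meta"))
  get_field <- function(key) {
    line <- grep(paste0("^", key, "="), meta, value = TRUE)
    if (length(line) != 1L) stop("malformed sidecar: missing ", key, call. = FALSE)
    strsplit(sub("^[^=]*=", "", line), ",", fixed = TRUE)[[1]]
  }
  genes <- get_field("genes")
  arities <- stats::setNames(as.integer(get_field("arities")), genes)
  wide <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_integer()),
                          progress = FALSE)
  sequences <- lapply(split(wide, wide$sequence), function(d) {
    d <- d[order(d$time), , drop = FALSE]
    m <- as.matrix(d[, genes, drop = FALSE])
    storage.mode(m) <- "integer"
    m
  })
  dbn_data(unname(sequences), arities)
}
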