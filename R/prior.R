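#' Initial up-regulation time of each gene
#'
#' Operationalizes "initial up-regulation" as the first time point at which a
#' gene's replicate-mean expression reaches a fold-change over its time-0
#' replicate mean: the smallest t >= 1 with `mean_t >= fold_threshold *
#' mean_0` (boundary inclusive). Genes that never cross get `NA`.
#'
#' @param data Long expression tibble (`gene`, `time`, `replicate`, `value`).
#' @param fold_threshold Fold-change over baseline (> 1, default 1.5).
#' @param genes Genes to evaluate; default all.
#' @return Tibble with columns `gene` and `up_time` (0-based integer or
#'   `NA`).
#' @export
initial_upregulation_time <- function(data, fold_threshold = 1.5, genes = NULL) {
  if (fold_threshold <= 1) stop("fold_threshold must be > 1", call. = FALSE)
  data <- validate_expression(data)
  if (is.null(genes)) genes <- expression_genes(data)
  means <- data |>
    dplyr::filter(.data$gene %in% genes) |>
    dplyr::group_by(.data$gene, .data$time) |>
    dplyr::summarise(mean_value = mean(.data$value), .groups = "drop")
  up <- unname(vapply(genes, function(g) {
    m <- means[means$gene == g, ]
    m <- m[order(m$time), ]
    base <- m$mean_value[m$time == min(m$time)]
    if (base <= 0)
      stop(sprintf(paste0("gene '%s' has non-positive baseline mean (%g); fold-change ",
                          "semantics undefined. Shift the data or use an additive rule."),
                   g, base), call. = FALSE)
    later <- m[m$time > min(m$time), ]
    hit <- which(later$mean_value >= fold_threshold * base)
    if (length(hit) == 0L) NA_integer_ else as.integer(later$time[hit[1]])
  }, integer(1)))
  tibble::tibble(gene = genes, up_time = up)
}

#' Candidate-regulator prior network from up-regulation timing
#'
#' Builds the preprocessed candidate network used to narrow the structure
#' search: a directed edge u -> v for every ordered gene pair whose initial
#' up-regulation times satisfy `time(u) < time(v)` (the earlier-responding
#' gene is the potential regulator of the later one). Ties produce no edge
#' in either direction, and genes that never up-regulate get no edges at
#' all. The result is necessarily a DAG. The fraction of the complete
#' self-loop-free digraph that the prior rules out is attached as attribute
#' `removed_fraction` and reported via `message()`.
#'
#' @inheritParams initial_upregulation_time
#' @return A [gene_network] over all genes with attribute
#'   `removed_fraction`.
#' @export
build_prior_network <- function(data, fold_threshold = 1.5) {
  times <- initial_upregulation_time(data, fold_threshold = fold_threshold)
  genes <- times$gene
  ok <- !is.na(times$up_time)
  pairs <- tidyr::expand_grid(regulator = genes[ok], target = genes[ok]) |>
    dplyr::filter(.data$regulator != .data$target) |>
    dplyr::left_join(stats::setNames(times, c("regulator", "reg_time")), by = "regulator") |>
    dplyr::left_join(stats::setNames(times, c("target", "tgt_time")), by = "target") |>
    dplyr::filter(.data$reg_time < .data$tgt_time)
  net <- gene_network(pairs[, c("regulator", "target")], nodes = genes)
  n <- length(genes)
  total <- n * (n - 1)
  removed <- if (total > 0) 1 - nrow(net) / total else 0
  attr(net, "removed_fraction") <- removed
  message(sprintf("prior network: %d of %d possible edges kept (%.1f%% removed)",
                  nrow(net), total, 100 * removed))
  net
}
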