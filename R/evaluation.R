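#' Convert a transition network to a gene regulatory network
#'
#' Projects the learned two-slice structure onto gene space: a `"prev"` edge
#' X[t] -> Y[t+1] becomes the GRN edge X -> Y, and (by default) a `"same"`
#' edge likewise — two genes related across or within the t/t+1 block are
#' reported as regulator and target. Self-persistence edges are dropped,
#' duplicate pairs merged, and initial-network edges are never included.
#'
#' @param structure A [dbn_structure].
#' @param include_same Map same-slice transition edges too (default `TRUE`).
#' @return A [gene_network] over the structure's genes.
#' @export
transition_to_grn <- function(structure, include_same = TRUE) {
  ed <- structure$trans
  if (!include_same) ed <- ed[ed$lag == "prev", ]
  ed <- ed[ed$parent != ed$child, c("parent", "child")]
  gene_network(tibble::tibble(regulator = ed$parent, target = ed$child),
               nodes = structure$genes)
}

#' Directed-edge confusion counts
#'
#' Exact set arithmetic on directed edge sets: `ce` true positives (edges in
#' both networks), `me` false negatives (in truth only), `fe` false
#' positives (predicted only). Direction matters: A -> B does not match
#' B -> A.
#'
#' @param truth,predicted [gene_network] objects (or edge tibbles with
#'   `regulator`/`target` columns).
#' @return One-row tibble with columns `ce`, `me`, `fe`.
#' @export
edge_confusion <- function(truth, predicted) {
  tk <- edge_keys(truth)
  pk <- edge_keys(predicted)
  tibble::tibble(ce = sum(pk %in% tk),
                 me = sum(!tk %in% pk),
                 fe = sum(!pk %in% tk))
}

#' Precision and recall from confusion counts
#'
#' Precision `P = ce / (ce + fe)` and recall `R = ce / (ce + me)`; each is
#' defined as 0 when its denominator is 0.
#'
#' @param confusion Data frame with columns `ce`, `me`, `fe` (one or more
#'   rows).
#' @return The input with `precision` and `recall` columns appended.
#' @export
precision_recall <- function(confusion) {
  confusion |>
    tibble::as_tibble() |>
    dplyr::mutate(
      precision = ifelse(.data$ce + .data$fe > 0, .data$ce / (.data$ce + .data$fe), 0),
      recall = ifelse(.data$ce + .data$me > 0, .data$ce / (.data$ce + .data$me), 0))
}

#' Evaluate a predicted network against a truth network
#'
#' Convenience wrapper combining [edge_confusion()] and
#' [precision_recall()].
#'
#' @inheritParams edge_confusion
#' @return One-row tibble: `ce`, `me`, `fe`, `precision`, `recall`.
#' @export
evaluate_network <- function(truth, predicted) {
  precision_recall(edge_confusion(truth, predicted))
}

#' Precision of a uniform random edge guess
#'
#' The precision a uniformly random directed-edge guess (no self-loops)
#' attains against the truth network: `|true edges| / (n * (n - 1))`. Useful
#' as the floor a timing-based prior degrades to on large networks.
#'
#' @param truth A [gene_network].
#' @return A number in `[0, 1]`.
#' @export
random_guess_precision <- function(truth) {
  n <- length(network_nodes(truth))
  if (n < 2) return(0)
  nrow(truth) / (n * (n - 1))
}

#' Round half-up to two decimals for reporting
#'
#' Table-style reporting convention (0.294 prints as 0.29, 0.295 as 0.30);
#' full precision is kept everywhere else.
#'
#' @param x Numeric vector.
#' @return `x` rounded half-up to 2 decimal places.
#' @export
report_round <- function(x) floor(x * 100 + 0.5) / 100
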