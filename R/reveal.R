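#' Plug-in entropy of discrete variables over pooled transitions
#'
#' Computes the empirical (plug-in) joint entropy, in nats, of one or more
#' tagged variables read across every pooled t -> t+1 transition of the
#' dataset: tag `"prev"` reads a gene at slice t, `"same"` at slice t+1.
#'
#' @param data A [dbn_data] object.
#' @param genes Tagged gene set: data frame with columns `gene` and `lag`,
#'   or character vector with lag names (unnamed entries default to
#'   `"prev"`), as in [count_transition()].
#' @return Entropy in nats (>= 0).
#' @export
empirical_entropy <- function(data, genes) {
  spec <- tagged_parents(genes)
  if (nrow(spec) == 0L) stop("genes must be nonempty", call. = FALSE)
  check_family_genes(data, spec$gene[1], spec$gene[-1])
  obs <- purrr::map2(spec$gene, spec$lag, function(g, lag) {
    unlist(lapply(data$sequences, function(m) {
      if (lag == "prev") m[-nrow(m), g] else m[-1L, g]
    }), use.names = FALSE)
  })
  cfg <- rep(0L, length(obs[[1]]))
  radix <- 1L
  for (i in seq_along(obs)) {
    cfg <- cfg + obs[[i]] * radix
    radix <- radix * data$arities[[spec$gene[i]]]
  }
  p <- tabulate(cfg + 1L, nbins = radix)
  p <- p[p > 0] / length(cfg)
  -sum(p * log(p))
}

#' @keywords internal
pooled_slices <- function(data) {
  list(prev = do.call(rbind, lapply(data$sequences, function(m) m[-nrow(m), , drop = FALSE])),
       nxt = do.call(rbind, lapply(data$sequences, function(m) m[-1L, , drop = FALSE])))
}

# entropy of the joint distribution of pre-extracted integer columns
#' @keywords internal
entropy_cols <- function(cols, arities) {
  cfg <- rep(0L, length(cols[[1]]))
  radix <- 1
  for (i in seq_along(cols)) {
    cfg <- cfg + cols[[i]] * radix
    radix <- radix * arities[i]
  }
  p <- tabulate(cfg + 1L, nbins = radix)
  p <- p[p > 0] / length(cfg)
  -sum(p * log(p))
}

#' @keywords internal
transition_mi <- function(data, child, parents) {
  # MI between the child at slice t+1 and prev-slice parents, in nats
  h_child <- empirical_entropy(data, tibble::tibble(gene = child, lag = "same"))
  h_par <- empirical_entropy(data, tibble::tibble(gene = parents,
                                                  lag = rep("prev", length(parents))))
  h_joint <- empirical_entropy(
    data, tibble::tibble(gene = c(child, parents),
                         lag = c("same", rep("prev", length(parents)))))
  list(mi = h_child + h_par - h_joint, child_entropy = h_child)
}

#' REVEAL parent-set search for one gene
#'
#' Scans the lattice of prev-slice parent sets by increasing size,
#' evaluating for each set the ratio of the mutual information between the
#' set (at slice t) and the child (at slice t+1) to the child's entropy. The
#' first set whose ratio reaches 1 (within a floating-point tolerance) is
#' returned — for a noise-free deterministic rule the true inputs attain
#' exactly 1. If no set reaches the threshold by `max_parents`, the
#' best-ratio set found is returned and flagged sub-threshold. A constant
#' child (zero entropy) returns an empty set with ratio defined as 1. Ties
#' are broken lexicographically by sorted parent names.
#'
#' @param data A [dbn_data] object.
#' @param child Child gene.
#' @param max_parents Largest parent-set size scanned (>= 1, default 3).
#' @param candidate_filter Optional [gene_network] restricting candidate
#'   (parent, child) pairs; the child itself is always a candidate
#'   (persistence).
#' @param tol Ratio slack below 1 at which a set counts as deterministic.
#' @return An `mi_result`: fields `child`, `parents`, `mi`, `child_entropy`,
#'   `ratio`, `threshold_met`.
#' @export
reveal_parents <- function(data, child, max_parents = 3L, candidate_filter = NULL,
                           tol = 1e-9) {
  if (max_parents < 1L) stop("max_parents must be >= 1", call. = FALSE)
  check_family_genes(data, child, character())
  allowed <- filter_fun(candidate_filter, data$genes)
  pool <- data$genes[allowed(data$genes, child) | data$genes == child]
  if (length(pool) == 0L)
    stop("no candidate parents available for '", child, "' under the filter",
         call. = FALSE)
  pool <- sort(pool)

  slices <- pooled_slices(data)
  child_col <- slices$nxt[, child]
  h_child <- entropy_cols(list(child_col), data$arities[[child]])
  if (h_child == 0) {
    return(mi_result(child, character(), mi = 0, child_entropy = 0, ratio = 1,
                     threshold_met = TRUE))
  }
  best <- NULL
  for (k in seq_len(min(max_parents, length(pool)))) {
    for (idx in utils::combn(length(pool), k, simplify = FALSE)) {
      pa <- pool[idx]  # pool sorted, so combn order is lexicographic
      pa_cols <- lapply(pa, function(p) slices$prev[, p])
      ar <- unname(data$arities[pa])
      r <- list(mi = entropy_cols(pa_cols, ar) + h_child -
                  entropy_cols(c(pa_cols, list(child_col)),
                               c(ar, data$arities[[child]])))
      ratio <- r$mi / h_child
      if (is.null(best) || ratio > best$ratio + 1e-15)
        best <- list(parents = pa, mi = r$mi, ratio = ratio)
      if (ratio >= 1 - tol) {
        return(mi_result(child, pa, mi = r$mi, child_entropy = h_child,
                         ratio = ratio, threshold_met = TRUE))
      }
    }
  }
  mi_result(child, best$parents, mi = best$mi, child_entropy = h_child,
            ratio = best$ratio, threshold_met = FALSE)
}

#' @keywords internal
mi_result <- function(child, parents, mi, child_entropy, ratio, threshold_met) {
  structure(list(child = child, parents = parents, mi = mi,
                 child_entropy = child_entropy, ratio = ratio,
                 threshold_met = threshold_met),
            class = "mi_result")
}

#' @export
print.mi_result <- function(x, ...) {
  cat(sprintf("<mi_result> %s <- {%s} | MI %.4f / H %.4f = ratio %.4f%s\n",
              x$child, paste(x$parents, collapse = ", "), x$mi, x$child_entropy,
              x$ratio, if (x$threshold_met) "" else " (sub-threshold)"))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.mi_result <- function(x, ...) {
  tibble::tibble(child = x$child,
                 parents = paste(x$parents, collapse = ","),
                 mi = x$mi, child_entropy = x$child_entropy, ratio = x$ratio,
                 threshold_met = x$threshold_met)
}

#' REVEAL network inference
#'
#' Runs [reveal_parents()] independently for every gene and assembles the
#' resulting prev-slice parent sets into a transition network (the initial
#' network is left empty; REVEAL models inter-slice relations only).
#' Children whose best set stayed below the determinism threshold are listed
#' in the structure metadata under `sub_threshold`.
#'
#' By default only parent sets that actually reached the determinism
#' threshold enter the network (`subthreshold = "drop"`): that is the
#' published REVEAL acceptance rule, and it is what makes REVEAL sparse and
#' conservative on noisy data. `subthreshold = "keep"` instead retains each
#' child's best sub-threshold set (flagged in the metadata), which
#' guarantees a nonempty answer at the cost of many weakly supported edges.
#'
#' @inheritParams reveal_parents
#' @param subthreshold `"drop"` (default) or `"keep"`: what to do with
#'   children whose best candidate set stays below the ratio threshold.
#' @return A [dbn_structure] with metadata fields `method = "reveal"`,
#'   `ratios` (a tibble of per-child results) and `sub_threshold`.
#' @export
reveal_network <- function(data, max_parents = 3L, candidate_filter = NULL,
                           tol = 1e-9, subthreshold = c("drop", "keep")) {
  subthreshold <- match.arg(subthreshold)
  results <- lapply(data$genes, function(g)
    reveal_parents(data, g, max_parents = max_parents,
                   candidate_filter = candidate_filter, tol = tol))
  trans <- dplyr::bind_rows(lapply(results, function(r) {
    if (length(r$parents) == 0L) return(NULL)
    if (!r$threshold_met && subthreshold == "drop") return(NULL)
    tibble::tibble(parent = r$parents, lag = "prev", child = r$child)
  }))
  dbn_structure(
    genes = data$genes, trans = trans,
    metadata = list(method = "reveal", max_parents = max_parents,
                    filtered = !is.null(candidate_filter),
                    subthreshold = subthreshold,
                    ratios = dplyr::bind_rows(lapply(results, tidy.mi_result)),
                    sub_threshold = vapply(results, function(r) r$child,
                                           character(1))[!vapply(results,
                                                                 function(r) r$threshold_met,
                                                                 logical(1))]))
}
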