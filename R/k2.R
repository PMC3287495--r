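#' Modified K2 greedy structure search for a two-slice DBN
#'
#' Learns the initial network and the stationary transition network by the
#' K2 strategy: each gene starts with no parents and single parents are added
#' greedily, keeping the addition that most increases the family's penalized
#' BIC score, until no single addition increases it (strictly) or
#' `max_parents` is reached. The two components are learned independently.
#'
#' Admissible parents follow the K2 node ordering: initial-network and
#' same-slice transition parents must come earlier in `order` (which
#' guarantees acyclicity), while `"prev"`-slice transition parents are
#' unrestricted — a cross-slice edge can never create a cycle — and include
#' the child itself (the standard persistence edge, dropped again when the
#' structure is converted to a gene regulatory network).
#'
#' @param data A [dbn_data] object.
#' @param order Character permutation of `data$genes` giving the K2 node
#'   ordering; defaults to the input gene order.
#' @param max_parents Maximum parents per family (default 3).
#' @param candidate_filter Optional [gene_network]: only its
#'   (regulator, target) pairs are admissible as (parent, child) pairs, in
#'   all three edge classes; the self-persistence `"prev"` edge is always
#'   admissible.
#' @return A [dbn_structure] whose `metadata` records the method, options
#'   and the per-family trace of accepted scores (monotone increasing).
#' @export
k2_dbn <- function(data, order = NULL, max_parents = 3L, candidate_filter = NULL) {
  order <- check_order(data, order)
  if (max_parents < 0L) stop("max_parents must be >= 0", call. = FALSE)
  allowed <- filter_fun(candidate_filter, data$genes)
  cache <- new.env(parent = emptyenv())

  score_b0 <- function(child, parents)
    cached_score(cache, data, child,
                 tibble::tibble(gene = parents, lag = rep("initial", length(parents))),
                 kind = "initial")
  score_tr <- function(child, parents)  # parents: tibble(gene, lag)
    cached_score(cache, data, child, parents, kind = "transition")

  b0_edges <- list(); tr_edges <- list(); trace <- list()
  for (pos in seq_along(order)) {
    child <- order[pos]
    earlier <- if (pos > 1L) order[seq_len(pos - 1L)] else character()

    # -- initial-network family
    pool <- earlier[allowed(earlier, child)]
    res <- greedy_family(
      pool = tibble::tibble(gene = pool, lag = rep("initial", length(pool))),
      score = function(pa) score_b0(child, pa$gene),
      max_parents = max_parents)
    if (nrow(res$parents) > 0)
      b0_edges[[child]] <- tibble::tibble(parent = res$parents$gene, child = child)

    # -- transition family: all genes as prev parents, earlier genes as same
    prev_pool <- data$genes[allowed(data$genes, child) | data$genes == child]
    same_pool <- earlier[allowed(earlier, child)]
    pool <- dplyr::bind_rows(
      tibble::tibble(gene = prev_pool, lag = rep("prev", length(prev_pool))),
      tibble::tibble(gene = same_pool, lag = rep("same", length(same_pool))))
    res_tr <- greedy_family(pool = pool,
                            score = function(pa) score_tr(child, pa),
                            max_parents = max_parents)
    if (nrow(res_tr$parents) > 0)
      tr_edges[[child]] <- tibble::tibble(parent = res_tr$parents$gene,
                                          lag = res_tr$parents$lag, child = child)
    trace[[child]] <- list(b0 = res$trace, transition = res_tr$trace)
  }

  dbn_structure(
    genes = data$genes,
    b0 = dplyr::bind_rows(b0_edges),
    trans = dplyr::bind_rows(tr_edges),
    metadata = list(method = "friedman", order = order, max_parents = max_parents,
                    filtered = !is.null(candidate_filter), score_trace = trace))
}

# Greedy K2 inner loop for one family. `pool` is a tibble(gene, lag) of
# admissible parents; `score(parents)` returns the penalized family score.
# A candidate is accepted only on strict improvement.
#' @keywords internal
greedy_family <- function(pool, score, max_parents) {
  current <- pool[0, , drop = FALSE]
  best <- score(current)
  trace <- best
  while (nrow(current) < max_parents && nrow(pool) > 0) {
    cand_scores <- vapply(seq_len(nrow(pool)), function(i)
      score(dplyr::bind_rows(current, pool[i, ])), numeric(1))
    i_best <- which.max(cand_scores)
    if (cand_scores[i_best] > best) {
      current <- dplyr::bind_rows(current, pool[i_best, ])
      pool <- pool[-i_best, , drop = FALSE]
      best <- cand_scores[i_best]
      trace <- c(trace, best)
    } else break
  }
  list(parents = current, score = best, trace = trace)
}

#' @keywords internal
cached_score <- function(cache, data, child, parents, kind) {
  key <- paste(kind, child,
               paste(sort(paste(parents$gene, parents$lag, sep = "@")), collapse = ","),
               sep = "|")
  if (!is.null(cache[[key]])) return(cache[[key]])
  val <- if (kind == "initial") {
    family_bic(count_initial(data, child, parents$gene), M = data$n_seq)$penalized
  } else {
    family_bic(count_transition(data, child, parents), M = data$n)$penalized
  }
  cache[[key]] <- val
  val
}

#' @keywords internal
check_order <- function(data, order) {
  if (is.null(order)) return(data$genes)
  order <- as.character(order)
  if (!identical(sort(order), sort(data$genes)))
    stop("order must be a permutation of the dataset's genes", call. = FALSE)
  order
}

#' @keywords internal
filter_fun <- function(candidate_filter, genes) {
  if (is.null(candidate_filter)) return(function(reg, tgt) rep(TRUE, length(reg)))
  unknown <- setdiff(network_nodes(candidate_filter), genes)
  if (length(unknown) > 0)
    stop("candidate filter references unknown gene(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  keys <- edge_keys(candidate_filter)
  function(reg, tgt) paste(reg, tgt, sep = "\r") %in% keys
}

#' Exhaustive per-family search (test oracle)
#'
#' Enumerates every admissible parent set of size up to `max_parents` for
#' each family under the same admissibility rules as [k2_dbn()] and keeps
#' the set with the highest penalized score. Ties (within 1e-9) are broken
#' toward the smaller set, then lexicographically by parent names. Intended
#' as an independent check on the greedy search; refuses more than 6 genes.
#'
#' @inheritParams k2_dbn
#' @return A [dbn_structure].
#' @export
exhaustive_oracle <- function(data, order = NULL, max_parents = 3L,
                              candidate_filter = NULL) {
  if (length(data$genes) > 6L)
    stop("exhaustive_oracle is limited to 6 genes", call. = FALSE)
  order <- check_order(data, order)
  allowed <- filter_fun(candidate_filter, data$genes)

  b0_edges <- list(); tr_edges <- list()
  for (pos in seq_along(order)) {
    child <- order[pos]
    earlier <- if (pos > 1L) order[seq_len(pos - 1L)] else character()

    pool0 <- earlier[allowed(earlier, child)]
    best0 <- best_subset(
      pool = tibble::tibble(gene = pool0, lag = rep("initial", length(pool0))),
      score = function(pa) family_bic(count_initial(data, child, pa$gene),
                                      M = data$n_seq)$penalized,
      max_parents = max_parents)
    if (nrow(best0) > 0)
      b0_edges[[child]] <- tibble::tibble(parent = best0$gene, child = child)

    prev_pool <- data$genes[allowed(data$genes, child) | data$genes == child]
    same_pool <- earlier[allowed(earlier, child)]
    pool <- dplyr::bind_rows(
      tibble::tibble(gene = prev_pool, lag = rep("prev", length(prev_pool))),
      tibble::tibble(gene = same_pool, lag = rep("same", length(same_pool))))
    best_tr <- best_subset(
      pool = pool,
      score = function(pa) family_bic(count_transition(data, child, pa),
                                      M = data$n)$penalized,
      max_parents = max_parents)
    if (nrow(best_tr) > 0)
      tr_edges[[child]] <- tibble::tibble(parent = best_tr$gene, lag = best_tr$lag,
                                          child = child)
  }
  dbn_structure(genes = data$genes,
                b0 = dplyr::bind_rows(b0_edges),
                trans = dplyr::bind_rows(tr_edges),
                metadata = list(method = "exhaustive", order = order,
                                max_parents = max_parents))
}

#' @keywords internal
best_subset <- function(pool, score, max_parents, tol = 1e-9) {
  best_pa <- pool[0, , drop = FALSE]
  best_sc <- score(best_pa)
  best_key <- ""
  for (k in seq_len(min(max_parents, nrow(pool)))) {
    for (idx in utils::combn(nrow(pool), k, simplify = FALSE)) {
      pa <- pool[idx, , drop = FALSE]
      sc <- score(pa)
      key <- paste(sort(paste(pa$gene, pa$lag, sep = "@")), collapse = ",")
      better <- sc > best_sc + tol ||
        (abs(sc - best_sc) <= tol &&
           (nrow(pa) < nrow(best_pa) ||
              (nrow(pa) == nrow(best_pa) && key < best_key)))
      if (better) { best_pa <- pa; best_sc <- sc; best_key <- key }
    }
  }
  best_pa
}

#' Learn a DBN structure by a named method
#'
#' Uniform entry point dispatching to the BIC/K2 search (`"friedman"`) or
#' the mutual-information lattice search (`"reveal"`); provenance (method
#' name and options) is attached to the returned structure's metadata.
#'
#' @param data A [dbn_data] object.
#' @param method `"friedman"` or `"reveal"`.
#' @param ... Passed to [k2_dbn()] or [reveal_network()].
#' @return A [dbn_structure].
#' @export
learn <- function(data, method = c("friedman", "reveal"), ...) {
  method <- tryCatch(match.arg(method),
                     error = function(e)
                       stop("unknown method '", method[1],
                            "'; valid methods: friedman, reveal", call. = FALSE))
  switch(method, friedman = k2_dbn(data, ...), reveal = reveal_network(data, ...))
}
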