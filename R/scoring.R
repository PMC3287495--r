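#' Sufficient-statistic counts for one family
#'
#' A family is one child gene together with one parent set. For the initial
#' network the child and its parents are all read in slice 0 of each
#' sequence, giving a total count of `n_seq`. For the transition network the
#' child is read at slice t+1, `"prev"` parents at slice t and `"same"`
#' parents at slice t+1, pooled over every transition of every sequence
#' (stationarity), giving a total of `n`.
#'
#' `count_initial()` takes untagged parent names; `count_transition()` takes
#' a tagged parent set: either a data frame with columns `gene` and `lag`,
#' or a character vector whose names are lags (e.g.
#' `c(prev = "x", same = "y")`; unnamed entries default to `"prev"`).
#'
#' @param data A [dbn_data] object.
#' @param child Child gene identifier.
#' @param parents Parent specification (see Details).
#' @return A `family_counts` object: `table` is a (parent configuration x
#'   child level) integer matrix indexed by mixed-radix configuration, with
#'   `total` equal to `n_seq` (initial) or `n` (transition).
#' @export
count_initial <- function(data, child, parents = character()) {
  parents <- untagged_parents(parents)
  check_family_genes(data, child, parents$gene)
  if (child %in% parents$gene)
    stop("child cannot be in its own initial parent set", call. = FALSE)
  child_obs <- vapply(data$sequences, function(m) m[1L, child], integer(1))
  parent_obs <- lapply(parents$gene, function(p)
    vapply(data$sequences, function(m) m[1L, p], integer(1)))
  family_counts(data, child, parents, child_obs, parent_obs, kind = "initial")
}

#' @rdname count_initial
#' @export
count_transition <- function(data, child, parents = character()) {
  parents <- tagged_parents(parents)
  check_family_genes(data, child, parents$gene, parents$lag)
  if (any(parents$gene == child & parents$lag == "same"))
    stop("child cannot be its own same-slice parent (self-cycle)", call. = FALSE)
  child_obs <- unlist(lapply(data$sequences, function(m) m[-1L, child]), use.names = FALSE)
  parent_obs <- purrr::map2(parents$gene, parents$lag, function(p, lag) {
    unlist(lapply(data$sequences, function(m) {
      if (lag == "prev") m[-nrow(m), p] else m[-1L, p]
    }), use.names = FALSE)
  })
  family_counts(data, child, parents, child_obs, parent_obs, kind = "transition")
}

#' @keywords internal
untagged_parents <- function(parents) {
  if (is.data.frame(parents)) parents <- parents$gene
  tibble::tibble(gene = as.character(parents),
                 lag = rep("initial", length(parents)))
}

#' @keywords internal
tagged_parents <- function(parents) {
  if (is.data.frame(parents)) {
    out <- tibble::tibble(gene = as.character(parents$gene),
                          lag = as.character(parents$lag))
  } else {
    lag <- names(parents) %||% rep("", length(parents))
    lag[!nzchar(lag)] <- "prev"
    parents <- as.character(parents)
    out <- tibble::tibble(gene = unname(parents), lag = lag)
  }
  if (!all(out$lag %in% c("prev", "same")))
    stop("parent lag tags must be 'prev' or 'same'", call. = FALSE)
  out
}

#' @keywords internal
check_family_genes <- function(data, child, parent_genes, parent_lags = NULL) {
  unknown <- setdiff(c(child, parent_genes), data$genes)
  if (length(unknown) > 0)
    stop("unknown gene(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  # the same gene may appear at both slices, but not twice at one slice
  key <- if (is.null(parent_lags)) parent_genes else paste(parent_genes, parent_lags)
  if (anyDuplicated(key) > 0)
    stop("duplicated parent", call. = FALSE)
}

# Tabulate (parent configuration, child level) pairs with a mixed-radix
# configuration index over the declared (not observed) parent arities.
#' @keywords internal
family_counts <- function(data, child, parents, child_obs, parent_obs, kind) {
  r_child <- data$arities[[child]]
  r_par <- if (nrow(parents)) unname(data$arities[parents$gene]) else integer()
  n_cfg <- prod(r_par)
  cfg <- rep(0L, length(child_obs))
  radix <- 1L
  for (i in seq_along(parent_obs)) {
    cfg <- cfg + parent_obs[[i]] * radix
    radix <- radix * r_par[i]
  }
  idx <- cfg * r_child + child_obs + 1L
  tab <- matrix(tabulate(idx, nbins = n_cfg * r_child),
                nrow = n_cfg, ncol = r_child, byrow = TRUE)
  structure(list(child = child, parents = parents, table = tab,
                 r_child = r_child, parent_arities = r_par,
                 total = sum(tab), kind = kind),
            class = "family_counts")
}

#' @export
print.family_counts <- function(x, ...) {
  cat(sprintf("<family_counts> child %s | %d parent(s) | %d configs x %d levels | total %d (%s)\n",
              x$child, nrow(x$parents), nrow(x$table), x$r_child, x$total, x$kind))
  invisible(x)
}

#' Maximized multinomial log-likelihood of one family
#'
#' Plugs the maximum-likelihood conditional probabilities
#' `theta_hat[j,k] = N[j,k] / N[j,.]` into the family log-likelihood,
#' giving `sum_jk N[j,k] * log(N[j,k] / N[j,.])` in nats, with the
#' conventions `0 * log 0 = 0` and unobserved parent configurations
#' contributing 0.
#'
#' @param counts A `family_counts` object.
#' @param pseudocount Optional nonnegative value added to every cell before
#'   computing the plug-in probabilities (0 by default: the pure maximum
#'   likelihood plug-in). Useful only as a numerical-robustness knob; the
#'   default score is the plain BIC.
#' @return The maximized log-likelihood (a nonpositive number; exactly 0 for
#'   a deterministic family).
#' @export
family_loglik <- function(counts, pseudocount = 0) {
  tab <- counts$table
  if (pseudocount > 0) {
    smooth <- tab + pseudocount
    row_tot <- rowSums(smooth)
    pos <- tab > 0
    return(sum(tab[pos] * log(smooth[pos] / row_tot[row(tab)[pos]])))
  }
  row_tot <- rowSums(tab)
  pos <- tab > 0
  sum(tab[pos] * log(tab[pos] / row_tot[row(tab)[pos]]))
}

#' Penalized (BIC) score of one family
#'
#' The family's contribution to the decomposable DBN score:
#' `loglik - (log(M) / 2) * dim`, where `dim = (r_child - 1) * prod(r_parents)`
#' counts the family's independent parameters from the declared arities, and
#' `M` is the effective sample size (`n_seq` for initial families, `n` for
#' transition families).
#'
#' @param counts A `family_counts` object.
#' @param M Effective sample size (>= 1).
#' @inheritParams family_loglik
#' @return A `family_score` object with fields `loglik`, `dim`, `penalized`.
#' @export
family_bic <- function(counts, M, pseudocount = 0) {
  if (M < 1) stop("M must be >= 1", call. = FALSE)
  ll <- family_loglik(counts, pseudocount = pseudocount)
  dim <- (counts$r_child - 1L) * prod(counts$parent_arities)
  structure(list(child = counts$child, parents = counts$parents,
                 loglik = ll, dim = dim,
                 penalized = ll - (log(M) / 2) * dim),
            class = "family_score")
}

#' @export
print.family_score <- function(x, ...) {
  cat(sprintf("<family_score> child %s | loglik %.6f | dim %d | penalized %.6f\n",
              x$child, x$loglik, x$dim, x$penalized))
  invisible(x)
}

#' Decomposable BIC score of a two-slice DBN structure
#'
#' The score splits exactly into an initial-network part penalized by
#' `log(n_seq)/2` per parameter and a transition part penalized by
#' `log(n)/2` per parameter; `bic_total()` is their exact sum (the
#' likelihood decomposes, so the two components are independent and can be
#' learned separately).
#'
#' @param structure A [dbn_structure].
#' @param data A [dbn_data] with all of the structure's genes.
#' @return A single numeric score in nats.
#' @export
bic_initial <- function(structure, data) {
  sum(vapply(structure$genes, function(g) {
    pa <- structure$b0$parent[structure$b0$child == g]
    family_bic(count_initial(data, g, pa), M = data$n_seq)$penalized
  }, numeric(1)))
}

#' @rdname bic_initial
#' @export
bic_transition <- function(structure, data) {
  sum(vapply(structure$genes, function(g) {
    pa <- structure$trans[structure$trans$child == g, ]
    family_bic(count_transition(data, g, tibble::tibble(gene = pa$parent, lag = pa$lag)),
               M = data$n)$penalized
  }, numeric(1)))
}

#' @rdname bic_initial
#' @export
bic_total <- function(structure, data) {
  bic_initial(structure, data) + bic_transition(structure, data)
}
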