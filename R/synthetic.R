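#' Simulation configuration
#'
#' Bundles the knobs of the synthetic benchmark generator. The defaults
#' reproduce the benchmark data shape used throughout the package: 21 time
#' points and 10 replicates per network, with sparse random topologies.
#'
#' @param n_genes Number of genes.
#' @param avg_in_degree Mean in-degree of the random topology (default 1.5;
#'   in-degrees are truncated to 0..3).
#' @param n_times Time points per replicate (default 21).
#' @param n_replicates Independent replicate time courses (default 10).
#' @param noise_sd Gaussian noise s.d. added at every step (default 0.05).
#' @param interaction_strength Two-element range of interaction-weight
#'   magnitudes (default `c(2, 5)`); each edge's sign is sampled
#'   (activation/repression).
#' @param activation_prob Probability an edge is activating (default 0.5).
#' @param seed Integer seed; every draw is derived from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes, avg_in_degree = 1.5, n_times = 21L,
                       n_replicates = 10L, noise_sd = 0.05,
                       interaction_strength = c(2, 5), activation_prob = 0.5,
                       seed = 1L) {
  stopifnot(n_genes >= 2, n_times >= 2, n_replicates >= 1, noise_sd >= 0,
            length(interaction_strength) == 2,
            interaction_strength[1] <= interaction_strength[2],
            activation_prob >= 0, activation_prob <= 1)
  structure(list(n_genes = as.integer(n_genes), avg_in_degree = avg_in_degree,
                 n_times = as.integer(n_times), n_replicates = as.integer(n_replicates),
                 noise_sd = noise_sd, interaction_strength = interaction_strength,
                 activation_prob = activation_prob, seed = as.integer(seed)),
            class = "sim_config")
}

#' @keywords internal
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Sample a random gene regulatory network topology
#'
#' Draws each gene's in-degree from a Poisson distribution with the
#' configured mean, truncated to 0..3, and picks its regulators uniformly
#' without self-loops. If no gene ends up regulating at least two targets, a
#' hub is created by adding targets to the best-connected regulator, so
#' every benchmark network contains at least one multi-target regulator.
#' Deterministic given `config$seed`.
#'
#' @param config A [sim_config].
#' @return A [gene_network] over genes `g01`, `g02`, ...
#' @export
random_grn <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    n <- config$n_genes
    genes <- sprintf("g%0*d", max(2L, nchar(n)), seq_len(n))
    k <- pmin(stats::rpois(n, config$avg_in_degree), min(3L, n - 1L))
    edges <- purrr::map_dfr(seq_len(n), function(i) {
      if (k[i] == 0L) return(NULL)
      tibble::tibble(regulator = sample(genes[-i], k[i]), target = genes[i])
    })
    if (nrow(edges) > 0) {
      out_deg <- table(factor(edges$regulator, levels = genes))
    } else {
      out_deg <- stats::setNames(rep(0L, n), genes)
    }
    if (max(out_deg) < 2L) {
      hub <- genes[which.max(out_deg)]
      need <- 2L - max(out_deg)
      taken <- edges$target[edges$regulator == hub]
      free <- setdiff(genes, c(hub, taken))
      add <- sample(free, min(need, length(free)))
      edges <- dplyr::bind_rows(edges, tibble::tibble(regulator = hub, target = add))
    }
    gene_network(dplyr::distinct(edges), nodes = genes)
  })
}

#' Simulate replicated expression time courses from a network
#'
#' Discrete-time squashed-linear dynamics with Gaussian noise: each gene
#' updates as `x_i[t+1] = logistic(b_i + sum_j w_ij * x_j[t]) + eps`, where
#' the sum runs over gene i's regulators, `eps ~ Normal(0, noise_sd)`, and
#' weights/biases are drawn once per network — magnitudes uniform in
#' `interaction_strength` with random activating/repressing sign, and biases
#' centred so the logistic operates in its sensitive range. Replicates share
#' the network parameters and differ only by their uniform random initial
#' state and by noise. Deterministic given `config$seed` (the parameter and
#' trajectory draws use a seed derived from it, offset from the topology
#' draw so network and dynamics use independent streams).
#'
#' @param grn A [gene_network] (e.g. from [random_grn()]).
#' @param config A [sim_config] with `n_genes` matching the network.
#' @return Long expression tibble (`gene`, `time`, `replicate`, `value`).
#' @export
simulate_timeseries <- function(grn, config) {
  stopifnot(inherits(config, "sim_config"))
  genes <- network_nodes(grn)
  if (length(genes) != config$n_genes)
    stop("config$n_genes does not match the network's gene count", call. = FALSE)
  n <- length(genes)
  with_seed(config$seed + 500009L, {
    W <- matrix(0, n, n, dimnames = list(genes, genes))  # W[i, j]: j -> i
    if (nrow(grn) > 0) {
      mag <- stats::runif(nrow(grn), config$interaction_strength[1],
                          config$interaction_strength[2])
      sgn <- ifelse(stats::runif(nrow(grn)) < config$activation_prob, 1, -1)
      W[cbind(match(grn$target, genes), match(grn$regulator, genes))] <- mag * sgn
    }
    b <- stats::runif(n, -0.5, 0.5) - 0.5 * rowSums(W)

    out <- purrr::map_dfr(seq_len(config$n_replicates), function(r) {
      x <- matrix(NA_real_, config$n_times, n)
      x[1, ] <- stats::runif(n)
      for (t in seq_len(config$n_times - 1L)) {
        x[t + 1L, ] <- stats::plogis(b + W %*% x[t, ]) +
          stats::rnorm(n, 0, config$noise_sd)
      }
      tibble::tibble(gene = rep(genes, each = config$n_times),
                     time = rep(seq_len(config$n_times) - 1L, times = n),
                     replicate = r,
                     value = as.vector(x))
    })
    out <- dplyr::arrange(out, factor(.data$gene, levels = genes),
                          .data$time, .data$replicate)
    # provenance: the drawn interaction weights and biases
    attr(out, "weights") <- tibble::tibble(regulator = grn$regulator,
                                           target = grn$target,
                                           weight = W[cbind(match(grn$target, genes),
                                                            match(grn$regulator, genes))])
    attr(out, "bias") <- stats::setNames(b, genes)
    out
  })
}

#' Generate a benchmark suite of (truth network, expression data) cases
#'
#' One case per (size, seed) pair, each holding the true network and the
#' simulated expression table. If `outdir` is given, every case's truth
#' (SIF) and expression table (TSV) are written there along with a
#' `manifest.txt` of flat `key=value` lines recording sizes, seeds and the
#' generator configuration, so a run can be regenerated byte-identically.
#'
#' @param sizes Integer vector of network sizes (e.g. `c(10, 20, 50, 100)`).
#' @param seeds Integer vector of seeds.
#' @param outdir Optional output directory.
#' @param ... Overrides passed to [sim_config()] (e.g. `noise_sd`).
#' @return Tibble with columns `size`, `seed`, `truth` (list of
#'   [gene_network]) and `expression` (list of tibbles).
#' @export
make_benchmark <- function(sizes, seeds, outdir = NULL, ...) {
  cases <- tidyr::expand_grid(size = as.integer(sizes), seed = as.integer(seeds)) |>
    dplyr::mutate(case = purrr::map2(.data$size, .data$seed, function(sz, sd) {
      cfg <- sim_config(n_genes = sz, seed = sd + 1000L * sz, ...)
      truth <- random_grn(cfg)
      list(truth = truth, expression = simulate_timeseries(truth, cfg))
    })) |>
    dplyr::mutate(truth = purrr::map(.data$case, "truth"),
                  expression = purrr::map(.data$case, "expression")) |>
    dplyr::select(-"case")
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    manifest <- c(sprintf("sizes=%s", paste(sizes, collapse = ",")),
                  sprintf("seeds=%s", paste(seeds, collapse = ",")),
                  sprintf("case_seed_rule=seed+1000*size"),
                  vapply(names(list(...)), function(nm)
                    sprintf("%s=%s", nm, paste(list(...)[[nm]], collapse = ",")),
                    character(1)))
    writeLines(manifest, file.path(outdir, "manifest.txt"))
    purrr::pwalk(cases, function(size, seed, truth, expression) {
      stem <- sprintf("n%d_s%d", size, seed)
      write_network(truth, file.path(outdir, paste0(stem, "_truth.sif")))
      write_expression(expression, file.path(outdir, paste0(stem, "_expr.tsv")))
    })
  }
  cases
}

#' Run the four benchmark method configurations over generated cases
#'
#' Reproduces the standard four-way comparison: the timing prior alone
#' (`"prior"`), REVEAL restricted by the prior (`"reveal+prior"`), the
#' BIC/K2 search (`"friedman"`), and the BIC/K2 search restricted by the
#' prior (`"friedman+prior"`); plain `"reveal"` is also available. Each
#' learned structure is converted to a GRN and scored against the case's
#' truth.
#'
#' @param cases Tibble from [make_benchmark()].
#' @param methods Character vector of method names (see Details).
#' @param n_levels,max_parents,fold_threshold Passed to the pipeline steps.
#' @return Tibble with one row per (method, size, seed):
#'   `ce`, `me`, `fe`, `precision`, `recall`.
#' @export
run_benchmark <- function(cases,
                          methods = c("friedman", "friedman+prior",
                                      "reveal+prior", "prior"),
                          n_levels = 3L, max_parents = 3L, fold_threshold = 1.5) {
  known <- c("friedman", "friedman+prior", "reveal", "reveal+prior", "prior")
  bad <- setdiff(methods, known)
  if (length(bad) > 0)
    stop("unknown method(s): ", paste(bad, collapse = ", "),
         "; valid: ", paste(known, collapse = ", "), call. = FALSE)
  purrr::pmap_dfr(cases, function(size, seed, truth, expression) {
    disc <- discretize(expression, n_levels = n_levels)
    prior <- if (any(grepl("prior", methods)))
      suppressMessages(build_prior_network(expression, fold_threshold = fold_threshold))
    else NULL
    purrr::map_dfr(methods, function(m) {
      predicted <- switch(
        m,
        "prior" = prior,
        "friedman" = transition_to_grn(k2_dbn(disc, max_parents = max_parents)),
        "friedman+prior" = transition_to_grn(
          k2_dbn(disc, max_parents = max_parents, candidate_filter = prior)),
        "reveal" = transition_to_grn(reveal_network(disc, max_parents = max_parents)),
        "reveal+prior" = transition_to_grn(
          reveal_network(disc, max_parents = max_parents, candidate_filter = prior)))
      dplyr::bind_cols(tibble::tibble(method = m, size = size, seed = seed),
                       evaluate_network(truth, predicted))
    })
  })
}
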