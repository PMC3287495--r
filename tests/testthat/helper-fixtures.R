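# Small in-code fixtures shared across the suite.

# dbn_data from a list of integer level vectors (one gene) or matrices
make_data <- function(..., arity = 2L) {
  seqs <- lapply(list(...), function(s) {
    if (is.matrix(s)) {
      storage.mode(s) <- "integer"
      s
    } else {
      matrix(as.integer(s), ncol = 1, dimnames = list(NULL, "g"))
    }
  })
  genes <- colnames(seqs[[1]])
  dbn_data(seqs, arities = stats::setNames(rep(as.integer(arity), length(genes)), genes))
}

# the 1-binary-gene dataset with slice-0 values {0,0,1,1} and transition
# child values {0,0,1,1}: four sequences of length 2
binary_gene_data <- function() {
  make_data(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
}

# deterministic copy: y[t+1] = x[t], x iid uniform; returns dbn_data
copy_data <- function(n_trans = 40, seed = 1) {
  set.seed(seed)
  x <- sample(0:1, n_trans + 1, replace = TRUE)
  y <- c(sample(0:1, 1), x[seq_len(n_trans)])
  make_data(cbind(x = x, y = y))
}

# XOR family: y[t+1] = a[t] xor b[t], with the four (a, b) input
# configurations perfectly balanced over the transitions so that every
# single-input mutual information is exactly zero
xor_data <- function(n_trans = 64, seed = 1) {
  set.seed(seed)
  stopifnot(n_trans %% 4 == 0)
  idx <- sample(rep(1:4, n_trans / 4))
  a <- c(c(0L, 0L, 1L, 1L)[idx], 0L)
  b <- c(c(0L, 1L, 0L, 1L)[idx], 0L)
  y <- c(0L, xor(a[seq_len(n_trans)], b[seq_len(n_trans)]) * 1L)
  make_data(cbind(a = a, b = b, y = y))
}

# random discrete dataset: independent uniform levels
random_data <- function(n_genes = 3, n_seq = 4, len = 6, arity = 2L, seed = 1) {
  set.seed(seed)
  genes <- paste0("g", seq_len(n_genes))
  seqs <- lapply(seq_len(n_seq), function(i) {
    matrix(sample(0:(arity - 1L), len * n_genes, replace = TRUE),
           ncol = n_genes, dimnames = list(NULL, genes))
  })
  dbn_data(seqs, arities = stats::setNames(rep(as.integer(arity), n_genes), genes))
}

# data from a known single-parent 2TBN: gene 1 iid; gene i copies its
# assigned earlier parent's previous value with probability 1 - flip
single_parent_data <- function(n_genes = 5, n_seq = 10, len = 11,
                               flip = 0.1, seed = 1) {
  set.seed(seed)
  genes <- paste0("g", seq_len(n_genes))
  parent_of <- c(NA, vapply(2:n_genes, function(i) sample(i - 1L, 1), integer(1)))
  seqs <- lapply(seq_len(n_seq), function(s) {
    m <- matrix(0L, len, n_genes, dimnames = list(NULL, genes))
    m[1, ] <- sample(0:1, n_genes, replace = TRUE)
    for (t in 2:len) {
      m[t, 1] <- sample(0:1, 1)
      for (i in 2:n_genes) {
        v <- m[t - 1, parent_of[i]]
        m[t, i] <- if (stats::runif(1) < flip) 1L - v else v
      }
    }
    m
  })
  list(data = dbn_data(seqs, stats::setNames(rep(2L, n_genes), genes)),
       parent_of = parent_of, genes = genes)
}

# long-form expression tibble from a gene x time x replicate array function
make_expression <- function(genes, times, reps, value_fun) {
  tidyr::expand_grid(gene = genes, time = times, replicate = reps) |>
    dplyr::mutate(value = purrr::pmap_dbl(list(gene, time, replicate), value_fun))
}

# activating 5-gene cascade truth network
chain_network <- function(n = 5) {
  genes <- paste0("g", seq_len(n))
  gene_network(tibble::tibble(regulator = genes[-n], target = genes[-1]),
               nodes = genes)
}
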