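# Closed-form expectations below were derived by hand from the multinomial
# MLE formulas: ll = sum N_jk log(N_jk / N_j.), penalty = (log M / 2) * dim.

test_that("initial-slice counts tally slice-0 rows and always total n_seq", {
  d <- binary_gene_data()
  fc <- count_initial(d, "g")
  expect_equal(as.vector(fc$table), c(2L, 2L))
  expect_equal(fc$total, d$n_seq)

  # one binary parent, all four (parent, child) slice-0 pairs seen once
  seqs <- list(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  mats <- lapply(seqs, function(s)
    matrix(as.integer(c(s[1], 0, s[2], 0)), 2, 2, dimnames = list(NULL, c("p", "c"))))
  d2 <- dbn_data(mats, c(p = 2L, c = 2L))
  fc2 <- count_initial(d2, "c", "p")
  expect_equal(as.vector(fc2$table), rep(1L, 4))

  # brute-force: totals equal n_seq for arbitrary parent sets
  d3 <- random_data(n_genes = 4, n_seq = 10, len = 5, arity = 3L, seed = 3)
  for (pa in list(character(), "g1", c("g1", "g3"), c("g1", "g2", "g4"))) {
    expect_equal(count_initial(d3, "g3", setdiff(pa, "g3"))$total, 10L)
  }
})

test_that("transition counts pool every t -> t+1 slice pair", {
  # child copies its own previous value: 4 transitions, all on the diagonal
  m <- matrix(c(1L, 1L, 1L, 1L, 1L), ncol = 1, dimnames = list(NULL, "g"))
  d <- dbn_data(list(m), c(g = 2L))
  fc <- count_transition(d, "g", c(prev = "g"))
  expect_equal(sum(diag(fc$table)), 4L)
  expect_equal(fc$total, 4L)

  # empty parent set gives the child's marginal over slice-(t+1) positions
  d2 <- make_data(c(0, 0, 1), c(1, 1, 0, 0, 1))
  fc2 <- count_transition(d2, "g")
  expect_equal(fc2$total, 2L + 4L)
  expect_equal(as.vector(fc2$table), c(3L, 3L))
  expect_equal(sum(fc2$table), fc2$total)
})

test_that("transition counting reads prev parents at t and same parents at t+1", {
  # x: 0,1,0,1 ; y copies x's previous value; z equals y at the same slice
  m <- cbind(x = c(0L, 1L, 0L, 1L), y = c(1L, 0L, 1L, 0L), z = c(1L, 0L, 1L, 0L))
  d <- dbn_data(list(m), c(x = 2L, y = 2L, z = 2L))
  fc <- count_transition(d, "y", c(prev = "x"))
  expect_equal(family_loglik(fc), 0)      # deterministic given prev x
  fc2 <- count_transition(d, "y", c(same = "z"))
  expect_equal(family_loglik(fc2), 0)     # deterministic given same-slice z
  expect_error(count_transition(d, "y", c(same = "y")), "self-cycle")
})

test_that("family log-likelihood matches closed forms", {
  d <- binary_gene_data()
  fc <- count_transition(d, "g")
  expect_equal(family_loglik(fc), 4 * log(0.5), tolerance = 1e-12)

  # deterministic family scores exactly zero
  expect_equal(family_loglik(count_transition(copy_data(), "y", c(prev = "x"))), 0)

  # counts [3,1]
  m <- matrix(c(0L, 0L, 0L, 1L, 0L), ncol = 1, dimnames = list(NULL, "g"))
  fc31 <- count_transition(dbn_data(list(m), c(g = 2L)), "g")
  expect_equal(as.vector(fc31$table), c(3L, 1L))
  expect_equal(family_loglik(fc31), 3 * log(0.75) + 1 * log(0.25), tolerance = 1e-12)
  expect_equal(family_loglik(fc31), -2.2493406, tolerance = 1e-7)
})

test_that("family BIC applies the log(M)/2 penalty over declared arities", {
  d <- binary_gene_data()
  fs <- family_bic(count_initial(d, "g"), M = 4)
  expect_equal(fs$dim, 1L)
  expect_equal(fs$penalized, -2.7725887 - (log(4) / 2) * 1, tolerance = 1e-7)
  expect_equal(fs$penalized, -3.4657359, tolerance = 1e-7)

  # deterministic binary child with one binary parent at M = 100
  fs2 <- family_bic(count_transition(copy_data(n_trans = 100), "y", c(prev = "x")),
                    M = 100)
  expect_equal(fs2$loglik, 0)
  expect_equal(fs2$dim, 2L)
  expect_equal(fs2$penalized, -(log(100) / 2) * 2, tolerance = 1e-12)
  expect_equal(fs2$penalized, -4.6051702, tolerance = 1e-7)

  # dim counts declared (not observed) levels: 3-level child, two 3-level parents
  d3 <- random_data(n_genes = 3, n_seq = 2, len = 8, arity = 3L, seed = 5)
  fs3 <- family_bic(count_transition(d3, "g1", c(prev = "g2", prev = "g3")), M = d3$n)
  expect_equal(fs3$dim, (3 - 1) * 9)
})

test_that("the empty-structure score on the binary gene splits as expected", {
  d <- binary_gene_data()
  s <- dbn_structure("g")
  expect_equal(bic_initial(s, d), -3.4657359, tolerance = 1e-7)
  expect_equal(bic_transition(s, d), -3.4657359, tolerance = 1e-7)
  expect_equal(bic_total(s, d), -6.9314718, tolerance = 1e-7)
})

test_that("the BIC decomposes exactly over components and families", {
  set.seed(99)
  for (rep in 1:20) {
    d <- random_data(n_genes = 5, n_seq = 3, len = 6, arity = 2L, seed = rep)
    genes <- d$genes
    # random admissible structure under the identity order
    b0 <- NULL; trans <- NULL
    for (i in seq_along(genes)) {
      earlier <- genes[seq_len(i - 1)]
      if (length(earlier) > 0 && stats::runif(1) < 0.6) {
        b0 <- rbind(b0, data.frame(parent = sample(earlier, 1), child = genes[i]))
      }
      prev <- sample(genes, sample(0:2, 1))
      if (length(prev) > 0)
        trans <- rbind(trans, data.frame(parent = prev, lag = "prev", child = genes[i]))
      if (length(earlier) > 0 && stats::runif(1) < 0.4)
        trans <- rbind(trans, data.frame(parent = sample(earlier, 1), lag = "same",
                                         child = genes[i]))
    }
    s <- dbn_structure(genes, b0 = b0, trans = trans)
    expect_equal(bic_total(s, d), bic_initial(s, d) + bic_transition(s, d),
                 tolerance = 1e-12)
    # equals the sum of per-family penalized scores, recomputed directly
    fam_sum <- sum(vapply(genes, function(g) {
      pa0 <- s$b0$parent[s$b0$child == g]
      tr <- s$trans[s$trans$child == g, ]
      family_bic(count_initial(d, g, pa0), M = d$n_seq)$penalized +
        family_bic(count_transition(d, g, tibble::tibble(gene = tr$parent, lag = tr$lag)),
                   M = d$n)$penalized
    }, numeric(1)))
    expect_equal(bic_total(s, d), fam_sum, tolerance = 1e-12)
  }
})

test_that("scores are invariant to gene and sequence reordering", {
  d <- random_data(n_genes = 4, n_seq = 5, len = 6, arity = 3L, seed = 12)
  s <- dbn_structure(d$genes,
                     trans = data.frame(parent = c("g1", "g2"), lag = "prev",
                                        child = c("g2", "g3")))
  base <- bic_total(s, d)
  # permute sequences
  d_seq <- dbn_data(rev(d$sequences), d$arities)
  expect_equal(bic_total(s, d_seq), base, tolerance = 1e-12)
  # permute gene columns
  perm <- c("g3", "g1", "g4", "g2")
  d_gene <- dbn_data(lapply(d$sequences, function(m) m[, perm]), d$arities[perm])
  s_gene <- dbn_structure(perm, trans = s$trans)
  expect_equal(bic_total(s_gene, d_gene), base, tolerance = 1e-12)
})

test_that("an independent parent lowers the transition BIC at large N", {
  set.seed(7)
  n <- 10000
  m <- cbind(x = sample(0:1, n + 1, TRUE), y = sample(0:1, n + 1, TRUE))
  storage.mode(m) <- "integer"
  d <- dbn_data(list(m), c(x = 2L, y = 2L))
  empty <- family_bic(count_transition(d, "y"), M = d$n)$penalized
  with_x <- family_bic(count_transition(d, "y", c(prev = "x")), M = d$n)$penalized
  expect_lt(with_x, empty)
})

test_that("the true parent set wins more often as N grows", {
  # child copies parent with 10% flips; competitors: empty set and a
  # superset with an independent extra gene
  win_rate <- function(n_trans) {
    wins <- vapply(1:12, function(seed) {
      set.seed(seed * 1000 + n_trans)
      x <- sample(0:1, n_trans + 1, TRUE)
      z <- sample(0:1, n_trans + 1, TRUE)
      y <- integer(n_trans + 1)
      y[1] <- sample(0:1, 1)
      flips <- stats::runif(n_trans) < 0.1
      y[-1] <- ifelse(flips, 1L - x[seq_len(n_trans)], x[seq_len(n_trans)])
      m <- cbind(x = x, y = y, z = z)
      storage.mode(m) <- "integer"
      d <- dbn_data(list(m), c(x = 2L, y = 2L, z = 2L))
      sc <- function(pa) family_bic(count_transition(d, "y", pa), M = d$n)$penalized
      true_sc <- sc(c(prev = "x"))
      true_sc > sc(character()) &&
        true_sc > sc(c(prev = "x", prev = "z")) &&
        true_sc > sc(c(prev = "z"))
    }, logical(1))
    mean(wins)
  }
  rates <- vapply(c(50, 500, 5000), win_rate, numeric(1))
  expect_true(!is.unsorted(rates))
  expect_equal(rates[3], 1)
})

test_that("likelihoods are never positive and errors name unknown genes", {
  d <- random_data(seed = 2)
  expect_lte(family_loglik(count_transition(d, "g1", c(prev = "g2"))), 0)
  expect_error(count_initial(d, "nope"), "unknown gene")
  expect_error(count_transition(d, "g1", c(prev = "nope")), "unknown gene")
  expect_error(family_bic(count_transition(d, "g1"), M = 0), "M must be")
})
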