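test_that("orientation is strict, tie-breaking, and monotone invariant", {
  expect_identical(orientation(2, 1), "forward")
  expect_identical(orientation(1, 2), "reverse")
  expect_identical(orientation(1, 1), "reverse")  # ties are not a > b
  expect_error(orientation(NA_real_, 1), "finite")
  expect_error(orientation(Inf, 1), "finite")

  set.seed(3)
  a <- runif(50, 1, 10); b <- runif(50, 1, 10)
  for (f in list(function(x) 2 * x + 7, function(x) x^3, exp)) {
    expect_identical(orientation(f(a), f(b)), orientation(a, b))
  }
})

test_that("binomial majority tail matches closed form and brute-force oracle", {
  expect_equal(binomial_majority_p(10, 10), 0.0009765625)
  expect_equal(binomial_majority_p(5, 10), 0.623046875)
  for (n in c(1, 2, 7, 18, 20, 25)) {
    for (k in 0:n) {
      expect_equal(binomial_majority_p(k, n), oracle_binom_tail(k, n),
                   tolerance = 1e-12)
      expect_equal(binomial_majority_p(k, n), binomial_majority_p(n - k, n))
    }
  }
  expect_error(binomial_majority_p(1, 0), "n >= 1")
  expect_error(binomial_majority_p(5, 4), "k <= n")
  # two-sided variant doubles the tail, capped at 1
  expect_equal(binomial_majority_p(18, 20, two_sided = TRUE),
               min(1, 2 * oracle_binom_tail(18, 20)))
})

test_that("a planted reversal pair is emitted with oracle p-values", {
  fix <- planted_pair_expr(k_resp = 19, n_resp = 20, k_non = 2, n_non = 20)
  rec <- find_reversal_pairs(fix$expr, fix$pheno, alpha = 0.05)
  expect_identical(nrow(rec), 1L)
  expect_identical(rec$gene_a, "GA")  # response orientation stored forward
  expect_identical(rec$k_resp, 19L)
  expect_identical(rec$k_nonresp, 2L)
  expect_equal(rec$p_resp, oracle_binom_tail(19, 20), tolerance = 1e-12)   # 21/2^20
  expect_equal(rec$p_nonresp, oracle_binom_tail(2, 20), tolerance = 1e-12) # 211/2^20
  expect_equal(rec$p_resp, 2.0027161e-05, tolerance = 1e-6)
  expect_equal(rec$p_nonresp, 2.0122528e-04, tolerance = 1e-6)
})

test_that("a pair dominant in the same direction in both groups is not a reversal", {
  fix <- planted_pair_expr(k_resp = 20, n_resp = 20, k_non = 20, n_non = 20)
  rec <- find_reversal_pairs(fix$expr, fix$pheno, alpha = 0.05)
  expect_identical(nrow(rec), 0L)
})

test_that("screening validates labels, class sizes and alpha", {
  fix <- planted_pair_expr(19, 20, 2, 20)
  expect_error(find_reversal_pairs(fix$expr, fix$pheno[-1, ], 0.05), "without phenotype")
  ph <- fix$pheno; ph$response[1] <- NA
  expect_error(find_reversal_pairs(fix$expr, ph, 0.05), "missing response")
  ph <- fix$pheno; ph$response <- c("responder", rep("non-responder", 39))
  expect_error(find_reversal_pairs(fix$expr, ph, 0.05), "2 samples per class")
  expect_error(find_reversal_pairs(fix$expr, fix$pheno, alpha = 1.2), "alpha")
})

test_that("null emission rate over candidate pairs stays below alpha squared plus tolerance", {
  set.seed(2024)
  n_pairs <- 2000L
  g <- 2L * n_pairs
  ids <- sprintf("N%04d", seq_len(g))
  expr <- matrix(rnorm(g * 40, 8, 1), nrow = g,
                 dimnames = list(ids, sprintf("s%02d", 1:40)))
  pheno <- toy_pheno(colnames(expr), rep(c("responder", "non-responder"), each = 20))
  cand <- data.frame(gene_a = ids[seq(1, g, 2)], gene_b = ids[seq(2, g, 2)],
                     stringsAsFactors = FALSE)
  rec <- find_reversal_pairs(expr, pheno, alpha = 0.05, candidate_pairs = cand)
  expect_lte(nrow(rec) / n_pairs, 0.05^2 + 0.003)
})

test_that("screening output is invariant to monotone distortion and to row/column order", {
  sim <- simulate_cohort(sim_config(n_genes = 60, n_resp = 15, n_nonresp = 15,
                                    n_planted_pairs = 6, seed = 5))
  base <- find_reversal_pairs(sim$expr, sim$pheno)
  expect_gt(nrow(base), 0L)

  distorted <- find_reversal_pairs(monotone_distort(sim$expr), sim$pheno)
  expect_identical(distorted, base)

  set.seed(9)
  rperm <- sample(nrow(sim$expr)); cperm <- sample(ncol(sim$expr))
  shuffled <- find_reversal_pairs(sim$expr[rperm, cperm], sim$pheno)
  expect_identical(shuffled, base)  # records canonicalised lexicographically
})

test_that("candidate enumeration covers g(g-1)/2 unordered pairs and is gated", {
  for (g in c(2L, 5L, 9L)) {
    expect_identical(nrow(reopairs:::all_gene_pairs(g)), (g * (g - 1L)) %/% 2L)
  }
  fix <- planted_pair_expr(19, 20, 2, 20)
  big <- rbind(fix$expr,
               matrix(rnorm(3 * 40, 8, 1), nrow = 3,
                      dimnames = list(c("X1", "X2", "X3"), colnames(fix$expr))))
  expect_error(find_reversal_pairs(big, fix$pheno, max_genes = 4L), "max_genes")
  expect_silent(find_reversal_pairs(big, fix$pheno, max_genes = 5L))
  # variance prefilter keeps the screen runnable on wide matrices
  rec <- find_reversal_pairs(big, fix$pheno, max_genes = 2L,
                             prefilter_top_variance = 2L)
  expect_true(is.data.frame(rec))
})
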