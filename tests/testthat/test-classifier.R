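test_that("majority voting over 41 disjoint pairs follows the strict rule", {
  # overlapping genes make per-pair orientations interact; use disjoint toy
  # pairs for exact counts
  n_pairs <- 41L
  ga <- sprintf("A%02d", 1:n_pairs); gb <- sprintf("B%02d", 1:n_pairs)
  sig <- data.frame(rank = 1:n_pairs, gene_a = ga, gene_b = gb)
  counts <- c(41L, 0L, 21L, 20L)
  expr <- matrix(0, nrow = 2 * n_pairs, ncol = 4,
                 dimnames = list(c(ga, gb), sprintf("s%d", 1:4)))
  for (s in 1:4) {
    fwd <- seq_len(n_pairs) <= counts[s]
    expr[ga, s] <- ifelse(fwd, 8, 6)
    expr[gb, s] <- ifelse(fwd, 6, 8)
  }
  pred <- predict_signature(expr, sig)
  expect_identical(pred$n_response_pairs, counts)
  expect_identical(pred$n_evaluable_pairs, rep(41L, 4))
  expect_equal(pred$score, counts / 41)
  expect_identical(pred$label, c("responder", "non-responder",
                                 "responder", "non-responder"))
  # REO invariance of the predictions
  expect_identical(predict_signature(monotone_distort(expr), sig), pred)
})

test_that("vote ties on an even evaluable count go to non-responder", {
  sig <- data.frame(rank = 1:2, gene_a = c("A1", "A2"), gene_b = c("B1", "B2"))
  expr <- matrix(c(8, 6, 6, 8), nrow = 4,
                 dimnames = list(c("A1", "B1", "A2", "B2"), "s1"))
  pred <- predict_signature(expr, sig)
  expect_identical(pred$n_response_pairs, 1L)
  expect_identical(pred$label, "non-responder")
})

test_that("pairs with absent genes are dropped and heavy absence warns", {
  sig <- load_published_signature()
  genes <- unique(c(sig$gene_a, sig$gene_b))
  set.seed(5)
  expr <- matrix(runif(length(genes) * 3, 4, 12), nrow = length(genes),
                 dimnames = list(genes, c("s1", "s2", "s3")))
  # remove FUT8: pair 1 unusable, 40 remain; 1 of 76 genes absent, no warning
  expr2 <- expr[setdiff(genes, "FUT8"), , drop = FALSE]
  expect_silent(pred <- predict_signature(expr2, sig))
  expect_identical(unique(pred$n_evaluable_pairs), 40L)
  # cross-platform case: most genes absent -> warning, still evaluable
  keep <- unique(c(sig$gene_a[1:10], sig$gene_b[1:10]))
  expect_warning(pred10 <- predict_signature(expr[keep, , drop = FALSE], sig),
                 "absent")
  expect_identical(unique(pred10$n_evaluable_pairs), 10L)
  # nothing evaluable at all -> error
  suppressWarnings(
    expect_error(predict_signature(expr[c("ABCC5", "CDKN3"), , drop = FALSE], sig),
                 "no evaluable"))
})

test_that("monotone score property: adding a forward pair never lowers the call", {
  set.seed(12)
  n_pairs <- 9L
  ga <- sprintf("A%02d", 1:n_pairs); gb <- sprintf("B%02d", 1:n_pairs)
  sig <- data.frame(rank = 1:n_pairs, gene_a = ga, gene_b = gb)
  for (k in 0:(n_pairs - 1)) {
    e1 <- matrix(0, 2 * n_pairs, 1, dimnames = list(c(ga, gb), "s1"))
    fwd <- seq_len(n_pairs) <= k
    e1[ga, 1] <- ifelse(fwd, 8, 6); e1[gb, 1] <- ifelse(fwd, 6, 8)
    e2 <- e1
    e2[ga[k + 1], 1] <- 8; e2[gb[k + 1], 1] <- 6  # flip one more to forward
    p1 <- predict_signature(e1, sig); p2 <- predict_signature(e2, sig)
    expect_gte(p2$score, p1$score)
    expect_false(p1$label == "responder" && p2$label == "non-responder")
    # odd N, all evaluable: responder call iff score > 1/2
    expect_identical(p1$label == "responder", p1$score > 0.5)
  }
})

test_that("response-ratio group comparison reproduces a hand Welch t-test", {
  pred <- data.frame(sample_id = sprintf("s%d", 1:4),
                     n_response_pairs = c(4L, 5L, 5L, 6L),
                     n_evaluable_pairs = 10L,
                     score = c(0.4, 0.5, 0.5, 0.6),
                     label = "responder", stringsAsFactors = FALSE)
  out <- response_ratio_by_group(pred, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(unname(out$group_means), c(0.45, 0.55))
  expect_equal(out$mean_difference, -0.1)
  # closed-form Welch on {0.4, 0.5} vs {0.5, 0.6}
  se <- sqrt(0.005 / 2 + 0.005 / 2)
  t_stat <- -0.1 / se
  df <- (0.005 / 2 + 0.005 / 2)^2 /
    ((0.005 / 2)^2 / 1 + (0.005 / 2)^2 / 1)
  expect_equal(out$p_value, 2 * pt(-abs(t_stat), df))

  ident <- pred; ident$score <- rep(0.5, 4)
  out2 <- response_ratio_by_group(ident, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(out2$mean_difference, 0)
  expect_warning(response_ratio_by_group(pred, c(TRUE, FALSE, FALSE, FALSE)),
                 "fewer than 2")
})

test_that("simulated sensitive lines score above resistant ones", {
  sim <- simulate_cohort(sim_config(n_genes = 100, n_resp = 12, n_nonresp = 12,
                                    n_planted_pairs = 10, seed = 44))
  sig <- data.frame(rank = seq_len(nrow(sim$truth)), sim$truth)
  pred <- predict_signature(sim$expr, sig)
  sensitive <- sim$pheno$response == "responder"
  out <- response_ratio_by_group(pred, sensitive)
  expect_gt(out$group_means[["group1"]], out$group_means[["group2"]])
  expect_lt(out$p_value, 0.05)
})

test_that("median split sends strictly-above-median counts to the high group", {
  mk <- function(counts) data.frame(sample_id = sprintf("s%d", seq_along(counts)),
                                    n_response_pairs = counts,
                                    n_evaluable_pairs = max(counts) + 1L,
                                    score = 0.5, label = "responder",
                                    stringsAsFactors = FALSE)
  g <- split_high_low(mk(c(10L, 20L, 30L)))
  expect_identical(unname(g), c("low", "low", "high"))  # tie at median -> low
  g <- split_high_low(mk(c(1L, 2L, 3L, 4L)))
  expect_identical(unname(g), c("low", "low", "high", "high"))
  expect_error(split_high_low(mk(c(5L, 5L, 5L))), "degenerate")

  set.seed(99)
  for (i in 1:20) {
    counts <- as.integer(sample(0:40, 11, replace = TRUE))
    if (length(unique(counts)) == 1L) next
    g <- split_high_low(mk(counts))
    med <- median(counts)
    expect_identical(length(g), 11L)
    expect_true(all(counts[g == "low"] <= med))
    if (any(g == "high")) expect_true(min(counts[g == "high"]) > med)
  }
})
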