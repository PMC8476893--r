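test_that("confusion metrics reproduce the worked cohort examples", {
  m <- metrics_from_counts(tp = 58, fn = 12, tn = 36, fp = 5)
  expect_equal(m$sensitivity_pct, 82.86)
  expect_equal(m$specificity_pct, 87.80)
  expect_equal(m$accuracy_pct, 84.68)
  expect_true(m$accuracy_ci[1] <= m$accuracy && m$accuracy <= m$accuracy_ci[2])

  expect_equal(metrics_from_counts(17, 2, 14, 9)$accuracy_pct, 73.81)
  perfect <- metrics_from_counts(10, 0, 10, 0)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)
  expect_equal(perfect$accuracy, 1)
})

test_that("confusion metrics from labelled predictions match counts and ignore order", {
  pred <- data.frame(sample_id = sprintf("s%d", 1:6),
                     label = c("responder", "responder", "non-responder",
                               "non-responder", "responder", "non-responder"),
                     stringsAsFactors = FALSE)
  truth <- setNames(c("responder", "non-responder", "non-responder",
                      "responder", "responder", "non-responder"),
                    pred$sample_id)
  m <- confusion_metrics(pred, truth)
  expect_identical(c(m$tp, m$fn, m$tn, m$fp), c(2L, 1L, 2L, 1L))
  perm <- c(4, 2, 6, 1, 3, 5)
  m2 <- confusion_metrics(pred[perm, ], truth)
  expect_identical(m[c("tp", "fn", "tn", "fp", "accuracy")],
                   m2[c("tp", "fn", "tn", "fp", "accuracy")])
  expect_error(confusion_metrics(pred[0, ], truth), "no predictions")
  expect_error(confusion_metrics(pred, truth[1:3]), "without a truth label")
})

test_that("Clopper-Pearson interval matches closed forms and test inversion", {
  expect_equal(unname(clopper_pearson_ci(0, 10)[1]), 0)
  expect_equal(unname(clopper_pearson_ci(10, 10)[2]), 1)
  # equal-tailed boundary closed form: (alpha/2)^(1/n), as binom.test reports
  expect_equal(unname(clopper_pearson_ci(10, 10)[1]), 0.025^(1 / 10),
               tolerance = 1e-10)
  expect_equal(unname(clopper_pearson_ci(10, 10)[1]), 0.6915,
               tolerance = 1e-4)

  # inversion oracle: bounds are the p where the one-sided exact tail hits
  # alpha/2, found by root-finding on the binomial CDF itself
  invert_ci <- function(k, n, alpha = 0.05) {
    low <- if (k == 0) 0 else
      uniroot(function(p) pbinom(k - 1, n, p, lower.tail = FALSE) - alpha / 2,
              c(1e-12, 1 - 1e-12), tol = 1e-12)$root
    high <- if (k == n) 1 else
      uniroot(function(p) pbinom(k, n, p) - alpha / 2,
              c(1e-12, 1 - 1e-12), tol = 1e-12)$root
    c(low, high)
  }
  for (n in c(1, 5, 17, 30)) {
    for (k in 0:n) {
      expect_equal(unname(clopper_pearson_ci(k, n)), invert_ci(k, n),
                   tolerance = 1e-6)
    }
  }
  expect_equal(unname(clopper_pearson_ci(94, 111)), invert_ci(94, 111),
               tolerance = 1e-6)
  expect_error(clopper_pearson_ci(5, 4), "successes")
})

test_that("AUC equals brute-force concordant-pair counting, ties at one half", {
  expect_equal(roc_auc(c(1, 2, 3, 10, 11, 12),
                       rep(c("non-responder", "responder"), each = 3))$auc, 1)
  set.seed(6)
  for (i in 1:25) {
    n <- sample(4:20, 1)
    truth <- sample(c("responder", "non-responder"), n, replace = TRUE)
    if (length(unique(truth)) < 2) next
    scores <- sample(seq(0, 1, 0.125), n, replace = TRUE)  # forces ties
    out <- roc_auc(scores, truth)
    expect_equal(out$auc, oracle_auc(scores, truth == "responder"))
    expect_true(out$ci[1] <= out$auc + 1e-12 && out$auc <= out$ci[2] + 1e-12)
  }
  # 4 vs 4 hand-listed case
  scores <- c(0.9, 0.8, 0.8, 0.3, 0.7, 0.8, 0.2, 0.1)
  truth <- rep(c("responder", "non-responder"), each = 4)
  expect_equal(roc_auc(scores, truth)$auc, oracle_auc(scores, truth == "responder"))
  expect_error(roc_auc(1:4, rep("responder", 4)), "both classes")
})

test_that("uninformative scores give AUC near one half", {
  set.seed(60)
  scores <- rnorm(400)
  truth <- rep(c("responder", "non-responder"), each = 200)
  expect_lt(abs(roc_auc(scores, truth)$auc - 0.5), 0.08)
})

test_that("signature gene DE: planted shifts detected, null rate calibrated", {
  set.seed(61)
  n <- 30
  truth <- rep(c("responder", "non-responder"), each = n)
  expr <- matrix(rnorm(1000 * 2 * n, 8, 1), nrow = 1000,
                 dimnames = list(sprintf("g%04d", 1:1000), sprintf("s%02d", 1:(2 * n))))
  expr["g0001", truth == "responder"] <- expr["g0001", truth == "responder"] + 2
  de <- signature_gene_de(expr, truth, rownames(expr))
  expect_lt(de$table$p_value[de$table$gene == "g0001"], 0.05)
  null_p <- de$table$p_value[-1]
  expect_lt(abs(mean(null_p < 0.05) - 0.05), 0.02)

  # zero variance in both groups is undefined
  expr["g0002", ] <- 3
  de2 <- signature_gene_de(expr, truth, c("g0001", "g0002"))
  expect_true(is.na(de2$table$p_value[de2$table$gene == "g0002"]))
  expect_identical(de2$n_significant, 1L)
  expect_error(signature_gene_de(expr, truth, "nope"), "absent")
})
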