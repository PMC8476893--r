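# Classification evaluation: confusion metrics with exact Clopper-Pearson
# intervals, ROC/AUC with DeLong confidence bounds, and the per-gene
# differential-expression summary for signature genes. Responder is the
# positive class throughout; proportions are also reported as percentages
# rounded to two decimals.

#' Confusion-matrix metrics from predictions and truth
#'
#' @param predictions Output of [predict_signature()], or any data.frame with
#'   `sample_id` and `label`.
#' @param truth Named vector of true labels (names = sample ids), or an
#'   unnamed vector aligned with `predictions` rows; coding per
#'   [normalize_response()].
#' @param conf_level Confidence level of the Clopper-Pearson accuracy interval.
#' @return List of class `evaluation_report`: counts `tp`, `fn`, `tn`, `fp`;
#'   `sensitivity`, `specificity`, `accuracy` (proportions);
#'   `accuracy_ci` (exact binomial); `*_pct` percentage versions rounded to
#'   two decimals.
#' @export
confusion_metrics <- function(predictions, truth, conf_level = 0.95) {
  if (nrow(predictions) == 0L) stop("no predictions to evaluate")
  if (!is.null(names(truth))) {
    idx <- match(predictions$sample_id, names(truth))
    if (anyNA(idx))
      stop("prediction(s) without a truth label: ",
           paste(utils::head(predictions$sample_id[is.na(idx)], 5L), collapse = ", "))
    truth <- truth[idx]
  } else if (length(truth) != nrow(predictions)) {
    stop("unnamed truth vector must align with the prediction rows")
  }
  truth <- normalize_response(truth)
  pred <- normalize_response(predictions$label)
  metrics_from_counts(tp = sum(pred == "responder" & truth == "responder"),
                      fn = sum(pred == "non-responder" & truth == "responder"),
                      tn = sum(pred == "non-responder" & truth == "non-responder"),
                      fp = sum(pred == "responder" & truth == "non-responder"),
                      conf_level = conf_level)
}

#' Confusion metrics from raw counts
#'
#' @param tp,fn,tn,fp Confusion counts (responder = positive class).
#' @param conf_level Confidence level for the Clopper-Pearson accuracy CI.
#' @return See [confusion_metrics()].
#' @export
metrics_from_counts <- function(tp, fn, tn, fp, conf_level = 0.95) {
  counts <- c(tp = tp, fn = fn, tn = tn, fp = fp)
  stopifnot(all(counts >= 0), sum(counts) >= 1)
  n <- tp + fn + tn + fp
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  acc <- (tp + tn) / n
  ci <- clopper_pearson_ci(tp + tn, n, level = conf_level)
  structure(list(tp = tp, fn = fn, tn = tn, fp = fp,
                 sensitivity = sens, specificity = spec, accuracy = acc,
                 accuracy_ci = ci,
                 sensitivity_pct = round(100 * sens, 2),
                 specificity_pct = round(100 * spec, 2),
                 accuracy_pct = round(100 * acc, 2)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("confusion: tp=%d fn=%d tn=%d fp=%d\n", x$tp, x$fn, x$tn, x$fp))
  cat(sprintf("sensitivity %.2f%%  specificity %.2f%%  accuracy %.2f%% (95%% CI %.2f-%.2f%%)\n",
              x$sensitivity_pct, x$specificity_pct, x$accuracy_pct,
              100 * x$accuracy_ci[1L], 100 * x$accuracy_ci[2L]))
  if (!is.null(x$auc))
    cat(sprintf("AUC %.3f (95%% CI %.3f-%.3f)\n", x$auc, x$auc_ci[1L], x$auc_ci[2L]))
  invisible(x)
}

#' Exact Clopper-Pearson binomial confidence interval
#'
#' The exact interval obtained by inverting the equal-tailed binomial test;
#' in closed form, beta-distribution quantiles. The lower bound is 0 when
#' `successes = 0` and the upper bound 1 when `successes = n`.
#'
#' @param successes,n Counts with `0 <= successes <= n`, `n >= 1`.
#' @param level Confidence level in (0, 1).
#' @return Numeric `c(low, high)`.
#' @export
clopper_pearson_ci <- function(successes, n, level = 0.95) {
  stopifnot(length(successes) == 1L, length(n) == 1L, n >= 1,
            successes >= 0, successes <= n, level > 0, level < 1)
  a <- (1 - level) / 2
  low <- if (successes == 0) 0 else stats::qbeta(a, successes, n - successes + 1)
  high <- if (successes == n) 1 else stats::qbeta(1 - a, successes + 1, n - successes)
  c(low = low, high = high)
}

#' ROC AUC with DeLong confidence interval
#'
#' The area under the ROC curve traced over all score thresholds, computed by
#' the midrank (Mann-Whitney) formula: the probability that a random
#' responder's score exceeds a random non-responder's, ties counted one half.
#' The confidence interval is DeLong's.
#'
#' @param scores Numeric scores (higher = more responder-like), e.g. the
#'   response ratio from [predict_signature()].
#' @param truth Labels per [normalize_response()]; both classes required.
#' @param conf_level Confidence level of the DeLong interval.
#' @return List: `auc`, `ci` (length-2), `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, truth, conf_level = 0.95) {
  truth <- normalize_response(truth)
  stopifnot(length(scores) == length(truth), all(is.finite(scores)))
  pos <- truth == "responder"
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) stop("roc_auc needs both classes present")
  r <- rank(scores)                       # midranks handle ties
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  roc <- pROC::roc(response = factor(truth, levels = c("non-responder", "responder")),
                   predictor = scores, quiet = TRUE, direction = "<")
  # pROC warns that a degenerate (AUC = 1) DeLong interval is 1-1; that is fine
  ci <- suppressWarnings(
    as.numeric(pROC::ci.auc(roc, conf.level = conf_level, method = "delong")))[c(1L, 3L)]
  if (!all(is.finite(ci))) ci <- c(auc, auc)  # zero DeLong variance
  ci <- pmin(1, pmax(0, ci))
  list(auc = auc, ci = c(low = ci[1L], high = ci[2L]), n_pos = n1, n_neg = n0)
}

#' Differential expression of signature genes between response classes
#'
#' Per-gene Welch two-sample t-test (responders vs non-responders) on the log2
#' values, with a count of genes below the significance threshold. A gene with
#' zero variance in both groups has no defined t statistic and is reported as
#' `NA`.
#'
#' @param expr Genes-by-samples log2 expression matrix.
#' @param truth Response labels aligned with the columns (or named by sample).
#' @param genes Gene symbols to test (present in `expr`).
#' @param alpha Significance threshold for the count (default 0.05).
#' @return List: `table` (data.frame `gene`, `mean_resp`, `mean_nonresp`,
#'   `p_value`) and `n_significant`.
#' @export
signature_gene_de <- function(expr, truth, genes, alpha = 0.05) {
  check_expression(expr)
  if (!is.null(names(truth))) truth <- truth[colnames(expr)]
  truth <- normalize_response(truth)
  miss <- setdiff(genes, rownames(expr))
  if (length(miss)) stop("gene(s) absent from expression matrix: ",
                         paste(utils::head(miss, 5L), collapse = ", "))
  pos <- truth == "responder"
  res <- vapply(genes, function(g) {
    x <- expr[g, pos]; y <- expr[g, !pos]
    p <- if (stats::sd(x) == 0 && stats::sd(y) == 0) {
      NA_real_
    } else {
      stats::t.test(x, y, var.equal = FALSE)$p.value
    }
    c(mean(x), mean(y), p)
  }, numeric(3))
  tab <- data.frame(gene = genes, mean_resp = res[1L, ], mean_nonresp = res[2L, ],
                    p_value = res[3L, ], stringsAsFactors = FALSE, row.names = NULL)
  list(table = tab, n_significant = sum(tab$p_value < alpha, na.rm = TRUE))
}
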