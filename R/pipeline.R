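# End-to-end workflows chaining the pipeline stages: discovery
# (screen -> rank -> select) and validation (predict -> evaluate ->
# optional survival stratification). The numbered scripts under analysis/
# are thin drivers over these two functions.

#' Discover a gene-pair signature on a training cohort
#'
#' Chains the three discovery stages: reversal-pair screening (exact binomial
#' test in each response class), random-forest mean-decrease-Gini ranking of
#' the binary pair features, and best top-N majority-vote selection. All
#' randomness flows from `config$seed`.
#'
#' @param expr Training genes-by-samples log2 expression matrix.
#' @param pheno Phenotype data.frame with `sample_id` and `response`.
#' @param alpha Binomial screening level (default 0.05).
#' @param config An [rf_config()].
#' @param n_max Selection sweep cap (see [select_best_top_n()]).
#' @param ... Further arguments to [find_reversal_pairs()] (e.g.
#'   `candidate_pairs`, `max_genes`).
#' @return List: `signature`, `curve` (N vs training accuracy), `ranked`,
#'   `pairs` (screened reversal records), `report` (training
#'   [confusion_metrics()] with AUC), `provenance` (alpha + resolved RF
#'   config).
#' @export
run_discover <- function(expr, pheno, alpha = 0.05, config = rf_config(),
                         n_max = NULL, ...) {
  pairs <- with_stage("screen", find_reversal_pairs(expr, pheno, alpha = alpha, ...))
  if (nrow(pairs) == 0L) stop("[screen] no reversal pairs at alpha = ", alpha)
  labs <- match_labels(expr, pheno)
  feats <- with_stage("rank", encode_pairs(expr, pairs))
  ranked <- with_stage("rank", rank_by_mdg(feats, labs, config = config))
  sig <- with_stage("select", select_best_top_n(ranked, expr, labs, n_max = n_max))
  pred <- predict_signature(expr, sig)
  report <- confusion_metrics(pred, stats::setNames(labs, colnames(expr)))
  auc <- roc_auc(pred$score, labs)
  report$auc <- auc$auc
  report$auc_ci <- auc$ci
  list(signature = sig, curve = attr(sig, "curve"), ranked = ranked,
       pairs = pairs, report = report,
       provenance = c(list(alpha = alpha), attr(ranked, "config"),
                      list(n_selected = nrow(sig))))
}

#' Validate a signature on an independent cohort
#'
#' Applies a signature (majority vote + response-ratio score) and, when truth
#' labels are available, evaluates it; when follow-up columns are present,
#' also stratifies survival -- by predicted label when response labels exist,
#' otherwise by the median split on response-pair counts.
#'
#' @param expr Genes-by-samples log2 expression matrix of the cohort.
#' @param signature Signature data.frame, e.g. [load_published_signature()].
#' @param pheno Optional phenotype data.frame (`response` and/or
#'   `dfs_time`/`dfs_event`, plus Cox covariates).
#' @param covariates Covariate names passed to [cox_adjusted()] when survival
#'   columns are present (defaults to those of `stage`, `age`, `gender` that
#'   exist in `pheno`).
#' @return List: `predictions`; `report` (with AUC) when labels are present;
#'   `survival` (list `km`, `cox`, `grouping`) when follow-up is present.
#' @export
run_validate <- function(expr, signature, pheno = NULL, covariates = NULL) {
  pred <- with_stage("predict", predict_signature(expr, signature))
  out <- list(predictions = pred)
  if (is.null(pheno)) return(out)

  has_resp <- "response" %in% colnames(pheno) &&
    any(!is.na(pheno$response[match(pred$sample_id, pheno$sample_id)]))
  if (has_resp) {
    truth <- stats::setNames(pheno$response, pheno$sample_id)[pred$sample_id]
    keep <- !is.na(truth)
    report <- with_stage("evaluate",
                         confusion_metrics(pred[keep, , drop = FALSE], truth[keep]))
    auc <- roc_auc(pred$score[keep], truth[keep])
    report$auc <- auc$auc
    report$auc_ci <- auc$ci
    out$report <- report
  }

  if (all(c("dfs_time", "dfs_event") %in% colnames(pheno))) {
    grouping <- if (has_resp) {
      stats::setNames(pred$label, pred$sample_id)
    } else {
      split_high_low(pred)
    }
    ds <- with_stage("survival", survival_dataset(grouping, pheno))
    km <- with_stage("survival", km_logrank(ds))
    if (is.null(covariates))
      covariates <- intersect(c("stage", "age", "gender"), colnames(pheno))
    covariates <- covariates[!vapply(covariates, function(v) anyNA(ds[[v]]), logical(1))]
    cox <- tryCatch(with_stage("survival", cox_adjusted(ds, covariates)),
                    error = function(e) {
                      warning(conditionMessage(e)); NULL
                    })
    out$survival <- list(km = km, cox = cox, grouping = grouping)
  }
  out
}

# re-raise any stage error prefixed with the stage name
with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    msg <- conditionMessage(e)
    if (startsWith(msg, "[")) stop(e)
    stop("[", stage, "] ", msg, call. = FALSE)
  })
}
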