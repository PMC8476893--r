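# Applying a gene-pair signature: response-pair counting, response-ratio
# score, majority-vote labels, and the groupings built on them.

#' Apply a gene-pair signature to an expression matrix
#'
#' For every sample, counts the signature pairs in response orientation
#' (`gene_a > gene_b` within the sample). A sample is labelled responder on a
#' strict majority of its evaluable pairs; an exact tie (possible only for an
#' even evaluable count) is labelled non-responder, so a responder call always
#' rests on majority evidence. Pairs with either gene absent from the matrix
#' (cross-platform application) are dropped and excluded from the evaluable
#' count.
#'
#' @param expr Genes-by-samples log2 expression matrix.
#' @param signature Signature data.frame (`gene_a`, `gene_b`), e.g. from
#'   [load_published_signature()] or [select_best_top_n()].
#' @return data.frame, one row per sample: `sample_id`, `n_response_pairs`,
#'   `n_evaluable_pairs`, `score` (= response ratio, in `[0, 1]`), `label`.
#' @export
predict_signature <- function(expr, signature) {
  check_expression(expr)
  if (is.null(signature) || nrow(signature) == 0L) stop("empty signature")
  genes <- unique(c(signature$gene_a, signature$gene_b))
  absent <- setdiff(genes, rownames(expr))
  if (length(absent) > 0.2 * length(genes))
    warning(length(absent), " of ", length(genes),
            " signature genes absent from the expression matrix (> 20%)")
  evaluable <- !(signature$gene_a %in% absent | signature$gene_b %in% absent)
  if (!any(evaluable))
    stop("no evaluable signature pairs: all pairs have a missing gene")
  feats <- encode_pairs(expr, signature[evaluable, , drop = FALSE])
  n_eval <- sum(evaluable)
  n_resp <- colSums(feats)
  data.frame(sample_id = colnames(expr),
             n_response_pairs = as.integer(n_resp),
             n_evaluable_pairs = n_eval,
             score = n_resp / n_eval,
             label = ifelse(2 * n_resp > n_eval, "responder", "non-responder"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Compare response-ratio scores between two groups
#'
#' Mean response ratio per group plus a Welch (unequal-variance) two-sample
#' t-test, as used to contrast chemoradiation-sensitive and -resistant cell
#' lines.
#'
#' @param predictions Output of [predict_signature()].
#' @param grouping Binary vector (logical, 0/1, or two-level factor/character)
#'   aligned with `predictions` rows; `TRUE`/1/first level names group 1.
#' @return List: `group_means` (named length-2), `mean_difference`
#'   (group1 - group2), `p_value` (Welch t; `NA` with a warning when either
#'   group has fewer than 2 scores).
#' @export
response_ratio_by_group <- function(predictions, grouping) {
  stopifnot(nrow(predictions) == length(grouping))
  if (is.logical(grouping)) grouping <- ifelse(grouping, "group1", "group2")
  if (is.numeric(grouping)) grouping <- ifelse(grouping == 1, "group1", "group2")
  grouping <- as.character(grouping)
  lev <- unique(grouping)
  if (length(lev) != 2L) stop("grouping must have exactly 2 non-empty groups")
  s1 <- predictions$score[grouping == lev[1L]]
  s2 <- predictions$score[grouping == lev[2L]]
  means <- stats::setNames(c(mean(s1), mean(s2)), lev)
  p <- NA_real_
  if (length(s1) < 2L || length(s2) < 2L) {
    warning("a group has fewer than 2 samples; t-test skipped")
  } else if (stats::sd(s1) == 0 && stats::sd(s2) == 0) {
    p <- if (means[1L] == means[2L]) 1 else 0
  } else {
    p <- stats::t.test(s1, s2, var.equal = FALSE)$p.value
  }
  list(group_means = means, mean_difference = unname(means[1L] - means[2L]),
       p_value = p)
}

#' Split samples into high- and low-response groups at the median
#'
#' High-response means a response-pair count strictly above the cohort median;
#' counts at the median go to the low group. Used for survival stratification
#' of cohorts that lack pathological response labels.
#'
#' @param predictions Output of [predict_signature()].
#' @return Character vector (`"high"` / `"low"`) named by sample id.
#' @export
split_high_low <- function(predictions) {
  if (nrow(predictions) < 2L) stop("need at least 2 samples to split")
  counts <- predictions$n_response_pairs
  if (length(unique(counts)) == 1L)
    stop("degenerate split: all samples have identical response-pair counts")
  med <- stats::median(counts)
  stats::setNames(ifelse(counts > med, "high", "low"), predictions$sample_id)
}
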