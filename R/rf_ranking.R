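# Random-forest importance ranking of reversal pairs.
#
# Each reversal pair becomes one binary feature per sample: 1 when the sample
# shows the pair's response orientation. Binary REO indicators are the only
# encoding that preserves exactly the rank information the screen used, so the
# forest sees nothing a batch effect could distort.

#' Random forest configuration
#'
#' @param ntree Number of trees (positive integer).
#' @param mtry Variables tried at each split; `NULL` means the randomForest
#'   classification default, `floor(sqrt(p))`, resolved at fit time.
#' @param seed Integer RNG seed; recorded, together with the fitting library
#'   version, in the ranking's metadata. Forest fits are reproducible given
#'   the same seed and library version only.
#' @return An `rf_config` list.
#' @export
rf_config <- function(ntree = 2500L, mtry = NULL, seed = 20200914L) {
  stopifnot(length(ntree) == 1L, ntree >= 1L)
  if (!is.null(mtry)) stopifnot(length(mtry) == 1L, mtry >= 1L)
  structure(list(ntree = as.integer(ntree),
                 mtry = if (is.null(mtry)) NULL else as.integer(mtry),
                 seed = as.integer(seed)),
            class = "rf_config")
}

#' Encode reversal pairs as a binary pair-by-sample feature matrix
#'
#' Entry (p, s) is 1 iff sample s shows pair p's response orientation, i.e.
#' `expr[gene_a, s] > expr[gene_b, s]` for records normalised by
#' [find_reversal_pairs()]. Invariant to strictly increasing per-sample
#' transforms of `expr`.
#'
#' @param expr Genes-by-samples log2 expression matrix.
#' @param pairs data.frame with `gene_a`, `gene_b` columns (reversal records or
#'   a signature).
#' @return Integer 0/1 matrix, pairs x samples; rownames `"gene_a>gene_b"`.
#' @export
encode_pairs <- function(expr, pairs) {
  check_expression(expr)
  ia <- match(pairs$gene_a, rownames(expr))
  ib <- match(pairs$gene_b, rownames(expr))
  if (anyNA(ia) || anyNA(ib)) {
    miss <- unique(c(pairs$gene_a[is.na(ia)], pairs$gene_b[is.na(ib)]))
    stop("gene(s) absent from expression matrix: ", paste(miss, collapse = ", "))
  }
  out <- (expr[ia, , drop = FALSE] > expr[ib, , drop = FALSE]) + 0L
  rownames(out) <- pair_ids(pairs)
  out
}

pair_ids <- function(pairs) paste0(pairs$gene_a, ">", pairs$gene_b)

#' Rank pairs by random-forest mean decrease Gini
#'
#' Fits a classification random forest to the binary pair features and ranks
#' every pair by its mean decrease Gini (MDG) importance, the total
#' Gini-impurity reduction attributable to the feature averaged over trees.
#' Ties in MDG are broken lexicographically by pair id so the ranking is a
#' deterministic function of the fitted forest.
#'
#' @param features Binary pairs-by-samples matrix from [encode_pairs()].
#' @param labels Response labels for the samples (columns), any coding accepted
#'   by [normalize_response()].
#' @param config An [rf_config()].
#' @return data.frame `rank`, `gene_a`, `gene_b`, `mdg`, sorted by `mdg`
#'   descending, with the resolved configuration (ntree, mtry, seed, library
#'   version) in `attr(, "config")`.
#' @export
rank_by_mdg <- function(features, labels, config = rf_config()) {
  stopifnot(inherits(config, "rf_config"))
  labs <- normalize_response(labels)
  if (length(labs) != ncol(features))
    stop("labels length must equal the number of samples")
  if (length(unique(labs)) < 2L) stop("labels contain a single class")
  if (min(table(labs)) < 2L) stop("need at least 2 samples per class")
  p <- nrow(features)
  mtry <- if (is.null(config$mtry)) max(1L, floor(sqrt(p))) else config$mtry
  if (mtry > p) stop("mtry (", mtry, ") exceeds the number of features (", p, ")")

  # constant features admit no split and have zero Gini reduction by
  # definition; exclude them from the fit
  varying <- apply(features, 1L, function(r) any(r != r[1L]))
  mdg <- rep(0, p)
  if (any(varying)) {
    x <- as.data.frame(t(features[varying, , drop = FALSE]))
    colnames(x) <- paste0("f", seq_len(ncol(x)))
    y <- factor(labs, levels = c("non-responder", "responder"))
    set.seed(config$seed)
    fit <- randomForest::randomForest(x = x, y = y, ntree = config$ntree,
                                      mtry = min(mtry, ncol(x)))
    imp <- fit$importance[, "MeanDecreaseGini"]
    stopifnot(all(is.finite(imp)), all(imp >= -1e-12))
    mdg[varying] <- pmax(unname(imp), 0)
  }

  ids <- rownames(features)
  ord <- order(-mdg, ids, method = "radix")
  split_ids <- strsplit(ids[ord], ">", fixed = TRUE)
  out <- data.frame(rank = seq_len(p),
                    gene_a = vapply(split_ids, `[`, "", 1L),
                    gene_b = vapply(split_ids, `[`, "", 2L),
                    mdg = unname(mdg[ord]),
                    stringsAsFactors = FALSE)
  attr(out, "config") <- list(ntree = config$ntree, mtry = mtry,
                              seed = config$seed,
                              library = paste0("randomForest ",
                                               utils::packageVersion("randomForest")))
  out
}
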