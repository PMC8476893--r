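# Relative expression orderings (REOs) and reversal-pair screening.
#
# A pair (a, b) is FORWARD in a sample when the expression of a strictly
# exceeds that of b. Because the comparison happens within one sample, the
# orientation is invariant to any strictly increasing transform of that
# sample's values -- the property that makes REO signatures robust to batch
# effects and normalisation choices.

#' Within-sample relative expression ordering of two genes
#'
#' @param expr_a,expr_b Finite numeric vectors (recycled) of expression values
#'   on any common within-sample scale.
#' @return Character vector: `"forward"` where `expr_a > expr_b` strictly,
#'   `"reverse"` otherwise. Ties count as reverse ("not a > b"), keeping the
#'   orientation binary; ties have measure zero on continuous data.
#' @export
orientation <- function(expr_a, expr_b) {
  if (!all(is.finite(expr_a)) || !all(is.finite(expr_b)))
    stop("orientation() requires finite expression values")
  ifelse(expr_a > expr_b, "forward", "reverse")
}

#' One-sided exact binomial majority test
#'
#' Tail probability that a fair coin shows the observed majority or a larger
#' one: `P(X >= max(k, n - k))` with `X ~ Binomial(n, 1/2)`. Used to ask
#' whether one orientation of a gene pair is stably dominant within a class.
#' The exact tail is used for all n; no normal approximation.
#'
#' @param k Number of samples showing the orientation of interest (vectorised).
#' @param n Number of samples in the class.
#' @param two_sided If `TRUE`, doubles the tail (capped at 1). The default is
#'   the one-sided tail on the dominant orientation.
#' @return p-value(s) in `[0, 1]`.
#' @export
binomial_majority_p <- function(k, n, two_sided = FALSE) {
  if (any(n < 1L)) stop("binomial_majority_p requires n >= 1")
  if (any(k < 0L) || any(k > n)) stop("binomial_majority_p requires 0 <= k <= n")
  m <- pmax(k, n - k)
  p <- stats::pbinom(m - 1L, n, 0.5, lower.tail = FALSE)
  if (two_sided) p <- pmin(1, 2 * p)
  p
}

# all unordered gene pairs as a 2-column index matrix (i < j)
all_gene_pairs <- function(g) {
  if (g < 2L) return(matrix(integer(0), ncol = 2L))
  idx <- which(upper.tri(matrix(0, g, g)), arr.ind = TRUE)
  cbind(idx[, "row"], idx[, "col"])
}

# FORWARD counts per pair within one sample set: K[i] = #{s : X[a_i,s] > X[b_i,s]}
forward_counts <- function(expr, pairs_idx, sample_idx) {
  a <- pairs_idx[, 1L]
  b <- pairs_idx[, 2L]
  k <- integer(nrow(pairs_idx))
  for (s in sample_idx) {
    col <- expr[, s]
    k <- k + (col[a] > col[b])
  }
  k
}

#' Screen reversal gene pairs between responders and non-responders
#'
#' A reversal pair is one whose dominant within-sample orientation differs
#' between the two classes, with the dominance statistically stable in *each*
#' class separately (exact binomial test against 1/2, `p < alpha` in both).
#' Emitted records are normalised so that the response orientation is
#' `gene_a > gene_b`, i.e. the forward orientation is the one dominant in
#' responders, and are ordered lexicographically by (gene_a, gene_b).
#'
#' @param expr Genes-by-samples log2 expression matrix (see
#'   [read_expression()]).
#' @param pheno Phenotype data.frame with `sample_id` and `response` covering
#'   every column of `expr`.
#' @param alpha Per-class significance level of the binomial test, in (0, 1).
#' @param candidate_pairs Optional data.frame (`gene_a`, `gene_b`) restricting
#'   the screen; by default all `g*(g-1)/2` unordered pairs are enumerated.
#' @param two_sided Use a two-sided binomial test in each class (the default is
#'   the one-sided tail on the dominant orientation).
#' @param max_genes Ceiling on the gene count for full pairwise enumeration
#'   (default 2000, about 2M pairs); raise explicitly for larger universes, or
#'   pass `prefilter_top_variance` / `candidate_pairs`.
#' @param prefilter_top_variance Optional integer: before enumeration, keep
#'   only this many genes by descending variance across samples. Off by
#'   default.
#' @return data.frame with one row per emitted pair: `gene_a`, `gene_b`,
#'   `k_resp`, `n_resp`, `k_nonresp`, `n_nonresp`, `p_resp`, `p_nonresp`.
#'   `k_*` count samples in the (normalised) forward orientation.
#' @export
find_reversal_pairs <- function(expr, pheno, alpha = 0.05,
                                candidate_pairs = NULL, two_sided = FALSE,
                                max_genes = 2000L,
                                prefilter_top_variance = NULL) {
  check_expression(expr)
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)")
  labs <- match_labels(expr, pheno)
  resp <- which(labs == "responder")
  nonresp <- which(labs == "non-responder")
  if (length(resp) < 2L || length(nonresp) < 2L)
    stop("need at least 2 samples per class (have ", length(resp), " responders, ",
         length(nonresp), " non-responders)")

  if (!is.null(prefilter_top_variance) && is.null(candidate_pairs)) {
    v <- apply(expr, 1L, stats::var)
    keep <- order(v, decreasing = TRUE)[seq_len(min(prefilter_top_variance, nrow(expr)))]
    expr <- expr[sort(keep), , drop = FALSE]
  }

  if (is.null(candidate_pairs)) {
    g <- nrow(expr)
    if (g > max_genes)
      stop("full pairwise enumeration over ", g, " genes exceeds max_genes = ",
           max_genes, "; raise max_genes, supply candidate_pairs, or set ",
           "prefilter_top_variance")
    pairs_idx <- all_gene_pairs(g)
  } else {
    ia <- match(candidate_pairs$gene_a, rownames(expr))
    ib <- match(candidate_pairs$gene_b, rownames(expr))
    bad <- is.na(ia) | is.na(ib)
    if (any(bad)) {
      miss <- unique(c(candidate_pairs$gene_a[is.na(ia)], candidate_pairs$gene_b[is.na(ib)]))
      stop("candidate pair gene(s) absent from expression matrix: ",
           paste(utils::head(miss, 5L), collapse = ", "))
    }
    pairs_idx <- cbind(ia, ib)
  }
  if (nrow(pairs_idx) == 0L) return(empty_reversal_records())

  k_resp <- forward_counts(expr, pairs_idx, resp)
  k_non <- forward_counts(expr, pairs_idx, nonresp)
  n_resp <- length(resp)
  n_non <- length(nonresp)

  # dominant orientation per class: forward iff strict majority of samples
  dom_resp_fwd <- 2L * k_resp > n_resp
  dom_non_fwd <- 2L * k_non > n_non
  p_resp <- binomial_majority_p(k_resp, n_resp, two_sided = two_sided)
  p_non <- binomial_majority_p(k_non, n_non, two_sided = two_sided)
  keep <- (dom_resp_fwd != dom_non_fwd) & (p_resp < alpha) & (p_non < alpha)
  if (!any(keep)) return(empty_reversal_records())

  a <- pairs_idx[keep, 1L]
  b <- pairs_idx[keep, 2L]
  kr <- k_resp[keep]
  kn <- k_non[keep]
  # normalise: store as gene_a > gene_b in responders
  flip <- !dom_resp_fwd[keep]
  tmp <- a[flip]; a[flip] <- b[flip]; b[flip] <- tmp
  kr[flip] <- n_resp - kr[flip]
  kn[flip] <- n_non - kn[flip]

  out <- data.frame(gene_a = rownames(expr)[a], gene_b = rownames(expr)[b],
                    k_resp = kr, n_resp = n_resp,
                    k_nonresp = kn, n_nonresp = n_non,
                    p_resp = p_resp[keep], p_nonresp = p_non[keep],
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene_a, out$gene_b, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_reversal_records <- function() {
  data.frame(gene_a = character(0), gene_b = character(0),
             k_resp = integer(0), n_resp = integer(0),
             k_nonresp = integer(0), n_nonresp = integer(0),
             p_resp = numeric(0), p_nonresp = numeric(0),
             stringsAsFactors = FALSE)
}

# map phenotype response labels onto the expression columns, erroring on
# unlabeled samples
match_labels <- function(expr, pheno) {
  if (!all(c("sample_id", "response") %in% colnames(pheno)))
    stop("phenotype table must have sample_id and response columns")
  idx <- match(colnames(expr), pheno$sample_id)
  if (anyNA(idx))
    stop("sample(s) without phenotype row: ",
         paste(utils::head(colnames(expr)[is.na(idx)], 5L), collapse = ", "))
  labs <- normalize_response(pheno$response[idx])
  if (anyNA(labs))
    stop("sample(s) with missing response label: ",
         paste(utils::head(colnames(expr)[is.na(labs)], 5L), collapse = ", "))
  labs
}
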