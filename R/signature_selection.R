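# Best top-N selection: sweep prefixes of the MDG ranking and keep the
# smallest prefix maximising resubstitution majority-vote accuracy.

#' Select the best top-N gene pairs as a signature
#'
#' For each N in 1..n_max, classifies every training sample by majority vote
#' over the top-N ranked pairs (responder iff more than N/2 pairs show the
#' response orientation) and computes training accuracy; returns the smallest
#' N attaining the maximum. Only prefixes of the ranking are considered, and
#' selection is deterministic given the ranking.
#'
#' @param ranked Ranking data.frame from [rank_by_mdg()] (`rank`, `gene_a`,
#'   `gene_b`, ...).
#' @param expr Training genes-by-samples log2 expression matrix.
#' @param labels Training response labels (coding per [normalize_response()]).
#' @param n_max Largest prefix to sweep; default `min(500, nrow(ranked))` --
#'   set to `nrow(ranked)` to sweep the full ranking.
#' @return Signature data.frame (`rank`, `gene_a`, `gene_b`) of the selected N
#'   pairs, with attributes: `curve` (data.frame `n`, `accuracy` for the full
#'   sweep), `best_accuracy`, and `provenance` (the ranking's config plus
#'   `n_max`).
#' @export
select_best_top_n <- function(ranked, expr, labels, n_max = NULL) {
  if (is.null(ranked) || nrow(ranked) == 0L) stop("empty ranking")
  if (is.null(n_max)) n_max <- min(500L, nrow(ranked))
  if (n_max > nrow(ranked)) stop("n_max exceeds the ranking length")
  labs <- normalize_response(labels)
  if (length(labs) != ncol(expr)) stop("labels length must equal sample count")

  top <- ranked[seq_len(n_max), , drop = FALSE]
  feats <- encode_pairs(expr, top)                 # n_max x samples, 0/1
  votes <- apply(feats, 2L, cumsum)                # votes[N, s] among top N
  if (n_max == 1L) votes <- matrix(votes, nrow = 1L)
  n_seq <- seq_len(n_max)
  pred_resp <- votes > n_seq / 2                   # strict majority, recycled by column
  truth_resp <- matrix(labs == "responder", nrow = n_max, ncol = length(labs),
                       byrow = TRUE)
  accuracy <- unname(rowMeans(pred_resp == truth_resp))

  best_n <- which.max(accuracy)                    # first (smallest) maximiser
  sig <- top[seq_len(best_n), c("gene_a", "gene_b"), drop = FALSE]
  sig <- data.frame(rank = seq_len(best_n), sig, stringsAsFactors = FALSE)
  rownames(sig) <- NULL
  attr(sig, "curve") <- data.frame(n = n_seq, accuracy = accuracy)
  attr(sig, "best_accuracy") <- accuracy[best_n]
  attr(sig, "provenance") <- c(attr(ranked, "config"), list(n_max = n_max))
  check_signature(sig)
  sig
}
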