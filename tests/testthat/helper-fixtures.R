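# Shared fixture builders: everything is generated in code at test time.

# small deterministic expression matrix
toy_expr <- function(genes = c("A", "B", "C"), samples = c("s1", "s2"),
                     seed = 42L) {
  set.seed(seed)
  matrix(round(stats::runif(length(genes) * length(samples), 4, 12), 3),
         nrow = length(genes), dimnames = list(genes, samples))
}

toy_pheno <- function(sample_ids, response) {
  data.frame(sample_id = sample_ids, response = response,
             stringsAsFactors = FALSE)
}

# cohort with one planted pair: forward in k_resp of the responders and
# k_non of the non-responders, deterministic placement
planted_pair_expr <- function(k_resp, n_resp, k_non, n_non, seed = 1L) {
  set.seed(seed)
  n <- n_resp + n_non
  ids <- sprintf("s%02d", seq_len(n))
  fwd <- c(seq_len(n_resp) <= k_resp, seq_len(n_non) <= k_non)
  a <- ifelse(fwd, 8, 6) + stats::runif(n, 0, 0.5)
  b <- ifelse(fwd, 6, 8) + stats::runif(n, 0, 0.5)
  expr <- rbind(GA = a, GB = b)
  colnames(expr) <- ids
  pheno <- toy_pheno(ids, rep(c("responder", "non-responder"), c(n_resp, n_non)))
  list(expr = expr, pheno = pheno)
}

# a strictly increasing transform applied per sample, deterministic per column
monotone_distort <- function(expr) {
  for (s in seq_len(ncol(expr))) {
    f <- switch((s %% 3L) + 1L,
                function(x) 2 * x + 7,
                function(x) x^3,
                function(x) exp(x / 4))
    expr[, s] <- f(expr[, s])
  }
  expr
}

# brute-force binomial majority tail: sum of C(n,i)/2^n over i >= max(k, n-k)
oracle_binom_tail <- function(k, n) {
  m <- max(k, n - k)
  sum(choose(n, m:n)) / 2^n
}

# brute-force AUC: concordant-pair fraction with ties counted one half
oracle_auc <- function(scores, positive) {
  sp <- scores[positive]
  sn <- scores[!positive]
  tot <- 0
  for (x in sp) for (y in sn) tot <- tot + (x > y) + 0.5 * (x == y)
  tot / (length(sp) * length(sn))
}
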