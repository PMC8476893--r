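# Synthetic cohorts with the statistical structure the pipeline assumes:
# two response classes, planted reversal pairs at configurable per-class
# stability, a majority of null gene pairs, per-sample strictly monotone
# batch distortions, and survival whose hazard depends on true response.
#
# Planting works by value swapping: both genes of a planted pair are drawn
# (baseline + Gaussian noise) and then, per sample, swapped when needed so
# the pair shows its class-dominant orientation with exactly the configured
# probability. Swapping controls orientation frequencies exactly -- the
# quantity the binomial screen models -- without disturbing the marginal
# value distribution.

#' Simulation configuration
#'
#' @param n_genes Total genes (planted pair genes are the first
#'   `2 * n_planted_pairs`).
#' @param n_resp,n_nonresp Samples per class.
#' @param n_planted_pairs Number of true reversal pairs (disjoint gene pairs).
#' @param stability_resp,stability_nonresp Probability, in (0, 1], that a
#'   planted pair shows its class-dominant orientation: forward
#'   (`gene_a > gene_b`) in responders with `stability_resp`, reverse in
#'   non-responders with `stability_nonresp`.
#' @param noise_sd Gaussian noise SD added to every log2 value (> 0).
#' @param batch Apply a per-sample strictly increasing distortion drawn from a
#'   parameterised family (affine, power, logistic warp) -- a surrogate for
#'   batch / normalisation differences that REO analysis must ignore.
#' @param hr_true Hazard ratio of responders vs non-responders for simulated
#'   DFS (> 0).
#' @param censor_rate Probability that a sample's follow-up is censored.
#' @param seed Integer seed; identical configs with identical seeds give
#'   bit-identical cohorts.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes = 500L, n_resp = 40L, n_nonresp = 40L,
                       n_planted_pairs = 50L, stability_resp = 0.95,
                       stability_nonresp = 0.95, noise_sd = 0.5,
                       batch = FALSE, hr_true = 0.25, censor_rate = 0.3,
                       seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), n_resp = as.integer(n_resp),
              n_nonresp = as.integer(n_nonresp),
              n_planted_pairs = as.integer(n_planted_pairs),
              stability_resp = stability_resp,
              stability_nonresp = stability_nonresp,
              noise_sd = noise_sd, batch = isTRUE(batch),
              hr_true = hr_true, censor_rate = censor_rate,
              seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_genes >= 2L, n_resp >= 1L, n_nonresp >= 1L,
              n_planted_pairs >= 0L, 2L * n_planted_pairs <= n_genes,
              stability_resp > 0, stability_resp <= 1,
              stability_nonresp > 0, stability_nonresp <= 1,
              noise_sd > 0, hr_true > 0, censor_rate >= 0, censor_rate <= 1)
  })
  structure(cfg, class = "sim_config")
}

# one strictly increasing transform per sample, drawn from a seeded family;
# domain is positive log2 expression values
draw_batch_transform <- function() {
  kind <- sample(c("affine", "power", "logistic"), 1L)
  switch(kind,
    affine = {
      a <- stats::runif(1, 0.5, 3); b <- stats::runif(1, -2, 7)
      function(x) a * x + b
    },
    power = {
      c <- stats::runif(1, 0.5, 2.5)
      function(x) x^c
    },
    logistic = {
      k <- stats::runif(1, 0.2, 1); x0 <- stats::runif(1, 6, 10)
      function(x) 30 / (1 + exp(-k * (x - x0)))
    })
}

#' Simulate a two-class cohort with planted reversal pairs
#'
#' Baseline log2 expression is drawn per gene (uniform on 4..12; the two genes
#' of a planted pair share one baseline and one per-sample noise draw, with a
#' small within-pair gap, so class information lives only in their joint
#' ordering); per-sample
#' Gaussian noise is added; each planted pair's orientation is then forced to
#' its class-dominant direction with the configured stability by swapping the
#' two values when needed; finally an optional strictly increasing batch
#' distortion is applied per sample. All remaining genes are exchangeable
#' noise, so every non-planted pair is null.
#'
#' @param config A [sim_config()].
#' @return List: `expr` (genes x samples log2 matrix), `pheno` (data.frame
#'   `sample_id`, `response`, `dfs_time`, `dfs_event`), `truth` (data.frame
#'   `gene_a`, `gene_b` of planted pairs, response orientation
#'   `gene_a > gene_b`).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  g <- config$n_genes
  n <- config$n_resp + config$n_nonresp
  gene_ids <- sprintf("G%04d", seq_len(g))
  sample_ids <- sprintf("S%03d", seq_len(n))
  is_resp <- c(rep(TRUE, config$n_resp), rep(FALSE, config$n_nonresp))

  baseline <- stats::runif(g, 4, 12)
  truth <- empty_truth()
  if (config$n_planted_pairs > 0L) {
    ia <- 2L * seq_len(config$n_planted_pairs) - 1L
    ib <- ia + 1L
    # the two genes of a planted pair share a baseline: class information
    # lives in the joint ordering only, not in either gene's marginal level
    baseline[ib] <- baseline[ia]
  }
  expr <- matrix(stats::rnorm(g * n, mean = baseline, sd = config$noise_sd),
                 nrow = g, ncol = n, dimnames = list(gene_ids, sample_ids))

  if (config$n_planted_pairs > 0L) {
    # Planted pairs are tightly co-expressed: both genes share the sample's
    # Gaussian noise draw and differ by a small within-pair gap (SD one fifth
    # of noise_sd). The class signal is carried by which gene sits on top, set
    # by swapping the two values when the drawn orientation disagrees with the
    # wanted one. Keeping the gap small relative to the between-gene spread
    # leaves each planted gene's marginal essentially class-independent, so
    # pairs mixing a planted gene with an unrelated gene stay null.
    p_fwd <- ifelse(is_resp, config$stability_resp, 1 - config$stability_nonresp)
    for (j in seq_len(config$n_planted_pairs)) {
      mid <- baseline[ia[j]] + stats::rnorm(n, 0, config$noise_sd)
      gap <- abs(stats::rnorm(n, 0, config$noise_sd / 5))
      va <- mid + gap / 2
      vb <- mid - gap / 2
      want_fwd <- stats::runif(n) < p_fwd
      need_swap <- (va > vb) != want_fwd
      tmp <- va[need_swap]
      va[need_swap] <- vb[need_swap]
      vb[need_swap] <- tmp
      expr[ia[j], ] <- va
      expr[ib[j], ] <- vb
    }
    truth <- data.frame(gene_a = gene_ids[ia], gene_b = gene_ids[ib],
                        stringsAsFactors = FALSE)
  }

  if (config$batch) {
    for (s in seq_len(n)) expr[, s] <- draw_batch_transform()(expr[, s])
  }

  surv <- simulate_survival(ifelse(is_resp, "responder", "non-responder"),
                            hr_true = config$hr_true,
                            censor_rate = config$censor_rate,
                            seed = config$seed + 104729L)
  pheno <- data.frame(sample_id = sample_ids,
                      response = ifelse(is_resp, "responder", "non-responder"),
                      dfs_time = surv$dfs_time, dfs_event = surv$dfs_event,
                      stringsAsFactors = FALSE)
  list(expr = expr, pheno = pheno, truth = truth)
}

empty_truth <- function() {
  data.frame(gene_a = character(0), gene_b = character(0), stringsAsFactors = FALSE)
}

#' Simulate disease-free survival for labelled samples
#'
#' Event times are exponential with hazard `lambda` for non-responders and
#' `lambda * hr_true` for responders (baseline median DFS 36 months).
#' Censoring is independent at the stated rate: each sample is censored with
#' probability `censor_rate`, and a censored sample's observed time is drawn
#' uniformly over (0, its event time).
#'
#' @param labels Response labels (coding per [normalize_response()]).
#' @param hr_true Responder vs non-responder hazard ratio (> 0).
#' @param censor_rate Probability a sample is censored, in \[0, 1\].
#' @param seed Integer seed.
#' @return data.frame `dfs_time` (months), `dfs_event` (1 = event observed).
#' @export
simulate_survival <- function(labels, hr_true, censor_rate = 0, seed = 1L) {
  if (hr_true <= 0) stop("hr_true must be > 0")
  stopifnot(censor_rate >= 0, censor_rate <= 1)
  labs <- normalize_response(labels)
  set.seed(as.integer(seed))
  lambda0 <- log(2) / 36
  rate <- ifelse(labs == "responder", lambda0 * hr_true, lambda0)
  t_event <- stats::rexp(length(labs), rate = rate)
  censored <- stats::runif(length(labs)) < censor_rate
  t_obs <- ifelse(censored, stats::runif(length(labs)) * t_event, t_event)
  data.frame(dfs_time = t_obs, dfs_event = as.integer(!censored))
}
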