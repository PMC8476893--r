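---
title: "Rank-based gene-pair signatures for chemoradiation-response prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rank-based gene-pair signatures for chemoradiation-response prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reopairs)
```

## The problem and the model

Only a minority of locally advanced rectal cancer (LARC) patients respond
pathologically to neoadjuvant chemoradiation (nCRT); a pre-treatment
transcriptomic predictor of response would spare non-responders an
ineffective and harmful therapy. Absolute expression values transfer poorly
between cohorts: microarray and sequencing platforms, batches and
normalisation pipelines all shift them. The *within-sample relative
expression ordering* (REO) of a gene pair — is gene $a$ expressed above gene
$b$ in this sample? — is invariant to any strictly increasing transform of
that sample's values, and therefore survives batch effects and most
normalisation choices untouched. `reopairs` builds classifiers from this
primitive.

A **reversal gene pair** is a pair whose dominant ordering differs between
responders and non-responders, with the dominance statistically stable in
each class. For a pair $(a, b)$ with expression $G_a, G_b$, a sample is in
*forward* orientation when $G_a > G_b$ strictly; ties count as "not
forward", keeping the orientation binary (ties have probability zero on
continuous data). Within each class the forward count $k$ out of $n$ samples
is referred to an exact binomial tail,

$$p = P\!\left(X \ge \max(k,\, n-k)\right), \qquad X \sim \mathrm{Bin}(n, 1/2),$$

and a pair is emitted when the dominant orientations differ between classes
*and* $p < \alpha$ in both classes separately (default $\alpha = 0.05$,
one-sided on the dominant orientation; a two-sided variant sits behind
`two_sided = TRUE`). Requiring stability in both classes is the strictest
reading consistent with a binomial screen of class-dominant orderings; a
pooled single-test variant would admit pairs stable in one class only.
Emitted records are normalised so the forward orientation is the
responder-dominant one, and no multiple-testing correction is applied at
this stage — the downstream importance ranking is the effective filter.

The screen's p-values use the exact tail for all $n$ (no normal
approximation): class sizes in this domain are at most a few hundred, where
exactness is cheap.

## Ranking and selection

Each reversal pair becomes one binary feature per sample — 1 when the sample
shows the pair's response orientation. This indicator is the only encoding
that preserves exactly the rank information the screen used, so the forest
inherits the REO robustness. A classification random forest
(`randomForest`) is fitted to these features and every pair is ranked by its
**mean decrease Gini** (MDG) importance; MDG ties break lexicographically by
pair id so the ranking is a deterministic function of the fitted forest. The
reference configuration is `ntree = 2500`, `mtry = 88`, seed `20200914`
(the published model's settings); when `mtry` is unset the usual
$\lfloor\sqrt{p}\rfloor$ default applies. Forest fits are reproducible only
for a fixed seed *and* library version, both of which are recorded in the
ranking's metadata; no analysis here depends on bit-exact forest
reproduction across library versions.

Selection sweeps prefixes of the ranking: for each $N$ up to `n_max`
(default 500), every training sample is classified by majority vote over the
top-$N$ pairs and resubstitution accuracy is recorded; the smallest $N$
attaining the maximum accuracy is the signature. Prefix-only search is what
"best top-$N$" means; no subset search is attempted, and no internal
cross-validation is used — the training accuracy reported is resubstitution
accuracy, and honest performance assessment belongs to held-out cohorts.

## Classification and evaluation

A sample's **response ratio** is the fraction of evaluable signature pairs
in response orientation; the sample is called a responder on a strict
majority. An exact tie (possible only for an even evaluable count) is called
non-responder, so a responder call always rests on majority evidence — with
the 41-pair published signature, $N$ is odd and ties cannot arise. Pairs
with a gene missing from the matrix are dropped per run and excluded from
the evaluable count, which is what lets one signature cross microarray
platforms; a warning fires when more than 20% of signature genes are absent.

Evaluation reports the confusion counts with responder as the positive
class, sensitivity/specificity/accuracy, an exact Clopper–Pearson interval
for accuracy (beta-quantile closed form), and the ROC AUC computed by the
midrank Mann–Whitney formula (ties at one half) with a DeLong confidence
interval from `pROC`. Percentages are rounded to two decimals for
reporting. The Welch unequal-variance $t$-test is the default for the
response-ratio group comparison and the per-gene differential-expression
summary; a pooled-variance test would assume equal within-group spread,
which nothing here guarantees.

For survival, patients are stratified either by predicted label (when
response labels exist) or by the median split on response-pair counts
(counts strictly above the median are "high"; ties at the median go low).
Kaplan–Meier curves, the log-rank test and a covariate-adjusted Cox model
(Efron tie handling; stage and gender as categorical indicators, age
continuous) quantify the disease-free-survival separation. "Average DFS"
per group is reported as the restricted mean survival time over the common
follow-up window — the only group mean that is well-defined under
censoring.

## The synthetic-data generator

Real cohorts cannot be redistributed with the package, so every stage is
exercised on simulated cohorts whose structure mirrors the analysis
assumptions (`simulate_cohort()`):

* per-gene baseline log2 expression uniform on 4–12, per-sample Gaussian
  noise (`noise_sd`, default 0.5);
* planted reversal pairs whose orientation is forced, by swapping the two
  values when needed, to the class-dominant direction with probability
  `stability_resp` in responders and `stability_nonresp` (reverse) in
  non-responders. Swapping controls the per-class orientation frequencies
  exactly — the quantity the binomial screen models. The two genes of a
  planted pair share their baseline and their per-sample noise draw and
  differ by a small gap (SD `noise_sd / 5`): planted pairs are tightly
  co-expressed, so neither gene's marginal level carries class information
  and pairs mixing a planted gene with an unrelated gene remain null;
* optional per-sample batch distortions drawn from a seeded family of
  strictly increasing maps (affine, power, logistic warp) — REO outputs must
  be bit-identical with and without them;
* DFS from exponential event times (baseline median 36 months) with hazard
  multiplied by `hr_true` (default 0.25) for responders. Censoring is
  independent at the stated rate: each sample is censored with probability
  `censor_rate`, a censored sample's observed time drawn uniformly over
  (0, its event time), which gives exactly the nominal censoring fraction.

The reference design used throughout the tests and the analysis scripts is
500 genes, 50 planted pairs at stability 0.95, and 40 + 40 samples — small
enough that a full screen (124,750 candidate pairs) and forest fit run in
seconds, large enough that recovery is a meaningful bar. Under this design
the screen recovers essentially all planted pairs, discovery returns a
signature dominated by planted truth, and held-out accuracy sits near the
per-pair stability.

What the generator does **not** emulate: platform-specific probe effects,
realistic gene–gene correlation, heavy-tailed expression noise, or
class-dependent marginal shifts in individual genes. Passing tests
demonstrate that the algorithms do what they claim on data satisfying their
own assumptions; they do not certify performance on any real cohort.

```{r}
sim <- simulate_cohort(sim_config(n_genes = 120, n_resp = 20, n_nonresp = 20,
                                  n_planted_pairs = 10, seed = 11))
pairs <- find_reversal_pairs(sim$expr, sim$pheno)
nrow(pairs)
head(pairs, 3)
```

## Numerical and design choices

* **Ties in orientation** resolve to reverse ("not $G_a > G_b$"),
  deterministically, rather than introducing a third state.
* **Stability bounds**: stabilities live in $(0, 1]$; 1 means deterministic
  planting.
* **Full enumeration is gated** at 2,000 genes (about 2M pairs) by default;
  `max_genes` raises the ceiling explicitly and `prefilter_top_variance`
  offers an optional variance pre-filter (off by default, since any
  pre-filter changes which pairs can be found).
* **Degenerate inputs** error early and specifically: unlabeled samples,
  classes below two samples, non-finite expression values, empty signatures,
  all-identical vote counts at the median split, no events in a survival
  dataset, and Cox fits with monotone likelihood (unbounded group
  coefficient) are all refused rather than silently absorbed.
* **Selection ties over $N$** go to the smallest $N$ (parsimony).
* **Missing expression values are rejected at load**, never imputed:
  an ordering computed against an imputed value would be an artefact of the
  imputation model, which defeats the purpose of the primitive.

## Reproducing cohort-scale published numbers

The published screen reports 13,388 reversal pairs on its training cohort
(GSE87211) and a selected signature of 41 pairs. Those numbers depend on an
external accession, on the exact candidate-pair universe after probe
collapsing, and on forest randomness in a specific library version, so the
package documents rather than asserts them. What is asserted, exactly, are
the desk-scale quantities: the classification metrics implied by the
published confusion counts, and the packaged 41-pair signature's
composition (41 pairs, 76 unique genes, six genes shared between pairs).
With GSE87211 downloaded, collapsed by probe means on the log2 scale, and
labelled by tumor-regression grade, `find_reversal_pairs()` at the default
alpha is the documented entry point for attempting the 13,388-pair
replication; agreement is not guaranteed because the original candidate
universe is not fully specified.

The published accuracy confidence intervals (for example 81.27–88.10%
around 84.68% with $n = 111$) are narrower than any exact Clopper–Pearson
interval at that sample size can be; this package implements the textbook
interval and makes no attempt to chase those printed bounds.

## Limitations

Resubstitution selection inflates training accuracy by construction; only
held-out evaluation is meaningful. The screen's both-class criterion is one
of two defensible readings of a binomial REO screen (the pooled alternative
is available via `two_sided`/candidate-pair composition but not default).
Signature discovery at transcriptome scale (tens of thousands of genes)
requires either the variance pre-filter or a candidate universe: full
enumeration grows quadratically. Survival simulation uses exponential
hazards; real DFS curves are not exponential, and the Cox recovery checks
validate the estimator, not the clinical model.
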