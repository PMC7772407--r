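---
title: "Methods: enrichment encoding, mRMR/IFS selection and rule-based classification of cancer-related lncRNAs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: enrichment encoding, mRMR/IFS selection and rule-based classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the modeling idea

Most long non-coding RNAs (lncRNAs) have no direct functional annotation,
but many have a known set of protein-coding genes whose expression tracks
theirs. Guilt-by-association transfers annotation through that co-expressed
gene set \(G(x)\): if the genes co-expressed with lncRNA \(x\) are
concentrated in cancer-relevant pathways, \(x\) itself is a cancer
candidate. `lncrules` implements this as a supervised pipeline with an
interpretable classifier at the end:

1. **Enrichment encoding.** Each lncRNA becomes a vector of enrichment
   scores, one per annotation term (GO-like and KEGG-like gene sets). The
   score against term \(t\) is the upper tail of the hypergeometric
   distribution,
   \[
   S(x, t) = -\log_{10} \sum_{l=m}^{\min(n, M)}
   \frac{\binom{M}{l}\binom{N-M}{n-l}}{\binom{N}{n}},
   \]
   with \(N\) the gene-universe size, \(M\) the term's in-universe gene
   count, \(n = |G(x)|\) (in-universe) and \(m\) the overlap. Larger score =
   stronger association; the score is a feature, not a significance claim
   (no multiple-testing correction, deliberately).
2. **mRMR ranking.** Features are ranked by minimum-redundancy
   maximum-relevance: greedily append the feature maximizing
   \(I(f; y) - \frac{1}{|S|}\sum_{s\in S} I(f; s)\) (the MID difference
   criterion), with mutual information computed on three-level discretized
   scores. Ranking runs on the original, imbalanced data — before any
   oversampling — so synthetic samples can never influence feature
   importance.
3. **IFS with CART.** Incremental feature selection evaluates nested
   prefixes of the ranked list (sizes `step, 2*step, …, F`) with a binary
   CART tree under stratified 10-fold cross-validation, scored by the
   Matthews correlation coefficient (MCC). The optimum is the smallest
   prefix attaining the maximal MCC; a trade-off prefix is the smallest one
   within `tradeoff_delta` of it.
4. **SMOTE.** The positive class is rare (the motivating dataset has 57
   positives against 14,829 negatives, ~1:260), so training folds are
   balanced by SMOTE: synthetic positives are convex combinations of a real
   positive and one of its `k = 5` nearest positive neighbors (raw
   Euclidean feature space).
5. **Decision rules.** The tree for the chosen prefix is refit on all
   samples and flattened into one rule per leaf
   (`IF score(term_a) > θ1 AND score(term_b) ≤ θ2 THEN cancer-related`),
   partitioning feature space: every sample matches exactly one rule.

## Numerical and algorithmic conventions

* **Hypergeometric tail.** Summed in natural-log space from `lchoose` terms
  with log-sum-exp; converts to base 10 at the end. Exact for `m = 0`
  (score 0) and stable at genome scale (`N = 20000, M = n = m = 200` stays
  finite). `stats::phyper` is used only as an independent test oracle so
  the check has two genuinely separate routes.
* **Discretization.** Codes −1/0/+1 at `mean ± t·sd` with the *population*
  standard deviation (divisor *n*) and default `t = 1`, mirroring the
  classical mRMR program's continuous-data default; a constant feature
  codes to all zeros. MI is reported in bits; the log base cannot change
  the ranking.
* **mRMR ties** break toward the smaller original column index, making the
  list deterministic and invariant to sample order.
* **CART.** Exhaustive best-split search; candidate thresholds are
  midpoints between consecutive distinct sorted values; `value ≤ threshold`
  routes left; split ties break toward the lowest feature index, then the
  smallest threshold; leaf ties predict the negative class (conservative
  when positives are rare). Defaults grow to purity (no depth/size limits,
  no pruning), configurable via `tree_config()`. The split scan is
  compiled (Rcpp) with per-feature orders sorted once at the root and
  partitioned down the tree; everything else is plain R.
* **Metrics.** SN, SP, ACC, MCC, Precision, F1 from the pooled held-out
  predictions (not per-fold averages — better defined with ~5 positives
  per fold). Zero-denominator conventions: MCC 0 if any factor under the
  root is 0; Precision 0 if TP+FP = 0; F1 0 if Precision+Recall = 0.
* **Folds** are stratified (with 57 positives, unstratified 10-fold CV can
  produce folds without a single positive) and dealt round-robin after a
  seeded per-class shuffle.
* **Seeds** are split per stage — generator, fold assignment, SMOTE — and
  echoed in the pipeline manifest, so any stage can be varied in isolation.

## SMOTE placement: the one genuinely open design choice

The method description this package follows says only that oversampling was
applied "in the procedure of evaluating" the tree. Two readings coexist:

* `global`: balance the full dataset once, then cross-validate the
  augmented data. This is what running a standalone SMOTE tool before a CV
  harness does.
* `train_only` (the package default): balance each training fold only and
  test on untouched originals.

The difference is not cosmetic. Synthetic positives are interpolations of
real ones; under `global`, interpolations of *test-fold* positives sit in
the training folds, and a flexible classifier recognizes the neighborhood
rather than the signal. On this package's own null fixture (planted signal
switched off entirely) `global` placement yields pooled optimum MCC around
0.84 — on pure noise — while `train_only` stays near 0. With the planted
signal on, `global` reports ~0.89 where `train_only` reports ~0.26; the gap
is leakage, not learning. Both modes are implemented because the original
procedure is plausibly `global`; the default is the honest one. Consequence:
the package's cross-validated MCC on the default synthetic fixture is a
genuinely hard number (~0.25–0.3), and an external expectation of ≥ 0.6 on
that fixture is attainable only under the leaky placement — we keep the
default and report the discrepancy rather than switching modes to satisfy
it. An independent check with scikit-learn's CART plus a NumPy SMOTE under
the same leakage-free protocol scores *lower* (~0.10–0.16), so the ceiling
is the protocol's, not this implementation's.

## The synthetic-data generator: what it emulates, what it does not

`synthetic_config()` defaults state the world the tests run in: a universe
of 2,000 genes; 288 GO-like + 12 KEGG-like terms with sizes uniform in
[10, 300] (independent random subsets — term overlap mimics GO nesting
without an ontology DAG); 57 positives and 1,000 negatives (configurable to
the full 14,829); 10 planted discriminative terms; positives draw 30% of
their co-expressed genes from the union of the planted terms' gene sets,
negatives draw uniformly. Co-expressed set sizes are uniform in [20, 200].
One random stream per dataset, consumed in a documented order (terms →
truth → entities), makes every artifact reproducible from `(config, seed)`.

Signal genes are drawn with replacement and de-duplicated; the signal
portion is topped up from the remaining pool genes so it keeps its intended
size whenever the pool allows (this also preserves the boundary property
that with `signal_fraction = 1` and a single sufficiently large planted
term, positives' gene sets stay inside that term), and the background
portion fills up from the rest of the universe, so set sizes are exact.

Not emulated: expression matrices and correlation-based co-expression
calling (profiles are generated directly as gene sets, as the upstream data
enters the real pipeline), ontology structure and annotation propagation,
and any realistic term-size or co-expression-size distributions. A green
test therefore establishes that the machinery recovers a planted
association signal at a stated strength under honest evaluation — not that
the pipeline reproduces any particular biological discovery. Note also that
the union of 10 planted terms covers roughly half the universe, so the
per-term signal is intentionally diluted; mRMR still places ≥ 8/10 planted
terms in its top 20 on the default fixture.

## Parameters that matter

| Parameter | Default | Why |
|---|---|---|
| gene universe | explicit file or inferred union | the original study does not state its universe; it is configuration here |
| discretization `t` | 1.0 | the referenced mRMR program's default; the source is silent |
| mRMR variant | MID (difference) | the common default of the cited program |
| SMOTE `k_neighbors` | 5 | stated by the source method |
| IFS `step` | 10 | stated by the source method |
| `tradeoff_delta` | 0.025 | consistent with the source's own optimum/trade-off pair (0.415 vs 0.393); their choice was by inspection |
| tree limits | none | the source names only the algorithm family; library defaults grow to purity |
| CV folds | 10, stratified | 10-fold stated; stratification is this package's choice (rare positives) |

## Known limitations

* Single CART trees have high variance; the pipeline reports pooled-CV
  metrics but no confidence intervals (single pass, as in the original
  procedure).
* mRMR is O(F²) mutual-information evaluations; fine for hundreds to a few
  thousand features, not engineered for the full 19,090-term encoding on a
  laptop (the IFS loop, not mRMR, dominates in practice).
* Rule supports are leaf counts on the (optionally SMOTE-balanced) training
  data; they are descriptive, not calibrated probabilities.
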