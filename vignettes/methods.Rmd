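---
title: "Feature fusion for 6mA site classification: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Feature fusion for 6mA site classification: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the model behind `fusion6mA`, the choices that
were genuinely open when it was built, and what its tests do and do not
establish. It states no numbers that the test suite and
`scripts/acceptance.R` do not themselves compute.

## The classification problem

The input is a set of equal-length DNA windows (41 bp by default), each
centered on an adenine; the task is to decide whether that central
adenine carries the N6-methyl mark. Window sets arrive as a
positive/negative FASTA pair. The schema enforced by `load_benchmark()`
is: odd uniform length, A/C/G/T alphabet only, adenine at position
(L+1)/2 (1-based). Ambiguity codes are rejected in strict mode and
dropped with a warning in lenient mode — never imputed, because every
encoder is defined on the four-letter alphabet only.

## Feature blocks

Four encoders turn a window into numeric features. Binary and NCP are
positional and injective: two distinct windows always get distinct
vectors, so no information is lost, at the cost of dimension (4L and
3L). The NCP indicators summarize chemistry: `a` distinguishes
double-ring purines (A, G), `b` the weakly hydrogen-bonded pair (A, T),
`c` the amino-group bases (A, C); jointly the three bits identify each
base uniquely, so NCP is a re-coordinatization of one-hot that places
chemically similar bases near each other.

The k-mer block is compositional: frequencies of the 4^k words among
the L−k+1 overlapping windows, so its components always sum to one. We
normalize by the window count L−k+1 for every k, which keeps that
invariant uniform across k; k defaults to 3 (64 features) — larger k
squares the dimension per step and at k = 4 already gives 256 mostly
sparse counts from 38 windows. Column order is lexicographic over
A < C < G < T; the ordering is a determinism contract only, since
downstream selection and the SVM are insensitive to column order.

ENAC (per-sliding-window base frequencies, window width 5 by default)
is provided as a comparator encoder; it is not part of the default
fusion list.

The Markov block is distributional rather than positional: from the
training samples of each class we fit, per adjacent position pair i, a
4×4 row-stochastic matrix

P^i[x, y] = (count(x at i, y at i+1) + α) / (count(x at i) + 4α),

with Laplace pseudocount α = 1 by default so that unseen transitions
get positive mass and log-ratios stay finite. The per-window feature is
the L−1 vector of log(P⁺ᵢ/P⁻ᵢ) lookups. Two decisions here were open:

* **One chain or two.** A feature could use the positive chain's
  probabilities alone (`positive_prob` mode) or the ratio of both
  chains (`log_ratio`, the default). We default to the ratio because it
  is the per-position sufficient statistic for discriminating the two
  chain models — its sum is exactly the chain likelihood-ratio score —
  and because a single-chain feature is not discriminative at positions
  where both classes behave alike. The other mode is kept as an option.
* **Initial probability.** The state distribution at position 1 is
  deliberately excluded; only transitions enter the feature, keeping
  the block at exactly L−1 components.

Summing the log-ratio block gives `mm_score()`, the Markov-chain
likelihood-ratio baseline classifier (positive iff the score exceeds
0), which the evaluation module can cross-validate on its own
(`cross_validate_mm()`).

## Selection, fusion, normalization

Each block is filtered by model-based selection before fusion: an
XGBoost binary classifier with fixed settings (100 trees, depth 6,
learning rate 0.3, single thread, seeded) is fit on the block, and
columns whose gain importance reaches the mean importance are kept
(ties kept; if a rule would keep nothing, the single best column is
kept and a message emitted). The ensemble settings are fixed constants,
not tuning knobs: their job is a reproducible importance ranking, not a
classifier. Selection can instead run after fusion, or both before and
after; "before" is the default because per-block selection lets a weak
block (k-mer alone classifies poorly) contribute its few informative
columns without being swamped in a joint ranking. The kept columns are
concatenated with block-name prefixes, and min–max normalization maps
each fused column to [0,1] using training extrema; constant training
columns map to 0, and out-of-range values in new data are clipped. All
of this is fitted on training rows only and frozen into the
`trained_pipeline`.

## Classifier

The decision function is an RBF-kernel SVM. The default operating
point is C = 1.0, γ = 0.125; optionally both are tuned by grid search
over powers of two spanning 2⁻⁵…2⁵ (step 1, hence an 11×11 grid),
scored by stratified 5-fold accuracy on the training data, with ties
broken toward the smallest C then the smallest γ — among equally
accurate candidates we prefer the smoothest, least regularized-away
model. The decision threshold is fixed at 0 and no probability
calibration is applied; ROC curves use the raw decision values. When
grid search runs inside an outer cross-validation it is refit per outer
fold (nested CV), so the outer estimate is honest.

## Evaluation

Metrics come from the pooled confusion table: Sn = TP/(TP+FN),
Sp = TN/(TN+FP), Acc = (TP+TN)/n, and MCC with the convention that a
zero factor in the denominator yields MCC = 0. On balanced sets
Acc = (Sn+Sp)/2 exactly, which the tests use as an identity check.
Pooled metrics are the headline and per-fold metrics are attached; for
equal-sized folds pooled and fold-averaged accuracy coincide. Fold
assignment is a seeded shuffle within each class, so folds are
stratified and reproducible; every fitted component — chains, masks,
normalization, grid search — is refit per training fold. AUC is
trapezoidal over the tie-grouped ROC sweep, equal to the Mann–Whitney
pair-counting probability; it is invariant under monotone score
transforms.

## Synthetic benchmark and calibration

The generator emulates the benchmark schema: windows of odd length L
with the center forced to adenine. Negatives are drawn from a uniform
first-order chain; positives share that chain except at a set of
signal position pairs (default: the five valid pairs nearest the
center), where each transition row is mixed toward a designated
successor base with weight ε (`effect_size`): row = (1−ε)·uniform +
ε·point-mass. The two pairs touching the center are excluded from
signal so that forcing the center base afterwards leaves the planted
rows exact. Plating the signal in transition rows (not marginal
composition) makes the Markov block the fully informative one, while
the k-mer and composition blocks capture it only partially — the
regime in which fusion is interesting; a separate `composition_bias`
knob tilts positive-class composition toward adenine when
marginal-composition signal is wanted.

Because the true chains are known, the Bayes-optimal classifier is the
exact log-likelihood ratio, and `bayes_accuracy()` estimates its
accuracy by Monte Carlo. For the default five signal pairs the decision
reduces to a binomial rule, so the Bayes accuracy has a closed form;
ε = 0.864 places it at 0.950, and that value is the fixed study
condition used by the acceptance checks (1,000 balanced windows,
10-fold CV). The problem sizes there — n = 1,000, 50,000 Monte-Carlo
draws — were chosen once as the package's standard benchmark scale.

What passing these tests shows: the pipeline recovers planted
transition signal to near the information-theoretic bound, collapses
to chance under label permutation, and every deterministic component
matches an independent brute-force oracle. What they do not show:
performance on real rice-genome data, whose base composition is not
uniform, whose positive sets carry redundancy-filtering artifacts, and
whose class-conditional structure is richer than first-order
transitions. Real-benchmark evaluation requires the published FASTA
pairs and is out of scope for the offline test suite.

## Numerical and degenerate-input conventions

* Chain scores accumulate in log space; 40-term probability products
  underflow double precision only in pathological cases, but log-sums
  avoid the issue entirely. Zero probabilities in ratio mode (possible
  only at α = 0) raise an error directing the user to a positive
  pseudocount.
* Window trimming is symmetric about the center and composes:
  trimming to radius r₂ after r₁ ≥ r₂ equals trimming to r₂ directly.
  The trimming-radius grid for window-length optimization defaults to
  10–20 (the full default window), evaluated by CV accuracy with ties
  going to the shorter window, since shorter windows cost less
  computation at equal accuracy.
* Degenerate SVM inputs (identical rows with both labels) are allowed
  to fail with an informative error or return chance-level output;
  they must never crash the session.
* MCC on a single-class prediction or truth vector is 0 by the
  zero-denominator convention.

## Known limitations

Single-stranded, fixed-window classification only: no genome scanning,
no strand reconciliation, no higher-order chains, and no probability
calibration of the SVM scores. The grid search is quadratic in the
grid size and is the slow path of the pipeline; the fixed default
operating point is used wherever the tests need speed.
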