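---
title: "Graph-based feature panels and association rules for subtype discovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graph-based feature panels and association rules for subtype discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

panelomics implements a five-stage discovery pipeline for transcriptomic
subtype studies: preprocessing, AMGM dispersion filtering, graph-based
feature selection (Louvain communities + per-community maximum independent
sets), auto-encoder classification, and FP-Growth association-rule mining
with repeat-count ranking. This vignette records the models, the parameters
that matter, the numerical choices, and the places where the design was
genuinely open — and what the synthetic cohorts the package tests itself on
do and do not establish about real data.

## The problem

Renal cell carcinoma splits into three histological subtypes (clear-cell,
papillary, chromophobe) with very different clinical courses. Given bulk
mRNA or miRNA profiles for a cohort labeled with these subtypes, we want a
compact panel of molecules that discriminates the subtypes, plus the
association rules that tie panel molecules to each subtype. The data regime
is high-dimension low-sample-size: tens of thousands of features, around a
thousand samples, heavy class imbalance (the chromophobe arm is roughly 9%
of samples).

## Preprocessing

Tables are read in either orientation (samples-in-rows, or the
features-in-rows layout typical of repository downloads). Redundant features
are removed before anything else; we take the minimal reading — zero-variance
columns and exact duplicate columns (first kept, by feature-ID order) —
because these are precisely the degenerate cases that break the later
stages (a zero-variance feature has undefined z-score and min-max scale, and
scores exactly 1 under AMGM).

The hold-out split is 70/10/20 train/validation/test, stratified by subtype
with largest-remainder rounding of the per-class counts. Stratification is a
deliberate choice: with a minority class near 9%, an unstratified 10%
validation slice could miss it entirely. Every class must have at least
three samples so each partition is populated.

Two normalisations are available, both estimated on the training partition
only:

* z-score, `y = (x - mu) / sigma` (population sigma);
* min-max, `y = (x - min) / (max - min)`, with held-out values clipped to
  [0, 1] so downstream discretisation stays well defined.

Which transform feeds which stage was an open design point; the mapping we
adopt is driven by what each algorithm needs:

* **AMGM, classification and discretisation run on min-max data.** The
  modified AMGM exponentiates raw values, so it needs a bounded scale;
  the auto-encoder's sigmoid reconstruction and the equal-width low /
  medium / high bins both presuppose [0, 1].
* **The graph redundancy cosine runs on z-scored data.** On centred data
  the absolute cosine equals the absolute Pearson correlation — the natural
  redundancy measure. On all-positive min-max data, cosine similarity is
  dominated by the shared positive mean: essentially every feature pair
  scores 0.85–0.95, the weight matrix is nearly uniform, and community
  detection degenerates to a single community. With centred data the graph
  carries genuine correlation structure and Louvain recovers multiple
  communities, consistent with the tens of communities the method is
  expected to find on real cohorts.

## AMGM dispersion filtering

The score of feature i over n samples is the arithmetic-to-geometric mean
ratio, which is >= 1 with equality iff the feature is constant. Because
expression data contain zeros (which collapse the geometric mean), the
default is the modified form that exponentiates first:

$$R_i = \frac{\tfrac1n \sum_j e^{x_{ij}}}{e^{\bar x_i}}$$

computed as `mean(exp(x - mean(x)))` for numerical stability. On
min-max-scaled data this is a dispersion measure: constants score exactly 1,
and inflating deviations around the mean never lowers the score. Scores are
computed on the training partition only, so selection never sees test data
(the alternative — scoring all samples — is defensible but leaks the
held-out samples into selection).

In mRNA-like mode the top k = 1000 features by score (ties broken by feature
ID) pass to the graph stage; miRNA-like mode, with only ~1500–1900 features,
skips the filter.

## The feature graph

Every pair of selected features carries a weight blending relevancy against
redundancy:

$$W_{ij} = \beta\,\frac{R_i + R_j}{2} - (1-\beta)\,\lvert\cos(F_i, F_j)\rvert,
\qquad W_{ii} = 1,$$

with beta = 0.5 (mRNA mode) or 0.6 (miRNA mode). The raw AMGM values (>= 1)
enter unrescaled. Weights are squashed to (0, 1) by a logistic ("SoftMax")
scaling centred on the weight distribution:

$$\hat W_{ij} = \frac{1}{1 + e^{-(W_{ij} - \bar W)/\sigma_W}}.$$

The mean and standard deviation are taken over the off-diagonal
upper-triangle only: the diagonal is a fixed constant and would bias the
centring. The map is strictly increasing, so it changes no ordering.

A graph on n nodes carries n(n+1)/2 weighted edges counting self-pairs
(for 1545 nodes: 1,194,285).

**Communities.** Louvain modularity maximisation runs on the scaled weights
with self-loops dropped (a self-loop is selection-irrelevant and distorts
the modularity null model). We use igraph's implementation under a fixed
seed; determinism under a fixed seed is part of the function's contract.

**Candidate selection.** The scaled weights are thresholded into a Boolean
adjacency, a_ij = 1 iff (strictly) W-hat_ij > gamma and i != j, with gamma =
0.3. Within each community we take a maximum independent set of the induced
subgraph: no two selected features may be adjacent. Communities of at most
25 nodes are solved exactly by branch-and-bound (branch on the
highest-degree vertex, include-first, ties to the lowest feature ID); larger
communities use the Boppana–Halldórsson clique-removal approximation
(repeated Ramsey splits, removing the found clique each round, keeping the
best independent set; all vertex choices by lowest feature ID, so the output
is deterministic). The candidate panel is the union of the per-community
sets, recorded with each feature's community and AMGM score.

## Classification

The panel is evaluated by a self-organising stacked auto-encoder: the
encoder structure is grown greedily — the first layer gets ~2/3 of the input
width (capped at `max_units`), each further layer half the previous — and a
new layer is accepted only while the relative validation-loss improvement
exceeds a tolerance (default 1e-3), up to `max_layers`. Every candidate
stack is pretrained layer-wise as auto-encoders (sigmoid activations,
squared error) and then fine-tuned end-to-end under a softmax head
(cross-entropy, full-batch Adam). Model selection keeps the stack with the
best validation accuracy. The growth rule is this package's own design: it
realises "the model determines its own structure" as a concrete, seedable
procedure behind a pluggable interface. Two baselines sit behind the same
fit/predict contract: a single-hidden-layer MLP (nnet) and a
nearest-centroid classifier, which doubles as an independent oracle in the
tests.

Evaluation reports a K-by-K confusion matrix, one-vs-rest counts per class,
precision/recall/F1 per class, one-vs-rest ROC AUC from the continuous class
scores (rank/Mann–Whitney form, cross-checked against pROC), and accuracy in
two forms: the micro-averaged one-vs-rest form (the headline number
recomputable from the stored one-vs-rest counts) and the plain multiclass
fraction correct, which is what the package's own recovery tests assert. A
class absent from a partition yields NA AUC, never 0.

## Association-rule mining

Candidate-panel values are rescaled to [0, 1] on the pooled cohort (the
split is a classification concern; rules describe the whole cohort) and
discretised into equal-width thirds: low [0, 1/3), medium [1/3, 2/3), high
[2/3, 1] — upper bins left-closed. Each sample becomes a transaction holding
one level item per panel feature plus exactly one class item.

Frequent itemsets come from FP-Growth (min-support 0.1, max length 4):
items are ranked by descending global support (ties alphabetical),
transactions are rewritten in rank order, identical prefixes merge into
weighted branches, and mining recurses over conditional pattern bases. The
kernel is C++ for scale; its output is asserted identical (itemsets and
supports) to a brute-force Apriori enumeration in the tests. When only
class-anchored rules are wanted, the class items are ranked last and only
their conditional trees are mined — exactly the itemsets containing a class
item, at identical supports, without enumerating the rest.

Rules A -> C are scored by support, confidence = support(A u C)/support(A),
and lift = confidence / P(C); rules with lift >= 1.1 are kept. Class rules
are those whose consequent is exactly one subtype's class item. A subtype
whose prevalence is below min-support can never appear in a frequent
itemset, so it yields zero class rules — the imbalance-driven suppression
the chromophobe arm shows in practice, reproduced analytically and in tests.

Molecules are ranked by repeat count: the number of a subtype's rules whose
antecedent contains any level item of the molecule (levels pool into one
count per molecule). Dependency networks around an anchor molecule count how
often each co-feature shares an antecedent with the anchor among rules
passing optional support/lift cuts.

## The synthetic cohorts

The generator emulates the statistical structure the pipeline assumes, not
any particular platform: intensities are log-normal, `exp(base + class
offset + noise)` with per-feature base levels in [1, 3] on the log scale.
Default cohort imbalance mirrors a 611/321/89 three-subtype study.
Archetypes:

* **informative** features follow one of the K! permutations of the class
  offsets (0, e, 2e, ...) with effect e on the log scale;
* **redundant** blocks are an informative template plus multiplicative
  perturbations (sd 0.02), keeping within-block cosine > 0.95;
* **constant** features are identically zero;
* **noise** features share the log-normal magnitude but carry no class
  signal.

Provenance tags every feature with its archetype and its *signal group*: the
mean-profile equivalence class up to sign. A profile and its mirror (offsets
reversed) are pooled into one group because they carry identical subtype
information — any classifier separates the classes equally well with either
— and the graph stage's absolute-correlation redundancy deliberately treats
them as interchangeable, keeping one representative. Demanding both mirrors
in a panel would be demanding redundancy. For three classes this yields
three signal groups.

Planted co-occurrence rules force samples of a named subtype into a named
discretisation level (bin centre plus-or-minus a small jitter, inside the
feature's observed span) with probability 0.95, so rule mining has a known
pattern to recover. One realism limit is worth stating: on a cohort with
hundreds of strongly informative features (effect 3), every informative
feature's class item reaches within-class support ~1 after discretisation,
so a rule planted at 0.95 can never out-rank the natural signal in the
repeat-count table — the top of the table is decided by co-occurrence
combinatorics among equally perfect items. The package therefore asserts
(a) that the planted rule is recovered as a high-confidence class rule,
(b) that the repeat-count table's top molecule carries planted signal rather
than noise, and (c) on a cohort whose *only* class signal is the planted
rule, that the planted feature tops the table outright.

What passing these tests shows: the stages implement their definitions
correctly, jointly recover planted structure at realistic imbalance, and
reproduce the analytic imbalance effects. What they do not show: performance
on real cohorts — real expression data have correlated noise, batch
structure, and library-size effects the generator deliberately omits.

## Numerical choices and degenerate inputs

* Modified AMGM is computed in deviation form to avoid overflow; the classic
  variant refuses non-positive values (vanishing geometric mean).
* SoftMax scaling refuses a zero-spread weight matrix; adjacency
  thresholding is strict (`>` gamma) with gamma in (0, 1).
* Ties everywhere break by feature-ID order (top-k selection, MIS vertex
  choices), making every stage reproducible.
* One master seed derives per-stage seeds by hashing the stage name; no
  stage touches the global RNG state without restoring it.
* Problem sizes in the package's own tests: recovery runs use a 2000-feature,
  300-sample cohort (imbalance 180/94/26) with a 1000-feature filter cut —
  comfortably in the regime where every stage's behaviour is exercised, and
  small enough to re-run routinely.

## Known limitations

* Louvain is the only community detector; the method's outcome depends on
  the community structure, and near-uniform weight matrices (e.g. min-max
  cosine redundancy) collapse it — the reason the z-score mapping above is
  load-bearing.
* The clique-removal MIS is an approximation on large communities; the
  tests bound it against the exact solver only up to moderate sizes.
* The auto-encoder growth rule is one concrete realisation of
  structure-determining training; alternatives (unit pruning, width search)
  would fit behind the same interface.
* Rule mining on large panels produces millions of rules by combinatorial
  necessity; artifacts store the strongest 100k, and class-anchored focused
  mining is the intended mode at scale.
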