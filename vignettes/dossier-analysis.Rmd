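---
title: "Modelling acute oral toxicity from dossier data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling acute oral toxicity from dossier data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oraltox)
```

`oraltox` analyses tabulated regulatory oral-toxicity dossiers: study-level
LD50 and NOAEL records with OECD guideline and Klimisch reliability
metadata, binary structural fingerprints, and molecular descriptors. It
asks two kinds of questions. First, *redundancy*: how well do different
acute guidelines agree, how predictive is a 28-day NOAEL of acute toxicity
and of the 90-day NOAEL, and how safe is the pragmatic factor-3
extrapolation of a 90-day derived no-effect level (DNEL)? Second,
*predictability*: can a similarity-constrained nearest-neighbour vote and
supervised learners over molecular descriptors classify substances at the
2,000 mg/kg b.w. LD50 threshold, and where in chemical space (which
similarity modules) are such predictions reliable?

This vignette records the model choices, the tunable parameters, what the
synthetic data generator does and does not emulate, and the numerical
decisions a maintainer would want written down. Every number quoted here is
computed by the test suite or the examples below; nothing is asserted from
memory.

## 1. The data model and substance-level aggregation

A study record is one row: substance id, endpoint
(`acute_oral`/`repeated_28d`/`repeated_90d`), guideline (TG 401/420/423/425
for acute, TG 407/408 for 28- and 90-day), Klimisch score 1–4, key-study
and read-across flags, a positive value in mg/kg b.w., and a qualifier
(`exact`, `greater_than`, `greater_equal`) that preserves censoring for
limit-dose results.

The substance-level endpoint is the **arithmetic mean** of the studies that
pass a selection filter (Klimisch threshold, key-study-only, and so on); a
geometric mean is available (`mean_type = "geometric"`) but the arithmetic
mean is the default because it is the convention the aggregated field data
follow. Censored values participate at their bound — a "≥ 2,000" limit
test enters the mean as 2,000 — which matches how dissemination-site
values are reported, and the qualifier column retains the censoring for
audit. Unit conversion is deliberately out of scope: everything is mg/kg
b.w., and anything else is an input error.

The toxicant label is **strict**: a substance is an oral toxicant when its
aggregated acute LD50 is *below* 2,000 mg/kg; exactly 2,000 — the typical
censored limit-dose outcome — is non-toxic. One consequence worth knowing:
when several key studies disagree in their censoring (say "≥ 2,000" and an
exact 800), the mean simply averages the bound with the exact value. There
is no principled reconciliation of conflicting censored records; the
package flags none and invents none.

```{r aggregation}
studies <- as_study_table(data.frame(
  substance_id = "EC-1", endpoint = "acute_oral", guideline = "TG423",
  klimisch = 1L, key_study = c(TRUE, FALSE), read_across = FALSE,
  value = c(800, 2000), qualifier = c("exact", "greater_equal")))
aggregate_substance_value(studies)
```

## 2. Similarity graph and applicability-domain modules

Chemical similarity is the Tanimoto coefficient over binary substructure
fingerprints, $|A \cap B| / |A \cup B|$. Two empty fingerprints have
*undefined* similarity — the package raises an error rather than returning
0, because a silent 0 would quietly drop such pairs below any threshold.
The similarity graph connects pairs with similarity ≥ 0.7 (the
conventional read-across neighbourhood; the threshold is a parameter).

Modules — the applicability domains over which the classifiers are
evaluated — come from maximising Newman–Girvan modularity
$Q = \sum_c \left[ e_c/m - (d_c/2m)^2 \right]$ on the **unweighted**
thresholded graph at resolution 1. The graph is thresholded first and then
clustered, so edge weights would only re-encode what the threshold already
decided; similarity weights are kept on the edges for nearest-neighbour
use only. The weighted alternative is deliberately not offered as a
default because the module boundaries would then depend on two coupled
parameters.

Numerically, module detection is greedy multi-level (Louvain-style)
optimisation with eight perturbed-order restarts, keeping the best-Q
partition; the node-visit order is seeded, so results are reproducible and
the documentation warns that module *boundaries* (not Q) can shift under a
different seed. Graphs of at most 12 nodes are instead solved exactly by
integer programming (`igraph::cluster_optimal`): during development we
found a 7-node graph on which every one of 40 Louvain restarts stops at
Q = 0.125 while the optimum is 0.155 — escaping that local optimum needs a
coordinated multi-node move that single-level greedy passes cannot make —
so "greedy is good enough on tiny graphs" is simply false, and tiny graphs
are cheap enough to solve exactly. Isolated substances become singleton
modules; an edgeless graph yields all singletons with Q defined as 0 and a
warning. Module ids are contiguous from 0, numbered by decreasing size.

## 3. The similarity-constrained KNN classifier

A substance is predicted toxic when the **majority of its k = 5 most
similar neighbours with similarity ≥ 0.7** are toxic. Both k and the
threshold are configuration. Three conventions are pinned down explicitly
because the field description leaves them open:

* **Threshold-first, then top-k.** Candidates are filtered at the
  similarity threshold before ranking; with fewer than k candidates the
  available ones vote. The alternative reading (top-5 first, then
  threshold) gives the same answer whenever five candidates exist and is
  not separately implemented.
* **Self-exclusion is always on** when the query is part of the reference
  set: the query's own fingerprint has similarity 1.0 and would leak its
  own label into the vote.
* **Ties.** An even vote (possible with fewer than k candidates) defaults
  to non-toxicant, the majority class of dossier data; a substance with
  *no* qualifying neighbour gets the same default and is flagged
  `in_domain = FALSE`. Similarity ties at the k-th rank are broken by
  ascending substance id so predictions are deterministic.

The leave-self-out prediction column doubles as the **KNN feature** fused
into the supervised learners. Inside cross-validation that column is
recomputed against the training fold only (held-out substances are
predicted from the fold, not from the full set), which is stricter than
computing it once globally; the global mode remains available by simply
not passing fingerprints to the evaluator, since the field's published
workflow appears to have computed the feature once.

## 4. Supervised learners and reweighting

Class imbalance is handled by instance weights: every toxicant weighs
`n_negative / n_positive`, making the class totals equal. The exact ratio
is the default; `mode = "paper"` rounds it to two decimals (a 268/791
split gives 2.95), matching the convention of reported analyses.

The **decision tree** is a depth-2 weighted tree with the entropy split
criterion (rpart, `split = "information"`), enough to express the fused
rule of interest — split on the KNN feature, then on one descriptor.

The **multilayer perceptron** is one hidden sigmoid layer with
$\lceil (p + 2)/2 \rceil$ units, two sigmoid outputs with one-hot targets
and squared-error loss, trained by weighted online backpropagation:
learning rate 0.3, momentum 0.2, 500 epochs, instances visited in row
order. These numeric defaults pin down the common toolkit configuration
without depending on any toolkit. Features are standardised to zero
mean/unit variance before training — descriptors span orders of magnitude
and online training is unstable otherwise — and the standardisation
statistics travel with the model. Weight initialisation is uniform
(−0.5, 0.5) under a seed, so training is bit-reproducible; the inner loop
is compiled (Rcpp) because leave-one-out evaluation trains one network per
substance. Prediction is the class with the larger output. Prediction
inputs are schema-strict: a model trained without the KNN column rejects
inputs that carry it.

## 5. Feature importance over balanced subsets

Both protocols run on 100 class-balanced subsets (each preserving the
global class ratio to within one instance; the subsets partition the
data). The **Ranker** reports, per feature, the mean and SD of information
gain across subsets. Entropy is in bits. Continuous features are
discretised by Fayyad–Irani MDL binning computed on the data being scored;
a feature whose best cut fails the MDL criterion scores 0 — on small
subsets this is common and is the intended behaviour of the criterion, not
a bug. Discrete features (including the 0/1 KNN column) use their values
as bins.

The **WrapperEval** holds out each subset in turn and runs greedy forward
selection with the depth-2 tree, scoring held-out accuracy; a feature's
score is the number of iterations (0–100) in which it was selected. The
source description of this protocol is ambiguous between forward selection
and removal-impact; forward is the default (it is what the named toolkit
does), and `mode = "removal"` implements the other reading. Ties between
equally predictive candidates go to the earlier column in the feature
order, so a redundant pair splits: at most one of the two is selected per
iteration.

## 6. Concordance analyses

* **Guideline agreement.** Two guidelines agree on a substance when its
  per-guideline aggregated LD50s fall on the same side of 2,000 mg/kg. The
  diagonal is self-consistency: among substances with ≥ 2 studies under
  one guideline, all study-level values must classify identically.
* **28-day NOAEL rule.** The contingency table uses NOAEL ≤ 200 vs > 200
  (rows) against LD50 < 2,000 vs ≥ 2,000 (columns). NPV is the non-toxic
  fraction of the NOAEL > 200 row; PPV the toxic fraction of the ≤ 200
  row; the avoidable-study count is the (> 200, ≥ 2,000) cell. The
  boundary conventions come from the published table labels.
* **Taylor-style constraints.** Approximated on machine-readable fields:
  a 28-day study with Klimisch ≤ 2 and no positive GHS H3xx flag. The
  original criteria also exclude mutagens and sensitisers on evidence the
  data model does not carry; this is an acknowledged approximation, not
  the full rule. The high-dose condition (NOAEL ≥ 1,000) is returned as a
  boolean, not applied as a filter, so predictivity can be split on it.
* **Factor-3 DNEL check.** A pair violates the assessment factor when the
  90-day NOAEL is *strictly* below one third of the 28-day NOAEL; exactly
  one third counts as within (the source is silent; the boundary case is
  resolved in favour of the extrapolation).

One printed-source inconsistency is worth recording: the published hazard
table's H302 counts (1,072 positive, 4,677 negative) give 18.6467% →
18.6% conclusive-positive, while the accompanying text prints 18.7%. The
package computes the honest arithmetic from counts (18.6), and the
"not orally toxic" complement is correspondingly 76.5 rather than 76.4.

## 7. What the synthetic generator emulates — and what it does not

The generator exists so that every downstream stage is testable offline
with data of the right *shape*. Its defaults are the study conditions of
the canonical dataset and are not tuned per test:

* **Scale and prevalence.** Nine modules totalling 1,059 substances;
  toxic modules are chosen so their total size matches the 268/1059 ≈
  25.3% toxicant prevalence. Each substance follows its module's latent
  state with probability `clustering_strength` (default 0.9), otherwise an
  independent coin flip at the target prevalence — at strength 0 labels
  are provably independent of structure, which the tests use as a
  no-leakage null (downstream KNN balanced accuracy ≈ 0.5).
* **Fingerprints.** Each module has a random core pattern (density 0.3);
  members copy it with a per-bit mutation rate solved (by `uniroot` on the
  closed-form expected similarity) so the expected within-module Tanimoto
  equals `within_module_similarity` (default 0.9). Expected between-module
  similarity stays far below the 0.7 threshold. Requests below the
  fully-randomised floor of 1/3 are a configuration error.
* **Dose-grid pile-ups.** Latent log10-LD50s are class-conditional
  truncated normals — toxicants centred at 800 mg/kg (borderline cases
  are the common case), non-toxicants at 4,500 — and with probability
  `p_snap` a study value is censored to its guideline's dose grid:
  non-toxicants down to the largest grid dose at or below their value
  with a `greater_equal` qualifier (the limit-dose convention that piles
  values at 2,000 and 5,000), toxicants to the nearest sub-2,000 grid
  dose. Grids are configuration, not code.
* **NOAEL structure.** The 28-day NOAEL is coupled to the acute class:
  P(NOAEL > 200 | non-toxicant) is a free parameter (0.75) and
  P(NOAEL > 200 | toxicant) is solved in closed form so the "NOAEL > 200
  ⇒ non-toxic" rule attains a configured NPV (default 0.945). A
  configured fraction (0.24) of unremarkable substances come from clean
  limit-dose studies reporting "≥ 1,000" in both durations — this
  mechanism, not the bivariate correlation, carries most of the
  high-28d/high-90d concordance (calibrated once to ≈ 70%); a plain
  bivariate lognormal cannot reach that concordance while keeping the
  90-day marginal visibly shifted low. The remaining pairs follow a
  bivariate log-normal with correlation 0.7 and a 0.25 log10 downward
  shift of the 90-day marginal, plus a 2% fraction of injected anomalies
  with the 90-day NOAEL five-fold above the 28-day one.
* **Hazard flags** follow the GHS bands of the aggregated LD50 with
  half-open-downward boundaries (a value censored *to* a grid point is a
  lower bound, so it belongs to the band above it); H303 — the optional
  Category 5 that regulators rarely apply — is assigned to only 2% of its
  band; `data_lacking`/`inconclusive` replace statuses at configured
  rates.
* **Descriptors** are linear blends of a toxicity signal, a
  module-structural effect and noise, with per-descriptor informativeness
  and realistic scales (counts rounded non-negative, magnitudes spanning
  orders of magnitude so standardisation genuinely matters).

Determinism is strict: each artifact draws from its own stream split off
the master seed, so adding a stage never perturbs earlier outputs, and the
same `(seed, config)` is bit-identical.

What it does **not** emulate: chemically realistic structures (fingerprints
are abstract bit sets, so nothing can be said about real fingerprint
software), natural-language results fields, activity cliffs within
modules, correlated missingness, or the long tail of guideline
idiosyncrasies. Acute study noise is clipped to the latent class's side of
2,000, so the aggregated label always equals the latent label — real data
has label noise at the threshold that this generator deliberately
excludes. Passing tests therefore demonstrate that the *pipeline* is
correct and that the methods behave as expected on data with this
structure; they do not certify classifier performance on real dossier
data.

## 8. Evaluation conventions

Sensitivity, specificity and balanced accuracy (BAC, their mean) are
percentages. A rate with a zero denominator is undefined and reported as
`NA` (printed `NAN` in tables); for a module without positives the BAC
falls back to the specificity alone — the reporting convention of the
published module tables — with an `undefined_sensitivity` flag retained so
nothing is silently hidden. Cross-validation is stratified (class
proportions within one instance per fold), reweights inside each training
fold, and pools held-out predictions into micro-averaged counts (chosen so
confusion counts are conserved); per-fold macro averages are also emitted.
Leave-one-out warns above 500 instances, and the pipeline caps it with a
class-stratified subsample (`loo_max_n`, 200 in the examples) to keep runs
in minutes.

Problem sizes used by the test suite were chosen to keep the full suite in
a few minutes while leaving each property clearly resolved: the canonical
n = 1,059 run for pipeline counts, n ≈ 1,000 × 20 seeds for the null
checks, n ≈ 5,000 for the NPV calibration, n ≈ 2,250 for the concordance
calibration, and n = 180 × 10 seeds for the leave-one-out comparison.

## 9. Known limitations

* The Taylor-style filter is an approximation (no mutagenicity or
  sensitisation evidence in the data model).
* Conflicting censored key studies are averaged, not reconciled.
* The wrapper protocol's tie-breaking favours earlier feature columns;
  with strongly redundant features the selection frequencies are
  order-dependent (the redundancy itself is detectable by comparing with
  the Ranker, which ties exactly).
* Module detection above 12 nodes is a seeded heuristic; Q values are
  stable in practice but the partition near module borders need not be.
* The perceptron implements the fixed classic configuration; there is no
  early stopping, no hyper-parameter search, and no probability
  calibration — by design, to stay faithful to the reference setup.
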