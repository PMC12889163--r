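---
title: "Evaluating EC-number predictions: models, metrics, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating EC-number predictions: models, metrics, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enzEval)
```

## The problem

Enzyme Commission (EC) numbers classify enzymes by the reaction they
catalyze in a four-level hierarchy (`class.subclass.sub-subclass.serial`,
e.g. `1.1.1.1`). Computational EC predictors — homology search, deep
learning, protein language models, contrastive learners — are usually
evaluated on incompatible datasets with incompatible metrics. enzEval is a
model-agnostic harness that scores any predictor's output tables under one
set of conventions, across three tasks:

1. **Exact prediction** — hierarchical multi-label precision/recall/F1 at
   EC levels 1–4.
2. **Completion** — for partially annotated enzymes (`1.1.-.-`), how often
   do independent models converge on the same completed label?
3. **Recommendation** — when a predicted EC is new or additional, is the
   *reaction* it denotes chemically similar to the truth?

The package never runs the predictors themselves; it consumes their
prediction tables (TSV: protein, EC, score in [0,1]) plus ground-truth
annotation tables, sequences (FASTA) and an EC-to-reaction table.

## Label model

EC labels are canonical strings with `-` for undefined levels. Defined
levels must form a contiguous prefix (`1.-.1.1` is rejected); inputs with
fewer than four fields are right-padded (`1.1.1` becomes `1.1.1.-`), since
both conventions occur in annotation files. Preliminary curator tokens
(`1.1.1.n5`) are accepted and treated as opaque defined tokens: they occur
in UniProt and there is no principled way to order them numerically.
Equality is textual; no registry validation is attempted, and
transferred/deleted EC numbers are taken at face value.

## Task 1: hierarchical metrics

At level *k*, both true and predicted label sets are truncated to *k*
defined levels and de-duplicated; confusion counts are one-vs-rest over the
union label space. Conventions, each of which some other benchmark decides
differently, are fixed as follows:

* **Partial truth at deeper levels.** A protein whose every true label is
  shallower than *k* is *excluded* at level *k* rather than scored zero:
  the annotation carries no ground truth there, and completion is a
  separate task. Partial *predicted* labels are likewise dropped once the
  level exceeds their depth.
* **0/0 cells are 0.** Precision with no emissions, recall with no
  positives, and F1 at 0+0 are all defined as 0 — the conservative,
  commonly used convention. When *no* protein is evaluable at a level, the
  aggregates are reported as `NA` rather than fabricated zeros.
* **Averaging.** Micro aggregates derive from summed counts; macro is the
  unweighted mean over classes with positive support; weighted weights by
  true support, so classes that appear only in predictions (support 0)
  cannot inflate the score — their false positives still count against the
  micro aggregates. All three are reported because published comparisons
  disagree on which to headline.

Batched variance (`evaluateBatched`) shuffles proteins under a seed and
splits them into *n* equal-sized, non-overlapping subsets that cover the
whole test set (468 proteins in 5 batches gives 94/94/94/93/93), reporting
mean ± sd of every aggregate. Per-group evaluation (`evaluateByGroup`,
e.g. Eukaryota vs Bacteria) and a per-class table across all four levels
(`perClassTable`, the sunburst export input) reuse the same counting core.

## Thresholding

Scores become label sets in one of two ways:

* **Regular** (`applyRegular`): the top-scoring label always, plus any
  label scoring at least `tExtra` (default 0.5). Argmax ties break to the
  lexicographically smallest EC string so results are deterministic.
* **Learnt** (`learnThresholds`): per class, candidate thresholds are
  exactly the class's observed validation scores, scanned exhaustively for
  the maximum binary F1; ties keep the smallest candidate (favoring
  recall). Classes with no validation positive map to a `NEVER` sentinel
  and are never emitted. Comparison is inclusive (score ≥ threshold), so a
  threshold equal to a positive's score keeps that positive. The
  candidate-set choice makes the optimum exact at finite cost — a fixed
  grid could miss it. Learnt thresholds must be fit on a held-out
  validation table; the runners refuse to fit them on the evaluation set.

## Ensembles

`majorityVote` takes each base model's top prediction as one vote;
abstaining models cast none. Every modal label is emitted — voting ties
yield multiple labels, which is also why voting ensembles tend to emit
additional EC numbers. The vote score is count/voters by default
(abstentions excluded, so sparse-coverage models do not dilute a confident
consensus); a count/all-models denominator is available.

`fitStacker` concatenates each base model's score vector over the shared
label space into one feature vector per protein (absent scores are 0 —
absence means "not predicted") and fits a one-vs-rest ridge-penalized
logistic regression per class observed in validation truth. Choices that
matter:

* The ridge penalty is λ = 0.001, fit down a decreasing λ-path (coordinate
  descent needs warm starts to converge at light penalties on separable
  one-hot features). Light regularization keeps the fit deterministic
  while leaving rare-class scores above the majority-class base rate — a
  stacker trained on a single perfect base model must reproduce it.
* Classes whose validation response is constant get intercept-only
  prevalence fits, so an all-abstaining feature matrix degrades to
  predicting the validation majority class. Classes with a single positive
  are fit by an in-package Newton/ridge IRLS with the same penalty, since
  the coordinate-descent backend requires two observations per class.
* Test-time base tables are matched to the training layout by model name,
  so base-table order is irrelevant; labels unseen at fit time are never
  emitted.

## Task 2: completion agreement

Completion entries are the (protein, partial label) pairs with depth < 4.
Each model contributes its top prediction per protein; a majority exists
iff some label's count *strictly* exceeds half the number of models (a 2–2
split of four models is not a majority). The denominator counts all models
in the comparison, abstainers included — "more than half of the models" is
read literally — with a voters-only mode available. The agreement *rate*
is the fraction of entries with a majority; the per-model agreement
*count* is how often that model's top equals the majority label, batched
for error bars with the same seeded five-batch scheme as Task 1.

Tops are *not* required to extend the partial prefix — the consensus is
scored as-is — but because the task is nominally completion, the fraction
of each model's tops that do extend the prefix is reported separately
(`prefixConsistency`).

`validateAgreement` justifies agreement as a confidence proxy: on proteins
whose every label is complete, it pairs each model's agreement count with
its weighted F1 and reports the Pearson correlation (two-sided t-test
p-value; `NA` on zero variance). On synthetic panels with a planted
quality ordering the correlation is strongly positive.

## Task 3: reaction similarity

EC numbers denote reactions, so a wrong-but-close prediction can still be
biologically useful. Reactions (`reactants>>products` strings) are
compared as fixed-length fingerprint bit sets under Tanimoto similarity.
The bundled backend hashes side-tagged character trigrams of each molecule
(plus a whole-molecule token) onto 1024 buckets with a polynomial rolling
hash; it is fully deterministic and dependency-free, and the backend is
pluggable behind a "reaction string → bit-index vector" contract for
anyone wanting a cheminformatics fingerprint instead.

Between two EC numbers present in the table, similarity is the maximum
over their reaction-record pairs (an enzyme matches if *any* catalyzed
reaction matches; the per-record aggregation is a package choice — the
task definition only aggregates across EC labels). Reaction tables are
incomplete, so when an EC is absent its fourth level is ignored and up to
`maxSamples` (default 10, without replacement, seeded) table ECs sharing
the first three defined levels are sampled; the value is their average
similarity to the other EC. If no three-level siblings exist, the shared
prefix relaxes to two, then one level; if nothing shares even the top
class, the similarity is 0 with a warning — 0 rather than NA keeps the
per-protein averages well defined.

Per model, three aggregates are reported: coverage (percentage of truth
proteins with ≥ 1 prediction), average similarity (mean best-pair
similarity over predicted proteins), and weighted similarity = average ×
coverage/100, which rewards models that dare to predict broadly. The
identity holds to 1e-12 by construction and is asserted in the tests.
`selectUnseen` restricts a test set to (protein, label) pairs absent from
training (the generalization condition), and `additionalPredictions`
extracts the matched-plus-extra cases for multi-function scoring. Whether
partial-task scoring should truncate predictions to levels 1–3 first is
ambiguous in published practice; both modes are exposed via
`truncateTo`.

## Curation

Dataset construction removes non-enzymes, collapses duplicate sequences
(smallest identifier wins, annotations united), and purges training
leakage: the union of train and test is clustered at a percent-identity
threshold and every training member of any cluster containing a test
sequence is removed. Cluster-membership removal can over-remove through
transitive clustering; that is the intended semantics, not a bug. The test
split is never modified, and retained training size is monotone
non-decreasing in the threshold.

The built-in clusterer is greedy: sequences in decreasing length order
join the first representative aligning at or above the threshold
(global alignment, identity = matches / alignment length), else found a
new cluster. A 4-mer containment prefilter skips alignments only at
thresholds ≥ 60%, where a pair sharing no 4-mer cannot plausibly reach
the bar, keeping the greedy result identical to an all-pairs oracle. An
adapter (`readClusterTsv`) accepts the representative/member TSV that
external clustering tools emit, for production-scale use; the provenance
log records which backend produced the clustering. Structure-availability
filtering and GO-term attachment are local-file hooks
(`structureFilter`, `attachMetadata`) — nothing is fetched over the
network.

## The synthetic generator

`syntheticSpec` defines the study conditions: a 4×3×3×4 label tree (144
complete labels) with geometric (long-tailed) leaf frequencies; 10% of
proteins multi-label; 15% of labels truncated to a random depth 1–3;
random amino-acid sequences of length 80–400; and five model profiles
spanning strong to weak predictors (level-1→4 accuracies from
0.95/0.90/0.85/0.80 down to 0.60/0.45/0.35/0.25, coverages 0.95 down to
0.50), emulating the performance spread real benchmark panels show.

Predictions are generated so that the designed accuracies are exact: one
uniform draw per protein decides the deepest correct level (with
non-increasing accuracies, correctness is nested, so the emitted label is
correct at level *k* with probability exactly *a(k)*); the first erred
level draws a different sibling token, so hierarchical metrics degrade
gracefully with depth, as they do for real predictors. Scores are the
designed probability of full correctness (a(4) for correct emissions,
1 − a(4) otherwise) plus uniform ±0.1 calibration noise — enough to make
threshold learning non-trivial without destroying the ranking. Toy
reaction tables plant one base reaction per three-level family and mutate
20% of tokens per level-4 child, with 10% of ECs held out to exercise the
fallback path.

What the generator does *not* emulate: biophysically plausible sequences,
real chemistry, correlated model errors, or annotation noise. Passing
tests therefore demonstrate that the *measurement machinery* is correct
under controlled conditions — not that any particular real predictor will
score well.

Parameter recovery is checked at n = 2000 with multi-label and incomplete
rates set to 0: the designed per-level accuracy is defined for a single
emitted label against the protein's primary label, which multi-label truth
would confound. Measured level-k micro precision recovers the designed
values within ±0.03 and coverage within ±2 percentage points.

## Numerical and reproducibility choices

* All randomness (batching, surrogate sampling, generation, stacking) is
  seeded; sub-seeds are derived from the master seed and a context string,
  and the caller's RNG state is never disturbed.
* Ties break lexicographically on the canonical EC string everywhere a
  deterministic choice is needed.
* Reports round-trip through JSON at full double precision
  (`digits = NA`); the TSV mirrors are for human consumption.
* Problem sizes in the test suite (200 oracle instances of ≤ 30 proteins,
  100 threshold scans of ≤ 100 samples, 1000 similarity pairs, 500-sequence
  curation families, n = 2000 recovery runs) were chosen so the whole
  suite exercises every advertised property in about two minutes on one
  core.

## Known limitations

* The built-in clusterer is a desk-scale tool; at hundreds of thousands of
  sequences an external clusterer via `readClusterTsv` is the right path.
* The token-hash fingerprint measures textual, not chemical, similarity;
  conclusions about real reaction chemistry need a cheminformatics
  backend plugged into the same contract.
* Efficiency records (wall time, peak memory, artifact sizes, in every run
  manifest) are informative only — they are hardware-dependent and never
  asserted against published numbers.
* Per-level (rather than per-full-EC) learnt thresholds and score
  calibration (Platt/isotonic) are out of scope.
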