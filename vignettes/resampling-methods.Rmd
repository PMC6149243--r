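---
title: "Resampling strategies for imbalanced binary fingerprint data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resampling strategies for imbalanced binary fingerprint data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fpresample)
```

## The problem

Curated bioactivity and toxicity datasets are almost always imbalanced:
active compounds (toxicants, DILI-positive drugs, assay hits) are a small
minority, with active/inactive ratios commonly between 0.04 and 0.27. A
classifier trained on such data with a symmetric loss drifts toward the
majority class: overall accuracy and even ROC-AUC can look excellent while
sensitivity (the true positive rate, the quantity a toxicologist actually
cares about) collapses, because the default 0.5 decision threshold sits on
the majority side of the score distribution. External, data-level
resampling — equalizing the class counts before training — is the simplest
family of remedies because it works with any classifier.

`fpresample` implements nine sampling conditions behind one uniform
contract, a seeded random-forest cross-validation harness to measure their
effect, and a synthetic generator so that all of it is testable without
any dataset download. The working currency is the `fp_dataset`: a dense
binary fingerprint matrix (MACCS keys, 166 bits, or Morgan/circular
fingerprints, conventionally 2048 bits) with per-row binary labels and
unique compound ids.

## The sampling conditions

All samplers equalize the two classes *exactly*, treat "minority" as
whichever class is rarer (nothing assumes actives are rare), derive all
randomness from one caller seed, and return a `sampling_result` carrying a
complete audit trail (removed rows, duplicated rows, the three parents of
every synthetic row, per-iteration reference fingerprints).

* **none** — the untouched original dataset; the baseline.
* **randus / randos** — classical random under-/over-sampling: remove
  uniform majority rows / append uniform (with replacement) duplicates of
  minority rows.
* **augrandus / augrandos** — under-/over-sampling guided by the
  *most-common-feature* (MCF) fingerprint. The MCF is a synthetic
  reference fingerprint built in `build_mcf()`: the threshold is the
  reference class's average per-bit frequency of ones; candidate bits are
  the bits of the *complete current dataset* whose frequency strictly
  exceeds that threshold, ranked by frequency; the number of set bits is
  the reference class's mean set-bit count per row, rounded half up.
  Under-sampling removes a random part of the rows *most* Tanimoto-similar
  to the majority MCF (pruning redundancy near the class core);
  over-sampling duplicates a random part of the minority rows *least*
  similar to the minority MCF (amplifying rare structures). The MCF is
  recomputed after every batch.
* **kmedoids1 / kmedoids2** — Tanimoto-cost k-medoids under-sampling with
  `n_medoids` = minority count. `kmedoids1` takes the best of 100
  independent random medoid draws; `kmedoids2` starts from one random
  draw and gives each medoid slot 30 random exchanges, always applying
  the exchange and retaining the best configuration ever observed. The
  cost being maximized is the sum over all majority rows of the Tanimoto
  similarity to their most similar medoid, so the retained medoids are
  real instances each representing a group of structurally related
  molecules.
* **smotetc / smotevdm** — binary SMOTE. Seed rows cycle through a seeded
  shuffle of the minority class; each seed row's k = 5 nearest *minority*
  neighbors are found under Tanimoto similarity (TC) or the Value
  Difference Metric (VDM); two distinct neighbors are drawn and each
  synthetic bit is the 2-of-3 majority vote among seed and neighbors —
  the binary analogue of SMOTE's interpolation.

### The Value Difference Metric

For binary features the Stanfill–Waltz VDM reduces to a per-bit lookup:
with $P(c \mid b_j = v)$ the class-conditional value probabilities
(estimated with Laplace smoothing 1 by default, so unseen value/class
combinations stay defined),

$$d(a,b) = \sum_j \sum_{c \in \{0,1\}} \left| P(c \mid b_j = a_j) - P(c \mid b_j = b_j) \right|^q,$$

with exponent $q = 2$ by default ($q$ is exposed because the metric's
literature uses both 1 and 2). Bits whose value distribution separates
the classes strongly dominate the distance; uninformative bits contribute
nothing. The conditionals are fitted on the dataset handed to the sampler
— inside cross-validation, that is the training fold only.

## Decisions made where the design was open

* **Medoid count.** The source description of the restart variant would
  set the medoid count to the *majority* count, which would make
  under-sampling vacuous; both k-medoids methods here use the minority
  count, the only choice that produces the balanced output every
  comparison presupposes.
* **Sensitivity.** Printed formulas for sensitivity in parts of the
  literature this package follows divide by TP + FP (which is precision);
  the prose definition — the true positive rate — is implemented:
  `tp / (tp + fn)`.
* **Augmented batch sizes.** "A number of samples" / "a part of the list"
  are not quantified in the literature; per iteration the candidate list
  is `batch_fraction` (default 0.1) of the current class-size excess and
  `removal_fraction`/`duplication_fraction` (default 0.5) of the list is
  acted on, both exposed as parameters. Small batches per recomputed MCF
  keep the information loss per step small, which is the stated point of
  the augmented variants.
* **MCF scarcity fallback.** If fewer candidate bits clear the threshold
  than the fingerprint needs, remaining bits are taken by descending
  frequency regardless of the threshold and the profile is flagged
  (`fallback = TRUE`) so audits can detect it.
* **Tie-breaks.** Neighbor and assignment ties always go to the lower row
  index; degenerate all-zero vs all-zero Tanimoto is defined as 1
  (identical objects). Both choices exist purely for determinism.
* **Where resampling happens.** Inside the cross-validation loop, on the
  training part of each fold only. Resampling before splitting leaks
  duplicated and synthetic minority rows into held-out folds and inflates
  every metric; that leaky variant exists behind an explicit
  `leaky = TRUE` flag (with a warning) for reproduction studies only.
* **The classifier.** A Breiman random forest specialised to binary
  predictors, implemented in compiled code inside the package (the
  deployment environment provides no R random-forest package): bootstrap
  per tree, `mtry = floor(sqrt(p))` features per node, Gini splits on
  bit = 0/1, trees grown to purity, scores = fraction of tree votes,
  1000 trees by default. Decision threshold 0.5 for the confusion-based
  metrics; AUC uses the vote fractions via the Mann–Whitney rank
  statistic (ties count one half, so constant scores give exactly 0.5).
* **Undefined metrics.** Ratios with zero denominators are reported as 0
  and named in a `flags` field rather than returned as NaN, so fold
  aggregates never silently drop folds.

## The synthetic generator: what it emulates, what it does not

`generate()` draws from a Bernoulli mixture in bit space: per-class
cluster prototypes (three minority clusters versus one majority cluster
by default — minority compounds in real screens are structurally the more
diverse side), rows equal to their prototype with independent per-bit
flips, and a fraction `overlap` (default 0.5) of minority prototypes that
are perturbed copies of majority prototypes, which plants borderline
actives near the decision boundary. Defaults: 166 bits, 300 inactives /
30 actives (imbalance ratio 0.1, inside the 0.04–0.27 band of curated
toxicity datasets), prototype density 0.3 (drug-like MACCS fingerprints
set roughly a quarter to a third of their bits), flip noise 0.2.

The flip-noise default was fixed by characterizing the regime during
design: at 0.1 the mixture is cleanly separable (a 200-tree forest
reaches perfect fold metrics and no majority bias, so nothing about
imbalance can be studied); from 0.15 upward the forest still ranks almost
perfectly (AUC near 1) but its 0.5 threshold is biased toward the
majority class — sensitivity far below specificity — which is precisely
the threshold pathology that resampling addresses. 0.2 sits safely inside
that regime. With `overlap = 0`, low noise, the generator instead gives a
separability sanity world (cross-validated AUC above 0.95).

What the generator does **not** emulate: real substructure correlations
between fingerprint bits (bits flip independently), chemistry (no SMILES
are generated — fingerprint space is the samplers' true domain), assay
noise structure, or train/external-set distribution shift. A green test
on synthetic data therefore establishes that the algorithms behave as
specified on their stated input class — not that any particular accuracy
will be reached on a real toxicity dataset.

## What the acceptance checks establish

The package's acceptance suite (also re-run by `scripts/acceptance.R`) is
property-based: exact balance restoration with subset/superset contracts
for all eight samplers across 50 imbalanced datasets; an exhaustive
post-hoc 2-of-3 parent-vote check of every SMOTE bit; brute-force
optimality of the restart k-medoids (and bounds for the swap variant) on
tiny enumerable instances; brute-force agreement of the confusion metrics
and pairwise-comparison AUC; the hand-derived MCF worked example; the
gap-closing behavior (no-sampling specificity exceeds sensitivity, and
SMOTE-TC / kMedoids2 shrink |sensitivity − specificity|, in at least 8 of
10 seeds under the default generator regime with 10-fold CV and 200
trees); and byte-identical reproducibility of audit trails and reports
under a fixed configuration. The headline percentages of the motivating
study are computed on externally curated datasets (Tox21, NCTR/LTKB-BD
DILI) and are deliberately not asserted anywhere.

## Known limitations

Binary labels and binary features only, by design. Nearest-neighbor
searches are exact (no indexing) — fine for the tens of thousands of rows
these methods target. The VDM is fitted on whatever dataset the sampler
receives; callers doing their own splitting must hand the sampler the
training part only. `kmedoids2` explores randomly rather than greedily;
on large majorities its cost is a lower bound on what a full PAM swap
would reach, which matches its source description.
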