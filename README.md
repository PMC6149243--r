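# fpresample

Resampling strategies for **imbalanced binary chemical datasets**.

Toxicity and bioactivity collections (Tox21 assay endpoints, DILI
benchmarks, screening decks) are dominated by inactives: active/inactive
ratios of 0.04–0.27 are the norm. A classifier trained on such data looks
great on accuracy and AUC while quietly failing at the one thing that
matters — finding the actives — because its decision threshold is biased
toward the majority class, so specificity ≫ sensitivity. `fpresample`
implements nine external (data-level) sampling conditions that equalize
the class counts before training, plus the machinery to measure whether
they close the sensitivity–specificity gap:

| condition | kind | idea |
|---|---|---|
| `none` | baseline | original dataset, untouched |
| `randus` | under | remove uniform majority rows |
| `augrandus` | under | remove rows most Tanimoto-similar to the majority's **most-common-feature (MCF) fingerprint**, recomputed each batch |
| `randos` | over | duplicate uniform minority rows |
| `augrandos` | over | duplicate minority rows *least* similar to the minority MCF |
| `kmedoids1` | under | best of 100 random medoid draws, Tanimoto assignment cost, medoids = minority count |
| `kmedoids2` | under | random medoid swaps (30 per medoid), best configuration ever observed |
| `smotetc` | over | binary SMOTE, Tanimoto k-NN, per-bit 2-of-3 majority vote of seed + 2 neighbors |
| `smotevdm` | over | binary SMOTE with Value-Difference-Metric k-NN |

For binary fingerprints the Tanimoto coefficient is
`T(a,b) = |a∧b| / |a∨b|`, and the VDM distance is
`d(a,b) = Σ_j Σ_c |P(c|bit_j=a_j) − P(c|bit_j=b_j)|^q` with
Laplace-smoothed class-conditional value probabilities (`q = 2` default).

Everything is deterministic under one caller seed, every sampler returns a
complete audit trail (removed/duplicated rows, the three parents of every
synthetic row, per-iteration MCF bit lists), and evaluation is a seeded
random-forest (1000 trees by default, compiled in-package) with
**stratified 10-fold cross-validation that resamples the training folds
only** — held-out rows are never touched, so synthetic rows cannot leak
into the measurement. Reported metrics: accuracy, sensitivity
`tp/(tp+fn)`, specificity `tn/(tn+fp)`, F-measure, and rank-based ROC-AUC.

## Worked example

```r
library(fpresample)

# a synthetic imbalanced dataset: 300 inactives / 30 actives, 166 bits,
# overlapping classes (the generator's default regime)
gen <- generate(generator_spec(), seed = 2026)
d <- gen$dataset
print(d)
#> <fp_dataset> 330 compounds x 166 bits (generic)
#>   actives (y=1): 30   inactives (y=0): 300

res <- resample(d, "smotetc", seed = 2026)
print(res)
#> <sampling_result> method 'smotetc', seed 2026: 600 x 166 (y=1: 300, y=0: 300)
#>   removed 0, duplicated 0, synthetic 270, iterations 0

report <- run_comparison(d, c("none", "randus", "kmedoids2", "smotetc"),
                         n_folds = 10, n_trees = 200, seed = 2026)
print(report)
#> <evaluation_report> 4 condition(s), 10-fold CV, 200 trees, seed 2026
#>   condition accuracy sensitivity specificity f_measure   auc   gap
#> 1      none    0.945       0.400       1.000     0.520 1.000 0.600
#> 2    randus    0.982       1.000       0.980     0.918 0.999 0.020
#> 3 kmedoids2    0.976       0.967       0.977     0.897 1.000 0.010
#> 4   smotetc    0.967       0.633       1.000     0.740 1.000 0.367
```

Reading the numbers: without sampling the forest ranks almost perfectly
(AUC 1.0) yet recovers only 40% of the actives at the 0.5 threshold —
the majority-class bias that imbalance causes. Every sampler shrinks the
sensitivity–specificity `gap`; the under-samplers (`randus`,
`kmedoids2`) close it almost completely on this dataset while keeping
accuracy and AUC intact.

Real data enters through `read_compound_table()` (CSV/TSV, `.smi` +
label table, or SDF) and `compute_fingerprints()` (MACCS 166 keys or
Morgan radius-2, RDKit backend), or through the plain-text dataset format
of `write_dataset()`/`read_dataset()`.

## Command line

Every step is also a subcommand of `fpresample_main()`:

```sh
Rscript -e 'quit(status = fpresample::fpresample_main())' simulate \
    --n-majority 300 --n-minority 30 --seed 1 --output data.fpds
Rscript -e 'quit(status = fpresample::fpresample_main())' sample \
    --input data.fpds --method smotetc --seed 1 \
    --output balanced.fpds --audit audit.json
Rscript -e 'quit(status = fpresample::fpresample_main())' evaluate \
    --train data.fpds --methods none,randus,smotetc,kmedoids2 \
    --folds 10 --trees 1000 --seed 1 --report report.json
```

Subcommands: `fingerprint`, `simulate`, `sample`, `evaluate`,
`similarity-debug`; `--config file` supplies defaults (`key = value`
lines, explicit flags win); identical configuration + seed reproduces
byte-identical artifacts.

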