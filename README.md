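# causalcaps

Chronic-disease risk prediction from tabular clinical data, in two stages:
causal discovery first, classification second. The package is aimed at
biostatisticians and clinical data scientists who want a disease classifier
that operates on an explicit causal graph of clinical features (blood
routine and biochemistry panels, for instance) rather than on the raw
feature table, and who need every stage to be testable without access to
patient data.

## Method

**Stage 1 — causal discovery (DirectLiNGAM).** Features and the disease
label are standardized and treated as variables of a linear non-Gaussian
acyclic structural equation model, `x = Bx + e`. The causal ordering is
estimated iteratively: for a candidate root `x_j`, every other variable
`x_i` is replaced by its least-squares residual

    r_ij = x_i − (cov(x_i, x_j) / var(x_j)) · x_j,

and an independence score — the negated sum of squared negative parts of
mutual-information differences between the two regression directions,
estimated with the maximum-entropy (log-cosh) entropy approximation —
ranks candidates; the most plausibly exogenous variable is appended to the
causal list, all remaining variables are residualized on it, and the loop
repeats. Causal strengths are then the OLS coefficients of each variable
on its predecessors (solved through the covariance matrix), an edge
`j → k` is kept when `|strength[k, j]| > τ`, and every feature without a
directed causal path into the disease label is pruned. The label node is
removed and becomes the class target of the resulting disease causal
graph.

**Stage 2 — graph capsule network.** Each patient instantiates the shared
causal graph with their standardized feature values as node attributes
(value, in-degree, out-degree, label-parent flag). A disentangling layer
applies `K` parallel linear maps per node; one symmetric-normalized
graph-convolution step (`Â = D̃^{−1/2}(A + Aᵀ + I)D̃^{−1/2}`) followed by a
channel map and `tanh` produces a node capsule per node; shared voting
matrices map node capsules to votes for two class capsules (healthy /
diseased); dynamic routing with the squash nonlinearity

    v = (‖s‖² / (1 + ‖s‖²)) · s/‖s‖

aggregates the votes, and the predicted disease probability is
`‖v_diseased‖ / (‖v_diseased‖ + ‖v_healthy‖)`. Training minimizes the
standard margin loss on class-capsule norms with Adam.

**Evaluation.** Confusion counts, accuracy, sensitivity, specificity,
PPV, NPV, F1, the Matthews correlation coefficient, and ROC/AUC (ties
half-credited, so AUC equals the normalized Mann–Whitney U statistic).

**Synthetic EHR generator.** Because no clinical data ship with the
package, a generator produces tables from linear non-Gaussian SEMs with a
logistic disease label and known ground truth (presets `chain5`, `hub10`,
`clinic37`), which is exactly the regime in which the discovery stage is
identifiable — so causal recovery and end-to-end learning are testable.

## Worked example

```r
library(causalcaps)

tab <- make_dataset(preset_spec("hub10"), n = 1500, seed = 11)
model <- lingam(tab, tau = 0.05)
model
#> Causal model (DirectLiNGAM)
#>   variables: 11 (label: disease)
#>   ordering:  f7 -> f3 -> f10 -> f5 -> f9 -> f8 -> f2 -> f1 -> f4 -> f6 -> disease
#>   edges:     5 at threshold 0.05
#>   retained causal graph: 3 node(s), label parents: f1, f2, f3
```

The `hub10` ground truth has exactly three causal parents of the disease
label (`f1`, `f2`, `f3`) among ten features; discovery retains exactly
those and prunes the seven distractors. The full pipeline (simulate →
discover → train → evaluate, with a 2/3 train split) then reports held-out
performance:

```r
res <- run_pipeline(list(preset = "hub10", n = 1500, seed = 11,
                         split = 2/3, out_dir = tempdir()))
res$report
#> Diagnostic metrics report
#>   confusion: tp=210 fp=69 tn=190 fn=31 (n=500)
#>    accuracy sensitivity specificity         ppv         npv          f1
#>       0.800       0.871       0.734       0.753       0.860       0.808
#>         mcc         auc
#>       0.609       0.893
```

Held-out AUC ≈ 0.89 on 500 test patients: the capsule network learns the
disease mechanism from the three-node causal graph alone. Sensitivity
(0.87) is the fraction of diseased patients correctly flagged;
specificity (0.73) the fraction of healthy patients correctly cleared;
MCC summarizes the whole confusion matrix on the [−1, 1] scale.

## Command line

```sh
Rscript $(Rscript -e 'cat(system.file("cli","causalcaps.R",package="causalcaps"))') \
    pipeline --config config.yaml
```

Subcommands `simulate`, `discover`, `train`, `predict`, `evaluate`, and
`pipeline` mirror the R functions; artifacts are plain CSV / JSON /
GraphML files.

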