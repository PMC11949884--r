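---
title: "Causal discovery plus capsule networks for chronic-disease prediction: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Causal discovery plus capsule networks for chronic-disease prediction: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(causalcaps)
```

## The problem

Given a table of numeric clinical features (blood routine and
biochemistry indicators are the motivating case) and a binary disease
label per patient, the package answers two questions in sequence: *which
features are causally upstream of the disease*, and *how well can disease
status be predicted from the causal graph of those features*. The two
stages are deliberately separable: the causal model is an interpretable
artifact in its own right, and the classifier consumes only the pruned
graph.

## Stage 1: DirectLiNGAM-style causal discovery

### Model and assumptions

The discovery stage assumes a linear acyclic structural equation model
over the standardized variables,

$$x = Bx + e,$$

with mutually independent, **non-Gaussian** noise terms $e_k$. Under
these assumptions the causal ordering is identifiable from observational
data; with Gaussian noise it is not, and `causal_order()` emits a warning
when *no* column shows appreciable non-Gaussianity (maximum estimated
negentropy below 0.005). The threshold was chosen from the sampling
distribution of the negentropy estimate: at $n = 5000$, Gaussian columns
fall below 0.001 and uniform or Laplace columns above 0.05, so 0.005
separates them with a wide margin. The maximum (rather than an average)
is used because marginals deep in a causal chain are convolutions that
Gaussianize even when every noise term is non-Gaussian; a single clearly
non-Gaussian root is enough to keep the procedure meaningful.

### The ordering loop

At each step, every remaining variable is scored as a candidate root.
For candidate $x_j$ and companion $x_i$, both regression residuals are
formed with the covariance-ratio formula
$r_{ij} = x_i - \frac{\mathrm{cov}(x_i,x_j)}{\mathrm{var}(x_j)} x_j$,
and the difference of mutual informations between the two directions is
estimated through the maximum-entropy entropy approximation
($H(u) \approx H_{\text{gauss}} - k_1(\mathbb{E}\log\cosh u - \gamma)^2 -
k_2(\mathbb{E}\, u e^{-u^2/2})^2$). The two joint entropies cancel
because each (regressor, residual) pair is a unit-Jacobian linear
transform of the same observation pair, which is what makes the
*difference* computable when neither mutual information is. The score of
a candidate is the negated sum of squared negative parts of these
differences: zero for a perfectly exogenous candidate, increasingly
negative with evidence against exogeneity. Ties in the argmax break to
the lowest column index, so the ordering is deterministic. After a root
is chosen, the remaining variables are replaced by their residuals on it
and re-standardized.

### Strength, thresholding, pruning

Given the ordering, causal strengths are ordinary least squares of each
variable on all its predecessors, solved through the covariance matrix;
a singular predecessor covariance falls back to a ridge solve with
penalty $10^{-6}$ and a warning. An edge $j \to k$ is kept when
$|b_{kj}| > \tau$ (default $\tau = 0.05$ on standardized data — roughly
2–3 standard errors of a null coefficient at the sample sizes the
package targets, $n \gtrsim 1000$). Pruning then retains exactly the
features with a **directed path into the label** (its causal ancestors),
not merely its direct neighbours: association "with the disease" is read
as a causal route into it. The label node is deleted and becomes the
class target; its direct parents are recorded on the graph.

Note the scale convention: coefficients are reported on the scale of the
data handed to `strength_matrix()`. The fitting front end `lingam()`
standardizes first (features *and* label), so its strengths are
standardized effects; recovery tests against a known generator compare
on the generator's scale.

### The label as the causal sink

`lingam()` anchors the disease label as the most downstream variable by
default (`label_as_sink = TRUE`). A standardized Bernoulli column
violates the linear-SEM assumptions badly: empirically it looks
"maximally non-Gaussian" to the independence score and captures the root
position, which inverts every label edge and empties the pruned graph.
Anchoring encodes the modelling stance that clinical features may cause
disease status and not vice versa — also exactly how the synthetic
generator works — while `label_as_sink = FALSE` restores the fully
symmetric procedure for users who want the label to compete.

## Stage 2: the graph capsule network

Every patient instantiates the *same* population-level causal graph;
only the node attribute vectors differ: standardized feature value,
in-degree, out-degree, and a label-parent flag.

The forward pass is, per patient:

1. **Disentangle:** $K$ parallel linear maps applied to each node's
   attributes ($K = 4$ channels by default).
2. **Propagate:** one graph-convolution step per channel with the
   symmetric-normalized operator
   $\hat A = \tilde D^{-1/2}(A + A^\top + I)\tilde D^{-1/2}$, followed by
   the channel's linear map and elementwise $\tanh$; channels are
   concatenated into a node capsule of dimension $d_{\text{node}} = 8$.
   One step is the smallest operator consistent with graph-convolutional
   routing; deeper stacks are intentionally not default.
3. **Vote:** shared matrices $W_j$ ($d_{\text{class}} = 16$) map each
   node capsule to a vote per class capsule (healthy, diseased).
4. **Route:** $r = 3$ iterations of dynamic routing — logits start at
   zero, couplings are a per-node softmax, class capsules are squashed
   coupling-weighted vote sums, and logits grow by the vote–capsule dot
   product. Routing state is re-initialized on every forward pass.
5. **Read out:** the disease probability is
   $\lVert v_d\rVert / (\lVert v_d\rVert + \lVert v_h\rVert)$, 0.5 if
   both norms vanish.

Training minimizes the mean margin loss
($m_+ = 0.9$, $m_- = 0.1$, $\lambda = 0.5$ — the canonical capsule
constants) with Adam (learning rate 0.002, batch size 32, 40 epochs by
default; a rate of 0.01 was observed to destabilize routing-coupled
training, which motivated the conservative default). Gradients are
computed analytically and verified against numerical differentiation in
the test suite; the routing couplings are treated as constants in the
backward pass (a stop-gradient, the common practice in capsule
implementations), while gradients flow through votes, the
graph convolution, the disentangle maps, and the squash of the final
class capsules. All randomness (initialization, batch shuffling) derives
from the single `seed` in `caps_config()`, so loss traces are
bit-reproducible.

### A representational limit worth knowing

The architecture is permutation-equivariant with weights shared across
nodes. Two nodes whose structural attributes (degrees, label-parent
flag) are identical are therefore *indistinguishable*: the model can
only learn functions that are symmetric in their values. This is the
right inductive bias when all retained parents matter (as in the
generator's disease mechanisms, which act through weighted sums), but a
target that singles out one of several structurally identical nodes
cannot be fit exactly. Relatedly, one propagation step averages the
values of adjacent nodes, so a two-node connected graph retains only the
sum of its two values. The test suite's separability check accordingly
uses a single-node graph, where the target is representable.

## The synthetic-EHR generator

The generator emulates the data regime the discovery stage assumes:
linear SEM features with strictly lower-triangular $B$ in the true
order, unit-variance uniform noise by default (bounded and clearly
non-Gaussian; Laplace is the heavy-tailed alternative), and a disease
label drawn from a logistic model on the features with the intercept
calibrated by root bisection so the realized prevalence matches the
target. Presets:

* `chain5` — five features in a chain with coefficients 0.8; the label
  depends on the chain's sink. Exercises ordering and strength recovery.
* `hub10` — three independent label parents (weights 2) plus seven
  distractors at 50% prevalence. Exercises pruning and end-to-end
  learning.
* `clinic37` — 37 features emulating a blood-routine plus biochemistry
  panel: eight label parents (weights 1.2), two downstream tiers of
  correlated markers (coefficients 0.5 and 0.4), prevalence 30%, a
  plausible figure for a chronic-disease cohort panel.

What the generator does **not** emulate: missingness mechanisms,
mixed-type or categorical features, latent confounding, nonlinear
feature–feature effects, and temporal structure. Passing tests therefore
demonstrate correctness of the machinery *in the identifiable regime*,
not performance on hospital data, where any of those violations may
dominate.

## Numerical choices and degenerate inputs

* Standardization uses the unbiased ($n-1$) variance; zero-variance
  feature columns are dropped with a warning, a zero-variance label is
  an error. Standardization is idempotent to $10^{-12}$.
* Residual orthogonality holds to $10^{-10}$ and is property-tested.
* `squash(0) = 0` by continuity; its backward pass at zero is the zero
  map (the function is quadratic near the origin).
* MCC with a zero denominator is 0 (the random-prediction limit); other
  zero-denominator rates are `NaN` with a warning rather than silently 0.
* AUC uses descending-threshold trapezoids with half-credit ties, so it
  equals the normalized Mann–Whitney U statistic exactly; this is
  cross-checked against an $O(n^2)$ pair-count oracle and against pROC.
* F1 defaults to the harmonic mean of PPV and sensitivity; the
  `"balanced"` variant (harmonic mean of sensitivity and specificity)
  is provided because both conventions circulate in the applied
  literature on diagnostic models.
* Parameter initialization is Glorot-scaled Gaussian under the config
  seed. JSON artifacts are written with 17 significant digits, so
  write-then-read is lossless and repeated runs are byte-identical.

## Problem sizes used by the test battery

Ordering recovery uses 50 replicates of `chain5` at $n = 5000$
(recovery rate is required to reach 90%). Strength
recovery uses one `chain5` draw at $n = 50000$ (tolerance $\pm 0.05$).
Pruning is checked exactly against a brute-force transitive-closure
oracle on 200 random DAGs with $p \le 8$. End-to-end learning trains on
1000 `hub10` patients and evaluates on 500 held out (AUC $\ge 0.85$
required; permuted labels must stay in $[0.4, 0.6]$). These sizes were
chosen to keep each property statistically sharp while the whole battery
runs in minutes on one core.

## Known limitations

* The binary disease label inside a linear-SEM discovery stage is a
  model mismatch; it is mitigated by anchoring the label downstream and
  validated on data generated the same way, but causal claims about real
  cohorts should be triangulated (for example with regression
  adjustment) before clinical use.
* Thresholding at a fixed $\tau$ is a pragmatic decision rule; no
  permutation null or bootstrap edge confidence is provided.
* No latent confounders, nonlinear mechanisms, or time series.
* The capsule classifier shares one graph topology across patients; it
  does not learn patient-specific structure.
* Deeper capsule hierarchies and reconstruction regularizers are out of
  scope; the single node-to-class level is the default and only level.
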