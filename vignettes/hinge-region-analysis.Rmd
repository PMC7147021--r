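---
title: "Methods: statistical analysis and prediction of hinge-bending regions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: statistical analysis and prediction of hinge-bending regions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hingeseek)
```

## The problem

Many proteins move between conformers by rotating quasi-rigid *dynamic
domains* about short *hinge-bending regions*. Given a set of protein
sequences with per-residue annotations — `H` for hinge-bending, `D` for
intradomain — two questions arise:

1. Which amino acids favour or disfavour hinge regions, and is the
   preference statistically significant?
2. Can hinge-bending residues be predicted from sequence alone?

`hingeseek` answers both with, respectively, a propensity statistic
(the Hinge Index) and kernel logistic regression (KLR) over
sliding-window encoded sequences, together with the evaluation machinery
these analyses need under severe class imbalance (hinge residues are
typically ~3% of all residues).

## The Hinge Index

For amino acid $a$, with $p(a)$ its overall frequency and $p(a \mid h)$
its frequency among hinge-region residues,

$$HI(a) = \log \frac{p(a\mid h)}{p(a)},$$

with natural logarithm (the base only rescales the statistic).
Positive values mark hinge-favouring residues, negative values
hinge-avoiding ones. Frequencies are plug-in estimates from the counts
$k_a$ (in hinges) of $n_a$ (overall), with totals $N_h$ and $N$.

Significance is assessed exactly: under the null hypothesis that the
$N_h$ hinge positions are a random draw from the $N$ residues, $k_a$
follows Hypergeometric$(N, n_a, N_h)$. The default two-sided p-value
uses the minimum-likelihood rule — the summed probability of all
outcomes no more probable than the observed one — because the
alternative ("assignment is not random") is non-directional; one-sided
tails are available via the `alternative` argument. Zero counts give a
$-\infty$ sentinel flagged in the output rather than a pseudo-count:
smoothing would silently bias small datasets, and the flag preserves
the information that the estimate is off the scale.

## Windowed one-of-n encoding

A window of odd length $w$ is slid over each sequence, one example per
residue. Each window position contributes a block of 24 indicators —
the 20 standard amino acids, the ambiguity codes `B`, `X`, `Z`, and `-`
for positions beyond a terminus — so an example is a binary vector of
$24w$ components with exactly $w$ ones. The target is 1 iff the central
residue is labelled `H`. Even window lengths are rejected because the
definition needs a central residue. Windows centred on ambiguous
residues are kept; their labels are taken as annotated.

Training sets are rebalanced to 1 positive : 9 negatives by discarding
negatives uniformly at random, once per training set. Test sets are
never rebalanced: all reported AUROC/AUPRC values refer to the natural
class balance.

## Kernel logistic regression

The model is $\mathrm{logit}\, y(\mathbf{x}) = \mathbf{w}\cdot
\boldsymbol\phi(\mathbf{x}) + b$ with the feature map defined implicitly
by a kernel $\mathcal K(\mathbf x, \mathbf x') = \boldsymbol\phi(\mathbf
x)\cdot\boldsymbol\phi(\mathbf x')$: linear ($\mathbf x\cdot\mathbf
x'$), polynomial ($(\mathbf x\cdot\mathbf x' + c)^d$, $d \in \{2,3\}$),
or RBF ($\exp\{-\theta\lVert\mathbf x-\mathbf x'\rVert^2\}$). Training
minimises the regularised cross-entropy

$$E = \tfrac12\lVert\mathbf w\rVert^2 - \tfrac\gamma2 \sum_{i=1}^\ell
\big[t_i\log y_i + (1-t_i)\log(1-y_i)\big],$$

in the dual ($\mathbf w = \sum_i \alpha_i \boldsymbol\phi(\mathbf x_i)$,
$\lVert\mathbf w\rVert^2 = \boldsymbol\alpha^{\mathsf T}\mathbf
K\boldsymbol\alpha$) by iteratively reweighted least squares. Each
iteration solves the bordered weighted-ridge system

$$\begin{pmatrix}\mathbf K + \lambda \mathbf S^{-1} & \mathbf 1\\
\mathbf 1^{\mathsf T} & 0\end{pmatrix}
\begin{pmatrix}\boldsymbol\alpha\\ b\end{pmatrix} =
\begin{pmatrix}\mathbf z\\ 0\end{pmatrix},$$

with $\lambda = 2/\gamma$, IRLS weights $s_i = y_i(1-y_i)$ (floored at
$10^{-10}$) and working responses $z_i = \eta_i + (t_i - y_i)/s_i$.
Design choices the schedule leaves open were fixed as follows:
initialisation $\boldsymbol\alpha = 0$, $b = \mathrm{logit}(\bar t)$; a
step-halving line search guarantees $E$ never increases; convergence is
a relative change in $E$ below `convergence_tol` (default $10^{-8}$)
with a 100-iteration cap (a non-converged model is returned with a
warning flag); and a jitter of $10^{-10}\,\mathrm{tr}(\mathbf K)/\ell$
is added to the system diagonal for numerical stability — far below
every equivalence tolerance used in validation. In the large-$\gamma$
limit the fit converges to unregularised logistic regression, which is
verified against `glm` in the test suite.

### Approximate leave-one-out tuning

Hyper-parameters ($\gamma$, plus $c$ or $\theta$) are tuned by
Nelder-Mead in natural-log space (standard simplex coefficients,
relative tolerance $10^{-4}$, 200-evaluation cap) against an
approximate leave-one-out cross-entropy computed from the final IRLS
system: with $\mathbf M$ the bordered system matrix, the left-out
linear predictor is approximated by the predicted residual
$\eta_i^{(-i)} = z_i - \alpha_i / (\mathbf M^{-1})_{ii}$. This is the
standard hat-matrix/leverage argument applied to the converged weighted
system; its fidelity is defined operationally — the test suite requires
it within 15% of brute-force leave-one-out retraining on small sets —
rather than by any particular closed-form reference. Tuning uses the
training set only; the polynomial degree is never tuned.

### Primal weights and their interpretation

For linear and quadratic kernels the primal weights are recovered from
$\mathbf w = \sum_i\alpha_i\boldsymbol\phi(\mathbf x_i)$. The explicit
quadratic map with components $\{\sqrt2\,x_ix_j\}_{i<j}$, $\{x_i^2\}$,
$\{\sqrt{2c}\,x_i\}$, $c$ reproduces $(\mathbf x\cdot\mathbf x'+c)^2$
exactly. Internally a quadratic model is stored as the equivalent form
$\mathrm{logit}\,y = \mathbf x^{\mathsf T}\mathbf Q\mathbf x +
\mathbf{l}\cdot\mathbf x + b_0$ with $\mathbf Q = \sum_i\alpha_i\mathbf
x_i\mathbf x_i^{\mathsf T}$, which predicts identically, keeps ensemble
averaging well defined across members with different $c$, and is the
natural basis for interpretation:

* because the inputs are binary ($x_i^2 = x_i$), the squared and scaled
  linear components fold into one *effective linear weight*
  $Q_{ii} + l_i$ per (position, amino acid) — this is what
  `linear_profile()` reports for both linear and quadratic models;
* the *effective pair weight* of two distinct indicators is $2Q_{ij}$,
  the logit contribution when both are active — `pair_heatmap()` and
  `strongest_pairs()` report these.

Profile normalisation divides by the largest weight *magnitude* of that
amino acid's profile (sign-preserving), so a normalised profile peaks at
$\pm 1$. Cubic and RBF models have no tractable primal form here and are
rejected by `primal_model()`.

## Evaluation under class imbalance

* **AUROC** is computed as the Mann-Whitney statistic with ties counted
  half, equal to the trapezoidal area under the tie-grouped ROC curve;
  a constant scorer gets exactly 0.5.
* **AUPRC** uses the step-wise non-interpolated rule
  $\sum_k (R_k - R_{k-1}) P_k$ over distinct thresholds; interpolation
  conventions change the value, so the choice is stated. Its random
  baseline equals the class prevalence.
* **DeLong's test** compares two AUROCs computed on the same labels via
  structural components; identical classifiers are defined to give
  $p = 1$ (avoiding 0/0 in the zero-variance case).
* **Splitting is always at sequence level** — train/test splits and CV
  folds assign whole sequences, never windows. Overlapping windows of
  one sequence are near-duplicates; splitting them across partitions
  would leak. Folds are stratified so each contains hinge-bearing
  sequences where possible; nested CV flags folds whose test windows
  lack positives and excludes them from the mean, with a warning.
* **Imbalance sweeps** retrain at several positive:negative training
  ratios against one fixed, never-subsampled test set.

## The bootstrap ensemble predictor

`train_ensemble()` draws bootstrap resamples *of sequences* (with
replacement, same sequence count as the input — resampling windows
would break the identity-filter semantics below), then windows,
rebalances 1:9, optionally tunes, and fits a quadratic KLR model per
member, recording each member's training-sequence identities.

For a query, `select_models()` drops every member trained on any
sequence with global-alignment identity above a threshold to the query
(identity = matched columns / alignment columns, path chosen by
Needleman-Wunsch with match +1, mismatch 0, linear gap -1; the function
is pluggable). Comparison is against every member training sequence,
the conservative reading. `aggregate_ensemble()` then averages the
surviving members' primal weights and biases component-wise — averaging
weights, not probabilities, yields a single directly evaluable model —
and `predict_sequence()` scores every residue, calling hinge strictly
above the threshold. The reported confidence is the predicted
probability itself. Default window length 87 with a quadratic kernel;
memory note: members are held in dual form and primal weights are
materialised incrementally during aggregation, since one quadratic
primal at $w = 87$ is a $2088\times2088$ dense matrix.

A CLI (`inst/scripts/hingeseek.R`) wraps generation, Hinge Index
reports, training, window sweeps, ensembles, prediction and weight
export; models and ensembles serialise to versioned JSON.

## The synthetic generator

Because real hinge annotations derive from curated pairs of solved
structures, the package ships a generator of synthetic annotated
sequences used by all tests and examples. Sequences are built as
`D (H D)^k` blocks — hinges always separate two domain segments —
with segment lengths uniform on configurable ranges and residues drawn
i.i.d. from region-specific composition vectors. The defaults are:
domain segments 55–120 residues, hinge segments 2–6, 1–3 hinges per
sequence, giving an expected hinge fraction of ~0.0296 — matching the
~0.03 prevalence typical of curated hinge datasets; background
composition is Swiss-Prot-like, and the default hinge composition
equals the background (no signal). Determinism: each sequence uses a
counter-derived substream of the master seed, so datasets are
reproducible and generation could be parallelised without changing
output.

Pairwise rules plant positional correlations: wherever anchor `(aa1,
region1)` occurs, the residue at a fixed offset (if in `region2`) is
resampled from a distribution with `aa2` multiplied by `boost`. This is
a post-hoc pass, simple but sufficient to plant conjunction-detectable
structure.

### Designed demonstration signals

Two canonical configurations are exported:

* `propensity_demo_config()` — hinge composition enriched in Pro (6x),
  Ser (3x), Gly (2x), devoid of Cys, depleted in large hydrophobics,
  mirroring the qualitative propensity pattern reported for real hinge
  regions (small residues favour hinges; Cys, usually disulphide-bonded,
  avoids them). The contrast strength was chosen so that the signal is
  detectable by a linear model on held-out sequences at desk-scale
  dataset sizes (a literal twofold contrast is statistically visible to
  the Hinge Index at $10^5$ residues but too weak for window-level
  discrimination at a few thousand training windows).
* `conjunction_demo_config()` — additionally plants one pair rule whose
  information is *conjunctive by construction*: common domain Ala
  anchors (3.5x background) boost Trp at the hinge position 8 residues
  upstream, while the domain Trp frequency is raised (12x) to equal the
  resulting marginal hinge-Trp frequency. A window then sees "Trp here"
  about equally often in both classes; only the conjunction "Trp here
  and Ala at +8" separates them — expressible by a quadratic kernel,
  inexpressible by a linear one. The pair offset must lie within the
  window span for the conjunction to be visible; with $w = 21$ both
  members of a +/-8 pair fit in one window. Naive rule placements fail
  this requirement or leak most of their information into marginals
  that a linear model exploits equally well, which is why the
  construction controls the marginal explicitly.

What the generator does *not* emulate: secondary structure, positional
autocorrelation within segments, realistic hinge-placement statistics,
or homology between sequences. Tests passing on generator data
demonstrate that the estimators recover what was planted under the
stated conditions — not that comparable accuracy holds on curated
structure-derived datasets.

## Numerical choices and scales used in validation

The validation suite runs at deliberately desk-scale sizes, chosen as
the package's own study conditions: propensity recovery uses ~$10^5$
residues; type-I control uses 200 replicate null datasets of 10
sequences; the kernel comparison uses 5 replicate datasets of 60
sequences (30 train / 30 test), window length 21 and ~2,300 training
windows after 1:9 rebalancing, with per-family regularisation
($\gamma = 0.1$ linear, $\gamma = 0.01$ quadratic — the quadratic
kernel's larger scale needs stronger regularisation at equal $\gamma$,
and per-family tuning is what the full pipeline would do). Dual-primal
agreement is asserted to $10^{-8}$, the quadratic feature-map identity
to $10^{-10}$, AUROC against exhaustive pair counting to machine
precision, and the approximate LOO to 15% of brute force.

## Known limitations

* The approximate LOO estimate degrades when IRLS weights are extreme
  (near-separable data at large $\gamma$); the tuner treats failed
  evaluations as infinite loss rather than crashing.
* Hinge Index values for amino acids absent from hinges are sentinels,
  not estimates; downstream consumers must check the `infinite` flag.
* `greedy_identity_filter()` honours the redundancy-removal contract of
  word-filter tools such as CD-Hit but is quadratic in the number of
  sequences; it is intended for curated-dataset scales (hundreds of
  sequences).
* Cubic and RBF models cannot be aggregated into ensembles or
  inspected for weights (no finite primal form); they are available for
  training and evaluation only.
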