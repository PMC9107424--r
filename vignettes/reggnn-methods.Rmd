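---
title: "Predicting cognitive scores from connectomes: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting cognitive scores from connectomes: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reggnn)
```

## The problem

A functional connectome is a $d \times d$ matrix of Pearson correlations
between the resting-state fMRI signals of $d$ brain regions (ROIs; the
classical AAL parcellation has $d = 116$). This package predicts a scalar
cognitive score — typically a full-scale or verbal IQ — from such a
matrix, with two pieces working together:

1. **RegGNN**, a small graph convolutional network that regresses the
   score directly on the (regularized) connectome; and
2. a **learning-based sample selection** step that picks the $k$ most
   predictive training subjects *before* the network is trained, using
   the Riemannian geometry of the SPD cone and graph-topological features
   of tangent matrices.

The rationale for selection: if connectome similarity implies score
similarity, subjects that consistently sit close — in *predicted* score —
to many held-out subjects are good representatives of the cohort, while
outliers that would distract a network trained on a handful of samples
are excluded.

## Geometry on the SPD cone

Correlation matrices are positive semidefinite but can be singular, so
each connectome $C$ is first nudged onto the SPD cone,
$P := C + \mu I$ with $\mu = 10^{-10}$ by default. We work under the
Log-Euclidean metric: the matrix logarithm maps the cone isometrically
onto the flat space of symmetric matrices, so

* the geodesic distance is
  $d(P, Q) = \lVert \log Q - \log P \rVert_F$;
* the tangent matrix encoding the geodesic from $P$ to $Q$, parallel
  translated to the identity, is simply $\log Q - \log P$. Transport is
  path-independent under this metric — it is a translation in
  log-coordinates — which is why this closed form is exact and no
  explicit transport formula is needed.

All matrix functions use symmetric eigendecompositions and the output is
re-symmetrized as $(M + M^\top)/2$, so results are exactly symmetric.
If $C + \mu I$ is numerically singular, $\mu$ is escalated by factors of
ten up to $10^{-4}$, after which the offending subject is reported by
id. (This failure mode cannot occur for valid correlation matrices plus
a positive shift, but file-supplied data can be arbitrarily degenerate.)

## Tangent-matrix features

A tangent matrix $S$ is a signed symmetric matrix describing linearized
connectivity *changes* between two subjects. Eight feature modes
compress it for the selection regressor:

| mode | content | length |
|------|---------|--------|
| `tm` | row-major upper triangle of $S$, diagonal included | $d(d{+}1)/2$ |
| `dc` | degree centrality of $S$ | $d$ |
| `ec` | eigenvector centrality of $S$ | $d$ |
| `cc` | closeness centrality of $S$ | $d$ |
| `cnu`| `c(dc, ec, cc)` unscaled | $3d$ |
| `cns`| the same, each block min–max scaled | $3d$ |
| `g`  | Log-Euclidean distance | 1 |
| `a`  | Euclidean distance of upper-triangular parts of $P_i$, $P_j$ | 1 |

Centralities need non-negative weights, so the absolute off-diagonal
entries of $S$ are used as the edge weights and the diagonal is treated
as absent: the magnitude of a connectivity change is the relevant
signal, and the graph topology itself is untouched. Conventions worth
stating exactly:

* **Degree** is the mean absolute edge weight,
  $\sum_{j \ne i} |S_{ij}| / (d-1)$.
* **Eigenvector centrality** is the principal eigenvector of $|S|$,
  non-negative and normalized to unit Euclidean norm. It is computed by
  power iteration (uniform start, tolerance $10^{-10}$, at most 1000
  iterations) applied to $|S| + I$: the spectral shift leaves the
  eigenvectors unchanged but guarantees convergence on bipartite-like
  graphs, where iterating on $|S|$ itself oscillates between two
  directions (the 3-node star is the canonical example). Graphs whose
  two leading eigenvalues are (near-)tied have an ill-conditioned
  principal eigenvector; the iteration reports non-convergence there
  rather than return an arbitrary vector.
* **Closeness** converts weights to lengths as $1/|S_{ij}|$ (stronger
  change = shorter distance), runs Dijkstra via igraph, and applies the
  Wasserman–Faust component scaling
  $\frac{r_i}{d-1} \cdot \frac{r_i}{\sum_{j} \delta(i,j)}$ so that
  disconnected graphs are handled gracefully; isolated nodes score 0.
* **Min–max scaling** uses $(v - \min v)/(\max v - \min v)$, mapping
  into $[0, 1]$ with constant vectors sent to zero. (The variant that
  subtracts the maximum instead of the minimum lands in $[-1, 0]$;
  since the downstream consumer is a linear regressor with intercept,
  the two differ only by an affine shift, and the $[0,1]$ form is the
  one consistent with the scaled features' documented range.)
* The `tm` vectorization order is fixed (row-major upper triangle
  including the diagonal) and is the only mode that is *antisymmetric*
  in the pair: swapping the two subjects negates it. All other modes
  are symmetric.

## Sample selection

Within a training set of $n$ subjects, selection runs a nested $N$-fold
cross-validation ($N = 5$ by default; any $N \ge 2$ works, and $N$
trades the number of train-in pairs against holdout coverage). Subject
positions are shuffled once with the configured seed and split into
near-equal folds (remainders go to the first folds). Each fold in turn
becomes the *holdout* group; the rest is the *train-in* group:

1. tangent matrices at the identity are computed for all
   $n_s(n_s-1)/2$ train-in pairs and all $n_s n_h$ train-in/holdout
   pairs (log-matrices are cached per subject, so each pair is a single
   matrix subtraction);
2. each tangent matrix becomes a feature vector under the configured
   mode;
3. a linear map $f$ is fit by ordinary least squares (with intercept)
   from train-in pair features to absolute score differences
   $|IQ_i - IQ_j|$; when the feature dimension exceeds the number of
   pairs — possible for `tm` — the minimum-norm solution is returned
   (column centering plus an SVD pseudoinverse, the same convention as
   scikit-learn's `LinearRegression`);
4. for every holdout subject, the $k$ train-in subjects with the
   smallest predicted difference have their frequency counter
   incremented (ties broken by ascending subject id).

After $N$ folds — each subject is in the train-in group exactly $N - 1$
times — the $k$ subjects with the highest cumulative frequency are
selected, ties again by ascending id. Predicted differences are used
as-is for ranking: negative predictions are not clipped, since ranking
is invariant under monotone shifts.

Two ambiguities were resolved as follows. The counting *direction*
(increment train-in subjects per holdout subject, not the reverse) is
the one under which cumulative counting is meaningful, because only
train-in membership recurs across folds. And selection always operates
on the $\mu$-regularized matrices *with* their negative correlations:
zeroing negatives is a training-side preprocessing choice for the
network only.

### What the frequency map can and cannot recover

For each holdout subject the counter rewards the $k$ nearest train-in
subjects, so within a tight score cluster roughly $k$ members — those
most central in score — accumulate near-ceiling counts. The selected
top-$k$ therefore concentrates *within* clusters reliably, but whether
the global top-$k$ contains exactly one representative of each of $k$
planted clusters depends on near-tied count comparisons *across*
clusters, which are sensitive to fold composition. Exact
one-per-cluster recovery is consequently an unstable event even when
the regressor predicts score differences essentially perfectly; the
acceptance script reports the observed recovery rate on a planted
three-cluster design rather than assuming it.

## RegGNN

The network input is the regularized adjacency with negative
correlations removed (entrywise zeroing by default; clamping negative
*eigenvalues* is available as `neg_handling = "clamp_eigenvalues"` for
fidelity to that reading — for a PSD correlation matrix the two differ,
and zeroed entries match the observation that positive correlations
carry most of the signal). With self-loops $\tilde P = P + I$ and
degree normalization
$\hat A = \tilde D^{-1/2} \tilde P \tilde D^{-1/2}$ (spectral radius
$\le 1$), the forward pass from $H^{(0)} = I$ is

$$H^{(1)} = \mathrm{ReLU}(\hat A\, W^{(1)}), \qquad
  H^{(2)} = \mathrm{ReLU}(\hat A\, H^{(1)} W^{(2)}),$$

with layer widths $d_0 = d$ (116 in the reference setting), $d_1 = 64$,
$d_2 = 1$, dropout (rate 0.1) after the first convolution only, and a
fully connected readout mapping the $d$-vector $H^{(2)}$ to the
predicted score. Dropout uses inverted scaling, so evaluation is a
plain deterministic forward pass.

Training minimizes mean squared error (the loss is a package choice;
MAE is the *reported* metric) by full-batch Adam
($\beta_1 = 0.9$, $\beta_2 = 0.999$, $\epsilon = 10^{-8}$), learning
rate $10^{-3}$, 100 epochs, and classical L2 weight decay
$5 \times 10^{-4}$ added to the gradients of the two convolution
weights and the readout weights. Full batch is the natural regime when
training on $k \le 15$ selected samples and removes ordering
nondeterminism. Two initialization choices are documented and
toggleable: weights are seeded uniform Glorot draws, and the readout
bias starts at the training-set mean score (`bias_init = "mean_score"`),
which centers early predictions and makes 100-epoch training converge
from sensible residuals; the bias is exempt from weight decay, since
decaying a bias near 110 IQ points would systematically drag
predictions downward. Backpropagation is implemented in closed form and
verified against finite differences to $10^{-4}$ relative error.

The absolute values of the readout weights rank ROIs by their influence
on the prediction (`region_weights()`); rankings from models trained
across the $k$-sweep can be averaged with `average_region_rankings()`
for biomarker reporting.

## The evaluation pipeline

`run_pipeline()` mirrors the full training process: an outer 3-fold
cross-validation splits subjects by id (file order is irrelevant);
within each fold, sample selection sees *only* the training split, the
network trains only on the $k$ selected subjects, and metrics (MAE,
RMSE) are computed on the untouched test split, for every $k$ in the
sweep (2–15 by default), plus a baseline trained on all training
subjects and a mean-predictor null. Per-$k$ results are averaged across
folds (fold-averaging, not error-pooling, matches "3-fold
cross-validation, we report the mean"); the summary reports mean ± sd
and min/max over the sweep, and a Welch two-sample $t$-test compares
the pooled per-subject absolute errors of the best-$k$ model against
the baseline (a documented convention — the pairing is not otherwise
determined). One master seed derives the split, selection, and
per-model seeds by fixed offsets, so runs are reproducible end to end
and components are independently reproducible.

## The synthetic cohort generator

Cohorts are generated in log-matrix coordinates so that the planted
geometry is exactly the geometry the selection method assumes: each
cluster receives a center log-matrix (entrywise sd
`between_cluster_sd`, default 1), each subject a perturbation of scale
`within_cluster_sd`, and the result is mapped through the matrix
exponential and rescaled to unit diagonal. The rescaling slightly
distorts the planted log-space geometry; all invariants are therefore
tested after rescaling. Score defaults emulate a neurotypical
full-scale IQ distribution (mean ≈ 111.6, sd ≈ 12): three clusters at
the mean and one standard deviation either side, with
`score_sd = 4` of independent noise.

Couplings:

* `cluster_only` — isotropic perturbations; the score is the cluster
  center plus noise.
* `linear_in_tangent` — within-cluster deviations lie along a *single
  shared tangent direction*, and the score is linear in the coordinate
  along it (spread `coupling_score_sd`, default 0.1 IQ points). The
  rank-one design is deliberate: it makes every homogeneous tangent
  feature exactly proportional to within-cluster score differences, so
  the linear regressor's target is realizable and parameter-recovery
  tests are meaningful. With isotropic deviations no linear map can
  predict $|\beta \cdot \delta|$ from sign-invariant features, and such
  a cohort could not validate the selection machinery.
* `pure_noise` — scores independent of the connectomes, for degradation
  tests.

What the generator does *not* emulate: fMRI time-series noise,
site/batch effects, head motion, realistic correlation structure of
real parcellations, or heavy-tailed score distributions. Passing tests
on these cohorts validate the machinery — geometry, features,
selection, optimization, bookkeeping — not clinical performance on real
data.

## Problem sizes in the tests

The test-suite runs at desk scale, chosen so the full suite completes
in well under a minute of compute per module: geometry properties at
$d \in \{2, 5, 20, 116\}$, centrality oracles on 200+ random graphs of
at most 6 nodes (against Floyd–Warshall and dense eigensolvers),
selection oracle equivalence at 10–12 subjects across all eight modes,
and an end-to-end pipeline at $n = 60$, $d = 30$ with the full
$k = 2..15$ sweep. The overfit-capacity check trains on five subjects
for 500 epochs.

## Known limitations

* The procedure assumes score differences are (approximately) linear in
  the chosen tangent features; the `tm` mode in particular is
  antisymmetric in each pair while the regression target $|\Delta IQ|$
  is symmetric, so `tm` can only exploit intercept and asymmetry-driven
  structure — a limitation inherent to the formulation, visible in the
  planted-cluster analysis above.
* Power-iteration eigenvector centrality declines to answer on graphs
  with a near-degenerate leading eigenpair (by design).
* The network is CPU-only and full-batch; it targets $k \le 15$
  training graphs and $d$ in the low hundreds, not large batches.
* Serialized model files are plain text, portable but not compact.
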