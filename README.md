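# reggnn

Predicting scalar cognitive scores (full-scale or verbal IQ) from
functional brain connectomes with a graph convolutional regression
network — **RegGNN** — trained on a small, carefully *selected* subset of
the training cohort.

## Who this is for

Researchers in network neuroscience / connectomics who have, per
subject, a d×d correlation matrix of regional rs-fMRI signals (e.g. the
116-ROI AAL parcellation) and a behavioral score, and who want a
reproducible, CPU-only pipeline for connectome-based score regression
with built-in training-sample selection and biomarker (ROI weight)
reporting. No imaging data ships with the package: a synthetic cohort
generator with planted cluster structure makes every component testable
offline.

## The method

**Geometry.** A connectome `C` is regularized onto the SPD cone,
`P = C + μI` (μ = 1e-10), which carries the Log-Euclidean metric:
`d(P, Q) = ‖log Q − log P‖_F`, and the tangent matrix of the geodesic
from `P` to `Q`, parallel translated to the identity, is
`S = log Q − log P` — the linearized "difference" of two connectomes.

**Sample selection.** Inside the training set, a nested N-fold
cross-validation repeatedly splits subjects into train-in and holdout
groups. Pairwise tangent matrices are compressed into feature vectors —
the full upper triangle (`tm`), degree / eigenvector / closeness
centrality of the tangent graph (`dc`, `ec`, `cc`), their
concatenations (`cnu`, `cns`), or scalar distances (`g` geometric, `a`
Euclidean) — and a linear map `f` is fit from train-in pair features to
absolute score differences `|IQ_i − IQ_j|`. For each holdout subject
the k train-in subjects with the smallest predicted difference are
counted in a frequency map; after all folds, the k subjects with the
highest cumulative frequency become the training set for the network.

**RegGNN.** With self-loops and symmetric degree normalization
`Â = D̃^{−1/2}(P + I)D̃^{−1/2}` (negative correlations zeroed first),
two graph convolutions `H⁽¹⁾ = ReLU(Â W⁽¹⁾)`,
`H⁽²⁾ = ReLU(Â H⁽¹⁾ W⁽²⁾)` (d₁ = 64, d₂ = 1, dropout 0.1 after the
first layer) feed a fully connected readout that maps the d-vector to
the predicted score. Training: full-batch Adam, lr 0.001, weight decay
5e-4, 100 epochs, MSE loss. The absolute readout weights rank brain
regions by influence on the prediction.

**Evaluation.** 3-fold outer cross-validation; selection sees only the
training split; MAE and RMSE on the untouched test split, swept over
k = 2..15, with mean ± sd (min, max) summaries, a train-on-everything
baseline, a mean-predictor null, and a Welch t-test comparing best-k
against baseline absolute errors.

## Worked example

```r
library(reggnn)

# synthetic cohort: 30 subjects, 20 ROIs, 3 score clusters (FIQ-like)
co <- generate_cohort(cohort_spec(n_subjects = 30, d = 20, seed = 7))

# pick the 5 most predictive training subjects (degree-centrality mode)
sel <- select_samples(co$subjects,
                      selection_config(k = 5, n_folds = 5, mode = "dc", seed = 7))
print(sel)
#> <selection: k = 5 , N = 5 , mode = dc >
#> selected: s002, s009, s013, s017, s029
head(sort(sel$frequency, decreasing = TRUE), 5)
#> s002 s009 s013 s017 s029
#>   12    8    8    8    8
```

`s002` ranked among the 5 nearest predicted neighbors of holdout
subjects 12 times across the 5 folds — it is the most "representative"
subject of this cohort in predicted score.

```r
cfg <- pipeline_config(outer_folds = 3,
                       selection = selection_config(n_folds = 5, mode = "dc"),
                       model = reggnn_config(d = 20),
                       k_sweep = 2:8, seed = 7)
report <- run_pipeline(co$subjects, cfg)
print(report)
#> Evaluation over 3 outer folds, 30 subjects, d = 20
#> k                 MAE       RMSE
#> 2              11.761     13.559
#> 3              11.860     13.630
#> 4              10.571     12.242
#> 5               9.702     11.388
#> 6               9.932     11.567
#> 7              10.194     11.732
#> 8              10.376     11.989
#> baseline        8.601     10.175
#> mean_pred       9.119     10.652
#> over k: MAE 10.628 +/- 0.856 (9.702, 11.860); RMSE 12.301 +/- 0.926 (11.388, 13.630)
#> best k = 5; Welch t-test (best k vs baseline) p = 0.4702
```

Each sweep row is the fold-mean test error when RegGNN is trained on
only the k selected subjects; `baseline` trains on every training
subject, `mean_pred` always predicts the training-mean score. On this
small cohort the best selected-k model (k = 5, MAE 9.702) is close to
the 20-subject baseline while training on a quarter of the data. ROI
importance for a trained model comes from `region_weights(fit$params)`.

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "reggnn", package = "reggnn"))')
Rscript $CLI simulate --out cohort/ --n 60 --d 30 --seed 1
Rscript $CLI select   --matrices cohort/ --scores cohort/scores.csv --k 5 --mode dc --out selection.tsv
Rscript $CLI pipeline --matrices cohort/ --scores cohort/scores.csv --out report/
Rscript $CLI report   --dir report/
```

Subcommands `train` and `evaluate` work on explicit subject-id lists
and serialized parameter files; a YAML `--config` file supplies
defaults, and every flag overrides it. Input format: one
whitespace-delimited d×d matrix file per subject (file name = subject
id) plus a `scores.csv` with header `id,FIQ,VIQ`.

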