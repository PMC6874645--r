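---
title: "Methods: early colorectal cancer prediction from case-report tables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: early colorectal cancer prediction from case-report tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Early-stage colorectal cancer is highly curable, but screening colonoscopy
finds few cases among many examinees, and in settings with scarce medical
resources a large share of missed diagnoses is clinically costly. The
`ecpredict` package implements an automated risk classifier built on the
cheapest data available for nearly every patient: the routine case report —
demographic and behavioral attributes (age, gender, smoking and drinking
history), endoscopic findings (lesion location, polyp size, lobulation),
and blood-test values. One row per patient, `m` numeric features (the
emulated cohort uses `m = 50`), and a binary outcome `y = 1` when pathology
confirms early cancer. The positive class is a small minority, which is why
the package reports the false negative rate, FNR = FN / (TP + FN) — the
missed-diagnosis rate — alongside accuracy, precision, recall and F1.

## The pipeline

Four stages, executed in this order by `ecp_run_once()` /
`ecp_run_repeated()`:

1. **Standardization** (`zscore_fit_transform`): each feature column is
   mapped to mean 0, standard deviation 1 using the *population* standard
   deviation (divide by *n*), so the unit-variance postcondition is exact.
   Constant columns are mapped to zero rather than erroring: they carry no
   information for any later stage.
2. **Nonnegativity restoration** (`rescale_nonnegative`): standardization
   produces signed values, but the factorization stage requires a
   nonnegative matrix and the belief-network stage expects inputs that can
   act as probabilities. Each column is affinely mapped onto [0, 1]
   (minimum to 0, maximum to 1), preserving within-column order. The two
   steps together are `preprocess_fit()`; fitted statistics can be applied
   to new samples with `preprocess_apply()` (out-of-range values are
   clipped).
3. **Nonnegative matrix factorization** (`nmf_factorize`): the `n x m`
   preprocessed matrix `X'` is factorized as `X' ~ W H` with `W >= 0`
   (`n x k`) and `H >= 0` (`k x m`), minimizing the squared Frobenius
   error by Lee–Seung multiplicative updates. Rows of `W` are the
   `k`-dimensional reduced samples passed downstream (default `k = 14`);
   `H` links each extracted feature to the original clinical attributes
   and is exported by `feature_weight_report()`.
4. **Deep belief network + linear SVM**: a stack of restricted Boltzmann
   machines (architecture `k -> 10 -> 4` by default) is pretrained
   greedily by CD-1 contrastive divergence on the training rows, fine-tuned
   with a supervised sigmoid head by full-batch back-propagation, and the
   4-unit top layer is exported as the feature matrix `X2`. A linear
   soft-margin SVM (`svm_fit`, SMO in the dual) is the final classifier;
   prediction is `sign(w . x + b)` with ties assigned to the cancer class.

Evaluation follows a stratified repeated-split protocol: within each label
class, 90% of the records are drawn for training and 10% held out
(`stratified_split`), the belief network and SVM are retrained per split,
and the five measures are averaged over `n_runs = 100` splits by default.

## Where information can leak, and the two modes

The source protocol factorizes the **full** matrix before splitting, so
unlabeled test rows influence the learned representation. The default mode
reproduces that order deliberately. `strict_no_leakage = TRUE` instead
standardizes and factorizes on the training rows only and maps held-out
rows into the latent space by nonnegative least squares against the fitted
`H` (`nmf_project`). Labels are never visible to any stage beyond the
training partition in either mode (the stratified split itself must read
all labels to stratify); the test suite verifies that flipping a held-out
label cannot change any fitted parameter.

## Tunable parameters that matter

| parameter | default | meaning / rationale |
|---|---|---|
| `k` | 14 | latent dimension of the factorization; the protocol's selected value on its cohort. Select per dataset with `k_sweep()`. |
| `hidden_sizes` | 10, 4 | belief-network widths; the final width (4) is the extracted feature count. The middle width is a free design choice. |
| `pretrain_epochs`, `learning_rate`, `batch_size`, `cd_steps` | 100, 0.1, 10, CD-1 | per-layer contrastive-divergence training; standard small-data settings. |
| `finetune_epochs`, `finetune_lr`, `momentum` | 1000, 0.5, 0.9 | full-batch heavy-ball back-propagation. Full-batch gradients are means over ~250 rows, so steps are small; plain descent at rate 0.1 for 100 epochs leaves the network underfitted, the extracted features uninformative, and the SVM collapses to the all-negative majority rule on a 10%-positive cohort. The momentum setting reaches a training cross-entropy regime where the features separate the classes. |
| `svm_C` | 1 | soft-margin penalty; `Inf` gives the hard margin of the printed formulation (rarely appropriate for noisy features). |
| `test_fraction`, `n_runs` | 0.10, 100 | the stratified repeated-split protocol. |

Two numerical choices deserve emphasis:

* **Feature standardization before the SVM.** Fine-tuned top-layer units
  saturate near 0/1; their raw activations can be nearly constant columns
  with informative variation at the 1e-3 scale, on which a unit-scale
  margin penalty is meaningless. `run_split` therefore z-scores the
  extracted features on training statistics before fitting the SVM and
  applies the same transform to the test block.
* **NMF initialization.** Multiplicative updates converge slowly from
  random starts on ill-conditioned low-rank matrices. The default
  initialization is a hybrid: the first restart uses the SVD-based NNDSVD
  point (zeros perturbed to small seeded positives so updates cannot lock
  them), the remaining restarts are uniform random; the lowest final
  objective wins. Denominators carry an epsilon of 1e-12; the objective
  trace is checked non-increasing to 1e-9 slack at every iteration.

## Choosing the latent dimension

`k_sweep()` re-runs the downstream pipeline for each candidate `k` and
records mean precision, recall and F1 over repeated splits. Mean F1 rises
steeply until the informative dimension is reached and then plateaus with
noise: beyond that point extra latent dimensions neither help nor
measurably hurt a downstream classifier that re-weights them. On such a
curve the raw argmax is close to uniformly distributed across the plateau
and systematically overshoots. The sweep therefore reports two values: the
raw argmax (`argmax_k`) and the one-standard-error selection
(`selected_k`) — the smallest `k` whose mean F1 is within one standard
error of the best, the same parsimony convention used for regularization
paths (e.g. `lambda.1se`). `selected_k` is the package's recommendation.

Note that standardizing and min–max rescaling each column adds two
affine rank-one components to the matrix, so the effective dimension the
sweep sees is about two above the rank of the raw data; selections
slightly above a generative rank are expected and correct.

A second practical caveat, measured during development: a *reduced*
training budget (fewer pretraining/fine-tuning epochs) underfits small-`k`
models disproportionately and biases the selection upward. Dimension
sweeps should run at full training fidelity even when other experiments
are scaled down.

## The synthetic cohort generator

The clinical records behind the source study are private and undeposited,
so the package ships a seeded generator (`generate_samples`,
`make_reference_fixture`) that emulates the *structure* the pipeline
assumes, not the cohort's actual marginals:

* `n = 270` patients, `m = 50` nonnegative features in three blocks:
  10 binary demographic/behavioral indicators, 25 endoscopic measurements,
  15 blood values.
* A planted nonnegative low-rank structure `X = clip0(U V + eps)` with
  `U` (`270 x 5`) and `V` (`5 x 50`) drawn entrywise Gamma(2, 2) — mean 1,
  strictly positive, identifiable up to scaling/permutation — and Gaussian
  noise of sd 0.5 (moderate relative to signal entries of mean 2.5).
* The last 10 columns are regenerated as pure gamma noise: redundant
  attributes carrying no label signal.
* Binary columns are thresholded at their median.
* Labels follow a logistic model on the first two latent factors with
  slope 4; the intercept is calibrated so realized prevalence lands within
  two percentage points of the 10% target (if a Bernoulli draw strays
  outside the band, the samples with the most extreme class probabilities
  are flipped to the nearest in-band count, deterministically).

All label signal lives in `U`; the noise columns carry none. Fixture
variants: `"noiseless"` (no noise, all-continuous, no redundant columns —
numerical rank exactly 5) and `"separable"` (noiseless plus deterministic
threshold labels with a planted margin: latent rows whose score falls
within 0.5 score-sd of the labeling threshold are redrawn). The separable
world exists so that "the pipeline classifies a separable-by-construction
cohort perfectly" is a meaningful end-to-end test.

What a green test on this generator does **not** establish: performance on
real case reports (unknown marginals, missingness, measurement artifacts,
label noise), robustness to distribution shift, or the clinical validity
of the extracted attribute weights. It establishes that every stage
implements its contract and that the pipeline recovers planted structure
it was designed to recover.

## Degenerate inputs and tie-breaks

* Constant columns: standardized to zero, flagged, never an error.
* Degenerate metric denominators (e.g. no predicted positives): the
  measure reports 0 with an `undefined` flag so repeated-split averages
  never abort.
* A point exactly on the SVM hyperplane is classified positive (the
  conservative choice for a cancer screen).
* SMO working pairs are chosen by maximal KKT violation with ties to the
  lowest index; the solver is exactly reproducible.
* All randomness (initializations, Gibbs draws, batch orders, splits) is
  driven by explicit seeds; repeated runs with one master seed are
  byte-identical. Temporary RNG state is isolated from the caller.

## Known limitations

* The CD-1 gradient is a biased estimate of the log-likelihood gradient;
  the bias is negligible near initialization (the enumeration-oracle test
  quantifies this on a 2x2-unit machine) but grows with weight magnitude.
* Multiplicative NMF updates can require tens of thousands of iterations
  for near-exact reconstruction of ill-conditioned low-rank matrices;
  for pipeline use (where `W` feeds a classifier) the default 500
  iterations are ample, but reconstruction studies should raise
  `max_iter`.
* Display truncation: the two-decimal display mode truncates rather than
  rounds (8/9 shows as 0.88), matching the narrative convention of the
  source protocol; full-precision values are always carried internally.
* The pipeline is binary-outcome only, assumes a complete matrix (missing
  values are rejected, not imputed), and implements no probability
  calibration or kernels.
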