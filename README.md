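# losformer

Attention-based prediction of ICU length of stay (LOS) for sepsis patients
from 16 routinely collected clinical and SOFA-related features, with a
calibrated synthetic-cohort generator, a cross-validation/ablation harness,
and Shapley attribution.

## Who this is for

Researchers studying deep tabular models on small clinical cohorts, and
anyone who needs a reproducible, fully inspectable reference implementation
of a CLS-token transformer regressor for structured ICU data. The clinical
cohort this model family was developed on is private, so the package ships a
generator that reproduces that cohort's *published* summary statistics; all
experiments here run on synthetic data.

## The model

For a standardized feature vector `x ∈ R^16`, the regressor is

1. batch norm over the input channels;
2. a feature tokenizer: each scalar feature `x_i` is embedded as its own
   token `x_i W_i + b_i ∈ R^d`, and a trainable, zero-initialized CLS token
   is prepended, giving `z ∈ R^(17×d)`;
3. a transformer encoder block: 5-head self-attention
   `softmax(QKᵀ/√d_k)V` with residual connections, layer norm, and a ReLU
   feed-forward network;
4. batch norm over the encoded token activations;
5. a **skip-connected token head**: the encoded CLS token (global summary)
   is added to a dense projection `f = Dense(Flatten(f′))` of the 16 encoded
   feature tokens (local detail), and `t_sc = Dense(CLS + f)` feeds a 1-unit
   output layer predicting LOS in days. Ablation modes `global_only`
   (`Dense(CLS)`) and `local_only` (`Dense(f)`) isolate the two information
   paths.

Training is Adam at 1e-3 with a 0.96 staircase decay every 10 epochs, batch
size 32, MSE loss on raw days, and validation-MAE early stopping. Forward
and backward passes are hand-written R matrix algebra, verified against
finite differences and brute-force oracles in the test suite.

The synthetic generator is a single-factor Gaussian copula: a latent normal
drives ICU LOS through a moment-calibrated truncated lognormal, and each
feature loads on that latent with an iteratively calibrated coefficient so
the realized feature–target correlations match the published ones (Pearson
for numeric, point-biserial for binary features).

## Worked example

```r
library(losformer)

# calibrate the generator to the published cohort table and draw a cohort
specs     <- table1_specs()
marginals <- calibrate_marginals(specs$marginals, seed = 1)
copula    <- calibrate_latent(specs$copula, marginals, seed = 1)
cohort    <- generate_cohort(2000, marginals, copula, seed = 1)

# preprocess: IQR outlier rule on the target, then four-fold CV
filtered <- filter_outliers(cohort)$cohort        # keeps 1944 of 2000 rows
cv <- crossvalidate(filtered,
                    los_config(d = 10, ffn_hidden = 40, seed = 1),
                    train_config(max_epochs = 40, patience = 8, seed = 1),
                    split_seed = 1, keep_fits = TRUE)
cv
#> <los_cv> 4 folds, common test set of 389 rows
#>   r2   0.296 +/- 0.020
#>   mae  2.178 +/- 0.032
#>   rmse 2.843 +/- 0.041

# explain one test patient
bg  <- shap_background(filtered, n = 32, seed = 1)
att <- shapley_sampled(cv$fits[[1]], filtered[cv$split$test_indices[1], ],
                       bg, n_permutations = 200, seed = 1)
att
#> <los_attribution> (sampled) base 4.766 days -> prediction 6.419 days
#>   largest contributions: GCS +1.211, MV -0.538, PF +0.438
```

Reading the numbers: each of the four fold models is scored on the common
20% test set; `r2` is the share of LOS variance explained, `mae`/`rmse` are
in days. The attribution's base value (4.77 days) is the mean model
prediction over the background sample, and per-feature contributions sum
exactly to the difference between the patient's prediction and that base.
Mechanical ventilation, the Glasgow Coma Scale and the P/F ratio — the
features with the strongest published correlations — dominate the importance
ranking on this synthetic cohort.

`autoplot(cv)` draws the per-fold calibration plot;
`tidy()`/`glance()` methods return per-fold and summary tibbles. A thin CLI
(`inst/cli/losformer`) wires the same functions into `generate`,
`preprocess`, `train`, `evaluate`, `ablate` and `explain` subcommands.

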