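# adaptivenet

Forecasting rheumatoid-arthritis disease activity from heterogeneous
clinical event histories with a recurrent neural network, in R.

RA registries record, per patient, an irregular mix of events: clinical
visits carrying the DAS28-BSR disease-activity score (plus joint counts,
inflammation markers and patient-reported outcomes, all with substantial
missingness) and medication adjustments (drug, drug class, prednisone
dose).  This package implements **AdaptiveNet**, an architecture built for
exactly that data shape, together with everything needed to study it end
to end: a seeded synthetic registry generator, cohort construction with
leakage-safe patient-level cross-validation, classical baselines, and the
full evaluation machinery.

The model encodes each event with a type-specific two-layer encoder into a
common latent space (the second layer is one shared parameter block),
pools the date-sorted latent sequence with an LSTM into a fixed-length
history encoding

```
h = LSTM( φ_visits(x_1), φ_meds(x_2), …, φ_visits(x_T) ),
```

and predicts from `ρ([h ; general patient features])`: the probability of
active disease (DAS28-BSR > 2.6) at the next visit (classification), or
the numeric change in DAS28-BSR (regression), with the forecast reported
as `reference + change` clamped to the instrument range [0, 9.4].
Training is Adam (learning rate 1e-4, batch size 256) with binary
cross-entropy / MSE loss; forward and backward passes are hand-derived and
implemented in RcppArmadillo, with gradient correctness pinned by a
finite-difference oracle in the test suite.  Baselines (random forest with
100 trees / depth 12, linear and logistic regression, RBF SVM with C = 10)
consume a flattened last-visit + last-medication view of the same
instances, so comparisons isolate the value of history modelling.

## Worked example

```r
library(adaptivenet)

# a synthetic registry calibrated to published RA cohort statistics
registry  <- simulate_registry(sim_config(n_patients = 150, seed = 21))
instances <- build_instances(registry)
instances
#> Prediction instances: 499
#>   patients: 150 ( 23 yielded no instance )
#>   reference visits: 499 ; distinct target visits: 499
#>   active at target: 64.5%

fit <- adaptivenet(instances, task = "regression",
                   config = anet_config(epochs = 40, seed = 1))
fit
#> AdaptiveNet regression model
#>   encoders: visits 21->64->32, meds 18->64->32 (second layer shared)
#>   LSTM hidden: 64; head: [64 + 10 general] -> 64 -> 1
#>   parameters: 34401; trained 40 epochs (best epoch 40)

head(predict(fit, instances, type = "forecast"), 3)
#> [1] 5.067518 2.642514 3.111868
```

The forecast values are DAS28-BSR scores at the next visit (scale 0–9.4;
values ≤ 2.6 would mean predicted remission).  The full protocol — 5-fold
patient-level cross-validation of the network against all baselines, with
per-fold accuracy/sensitivity/specificity/AUC (classification) or MSE
(regression) and Welch tests across folds — runs via:

```r
cv <- cross_validate(registry, "classification", k = 5, seed = 3,
                     config = anet_config(epochs = 60))
summary(cv)                       # mean ± SD per model over folds
evaluate_subgroups(cv)            # subgroup table + pairwise Welch p-values
```

A thin command-line wrapper with `simulate`, `train-eval` and `predict`
subcommands lives at `inst/cli/adaptivenet.R`.

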