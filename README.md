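# riskstack

Bagging–stacking ensembles with hybrid resampling for imbalanced
multi-class risk prediction of food-safety inspection records.

## The problem

National sampling-inspection programmes label unqualified food samples
with a three-level hazard class — low (0), medium (1), high (2) — by the
severity of the failed item. High-risk findings (heavy metals, pathogens,
illegal additives) are rare (~5–7% of rows), so plain classifiers drift
toward the majority classes and miss exactly the samples regulators must
catch. `riskstack` is for analysts building risk-scoring models on such
tables: it packages a framework designed to recover high-risk recall
without sacrificing overall performance, together with a synthetic
record generator so every stage is testable without confidential data.

## The method

For training data $D = \{(x_i, y_i)\}$, the framework runs:

1. **B balanced bags** (default $B=5$): per bag, a stratified bootstrap
   of $D$ is balanced by SMOTE–Tomek — SMOTE interpolation
   $x_{new} = x_i + \lambda(x_j - x_i),\ \lambda \sim U(0,1)$ raises
   every class to the majority count, then Tomek links (mutual nearest
   neighbours with different labels) are cleaned.
2. **Stacking per bag**: five heterogeneous tree learners (random forest
   plus four gradient-boosted variants, implemented in-package with Rcpp)
   emit stratified 3-fold out-of-fold class probabilities; the
   $N \times 15$ meta-feature matrix trains a multinomial logistic
   meta-learner (glmnet ridge).
3. **Soft voting**: the $B$ stacked probability matrices are averaged
   into $P_{final}$.
4. **High-risk threshold**: label = high iff
   $P_{final}(\text{high}) > \tau$ (default $\tau = 0.5$); otherwise the
   argmax over {low, medium} only. The threshold is tuned on a 0.1–0.9
   sweep as the smallest value attaining the maximal high-risk F1.

Evaluation follows the standard imbalanced-multi-class toolkit:
per-class precision/recall/F1, macro-F1, weighted-F1
($w_c = n_c/N$), and one-vs-rest AUC with macro-AUC.

See `vignettes/riskstack-methods.Rmd` for the full methods account and
design decisions.

## Worked example

```r
library(riskstack)

# reference-shaped synthetic world: 792 records, class counts 279/458/55
tab  <- generate_inspection_records(generator_config(seed = 7))
sp   <- stratified_split(tab, test_fraction = 0.2, seed = 1)
fit  <- build_feature_matrix(sp$train, feature_schema(), fit = TRUE)
test <- build_feature_matrix(sp$test, fit$schema, fit = FALSE)

cfg   <- ensemble_config(base_specs = default_base_specs(seed = 11,
                                                         n_estimators = 60),
                         seed = 11)
model <- fit_bagging_stacking(fit$features, cfg)
pred  <- predict(model, test$X)

classification_report(test$y, pred$labels)
#> Classification report (N = 159 )
#>              low medium   high
#> precision 0.7358 0.7766 0.5833
#> recall    0.6964 0.7935 0.6364
#> f1        0.7156 0.7849 0.6087
#> accuracy 0.7484 | macro-F1 0.7031 | weighted-F1 0.7483

roc_auc_ovr(test$y, pred$proba)$macro_auc
#> [1] 0.8578384

curve <- threshold_metric_curve(test$y, pred$proba)
select_optimal_threshold(curve)
#> [1] 0.4
```

The test partition holds 159 rows (56 low / 92 medium / 11 high — the
largest-remainder 20% allocation). At the default threshold the ensemble
recovers 7 of the 11 high-risk rows (recall 0.64) while keeping medium
and low F1 near 0.78/0.72; the sweep selects 0.4 as the smallest
threshold attaining the maximal high-risk F1 on this split.
(`n_estimators = 60` is a compute-scaled profile; the reference setting
is 150 trees per learner.)

## Command line

```sh
./exec/riskstack simulate --n 792 --seed 7 --out records.csv
./exec/riskstack featurize --in records.csv --schema schema.json --out features.csv
./exec/riskstack fit --train records.csv --config cfg.yaml --out model.rds
./exec/riskstack predict --model model.rds --in records.csv --out preds.csv
./exec/riskstack tune-threshold --model model.rds --val records.csv \
    --grid 0.1:0.9:0.1 --out curve.csv
./exec/riskstack benchmark --config cfg.yaml --out results/
./exec/riskstack robustness --config cfg.yaml --fractions 0.1,0.2,0.4 --out results/
```

YAML config keys are documented in `?config_from_yaml`.

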