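# prombench

Choosing a classifier for a clinical screening task — say, calling a breast
mass benign or malignant from fine-needle-aspirate measurements — is rarely
settled by accuracy alone. The people who deploy the model also care about
how much training data a family needs, how sensitive it is to feature
scaling and hyper-parameter tuning, and how well it tolerates irrelevant
attributes. These criteria conflict, and an ad-hoc glance at a metrics table
hides the trade-offs.

`prombench` turns model selection into an explicit multi-criteria decision:

1. **Benchmark** five classifier families — support vector machine, random
   forest, logistic regression, k-nearest neighbour, naive Bayes — under one
   protocol: Tukey-fence outlier winsorisation, standardisation and PCA
   fitted inside each training fold, stratified 10-fold cross-validation,
   exhaustive hyper-parameter grid search.
2. **Assemble** a decision matrix mixing the six quantitative criteria
   (accuracy, recall, precision, F1, ROC-AUC, log loss) with four coded
   qualitative usability criteria.
3. **Weight** each criterion from a linguistic importance label via
   triangular fuzzy numbers: label → TFN `(l, m, u)` → Yager index
   `(l + 2m + u)/4` → normalised crisp weight.
4. **Rank** the alternatives with PROMETHEE II outranking flows.

## The method

For alternatives `a, b` and criterion `j` with weight `w_j` (Σ w_j = 1), the
pairwise deviation `d_j(a, b)` (sign-flipped for minimised criteria) is mapped
to a preference degree by a Gaussian preference function

```
P_j(d) = 0                     if d ≤ 0
P_j(d) = 1 − exp(−d²/(2s_j²))  if d > 0
```

so that near-ties generate almost no preference. The spread `s_j` defaults to
the population standard deviation of criterion `j`'s column ("auto").
Aggregation and flows follow the standard PROMETHEE II definitions:

```
π(a, b)  = Σ_j w_j · P_j(d_j(a, b))            aggregated preference index
Φ⁺(a)    = (1/(n−1)) Σ_{b≠a} π(a, b)           positive outranking flow
Φ⁻(a)    = (1/(n−1)) Σ_{b≠a} π(b, a)           negative outranking flow
Φ(a)     = Φ⁺(a) − Φ⁻(a)                        net flow, ranks alternatives
φ_j(a)   = (1/(n−1)) Σ_{b≠a} [P_j(a,b) − P_j(b,a)]   unicriterion net flow
```

The identity `Φ(a) = Σ_j w_j φ_j(a)` decomposes every net flow into
per-criterion contributions — the segments of the PROMETHEE "rainbow"
diagram — which the package computes and writes alongside each ranking.

## Worked example

Rank the published five-model, ten-criterion Wisconsin decision matrix
(shipped as plain CSV under `inst/extdata/`):

```r
library(prombench)
dm <- read_decision_matrix(
  system.file("extdata", "wisconsin_decision_matrix.csv", package = "prombench"))
flows <- compute_flows(dm)
#> Gaussian spreads: accuracy=0.5831, recall=0.8, precision=0.5831, ...
rank_complete(flows)
#>   rank         alternative phi_plus phi_minus phi_net
#> 1    1                 SVM  0.79558    0.0000  0.7956
#> 2    2                 KNN  0.27223    0.2101  0.0621
#> 3    3       Random Forest  0.07461    0.3110 -0.2364
#> 4    4         Naive Bayes  0.03850    0.3421 -0.3036
#> 5    5 Logistic Regression  0.02891    0.3465 -0.3176
```

The SVM's negative flow is exactly 0: it is best-or-tied on all ten criteria,
so no alternative exerts any preference over it, for any choice of positive
spreads — and it therefore ranks first. Its net flow decomposes into
per-criterion contributions (rainbow segments):

```r
round(flow_contributions(flows)["SVM", ], 4)
#>  accuracy  recall  precision  f1_score  roc_auc  log_loss  ...
#>    0.1024  0.0954     0.1024    0.0954   0.1070    0.1032  ...
```

A full synthetic run — generate a two-class Gaussian-mixture cohort shaped
like the Wisconsin data (569 rows, 357/212 class split, 30 features), bench
all five families, assemble the matrix and rank — is one pipeline:

```r
data    <- generate_synthetic(synthetic_config())
metrics <- bench_classifiers(data, folds = 10, seed = 42)
dm      <- assemble_decision_matrix(metrics)
rank_complete(compute_flows(dm))
```

The same steps are scriptable from a shell via the thin CLI in
`inst/exec/prombench` (`simulate`, `bench`, `rank`, `report` subcommands).

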