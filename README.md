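# consensustox

Consensus (Q)SAR toxicity modeling with Pareto-front model selection.

Regulatory screening of large chemical inventories leans on in silico
(Q)SAR models that predict binary toxicity endpoints (endocrine activity,
genotoxicity, ...). Any single model has two weaknesses: it is only
reliable inside its applicability domain (AD), and its predictive power is
limited. Combining several component models into a *consensus* model can
improve both — but which models to combine, and how to weight them, is an
empirical question. `consensustox` answers it exhaustively: it evaluates
**every** subset of a component-model panel under **six** combination
schemes, then selects the non-dominated models over coverage and
predictive power.

The package is for computational toxicologists and cheminformaticians who
already have per-chemical predictions from a panel of binary classifiers
(each reporting `active`, `inactive`, or `out_of_domain`) plus observed
labels, and want the best consensus model for screening.

## The method

For a model with confusion counts TP/FP/TN/FN over its in-domain
predictions and coverage = (in-domain chemicals)/(all chemicals):

- Sn = TP/(TP+FN), Sp = TN/(TN+FP), BA = (Sn+Sp)/2
- modified score₁ = BA × coverage
- predictivity = 0.7·BA + 0.3·(1 − |Sn − Sp|)
- **ModP** (modified predictivity) = 0.7·BA + 0.3·Sn — biased toward
  sensitivity, to minimize false negatives in hazard screening

A consensus of members with weights *w* (all 1 for majority voting; a
member's own BA / modified score₁ / predictivity / ModP for the four
statistical schemes; per-chemical inverse kNN distances in descriptor
space for the kNN scheme) predicts per chemical in two steps:

1. **AD rule** — inside the consensus AD iff Σ w(members covering the
   chemical) ≥ ½ Σ w (equality counts as inside);
2. **weighted vote** — `active` iff Σ w(active voters) > Σ w(inactive
   voters), out-of-domain members abstaining; ties resolve to `active`.

For *n* component models and *r* schemes, counting each single model once,
the number of distinct models is N = r(2ⁿ − 1) − (r − 1)n, e.g. 70 for
n = 4 and 6088 for n = 10 at r = 6. All are evaluated; the **Pareto
front** over (coverage, ModP) keeps the non-dominated ones, and the
**optimal** model is the front member closest (Euclidean, both axes as
fractions) to the ideal point (coverage 1, ModP 1). A label-shuffling
bootstrap then asks whether the front's composition — which component
models appear, and how many members the front's models use — is a tail
event (< 5%) under random assignment of the same number of front labels.

## Worked example

Using the small synthetic three-model panel shipped with the package:

```r
library(consensustox)
preds <- read_prediction_table(system.file("extdata",
  "synthetic_predictions.csv", package = "consensustox"))
labs <- read_labels(system.file("extdata",
  "synthetic_labels.csv", package = "consensustox"))

records <- annotate_pareto(evaluate_all(preds, labs))
records[records$is_pareto, c("members", "scheme", "coverage", "modp")]
#>    members scheme       coverage  modp
#>  1 mA      component       0.925 0.883
#>  2 mA;mB   majority        0.975 0.862
#>  3 mA;mB   ba              0.925 0.883
#>  ...                                      (11 front rows in total)
#>  7 mA;mC   majority        1     0.785

records[records$is_optimal, ]
#> optimal: mA [component], coverage 0.925, ModP 0.883
```

Three trade-off points emerge: the strongest single model `mA`
(ModP 0.883 at coverage 0.925), a majority pair with broader coverage at
slightly lower ModP, and a full-coverage pair at ModP 0.785. `mA` sits
closest to the ideal point, so it is flagged optimal. The bootstrap then
quantifies composition trends:

```r
bootstrap_pareto(records, n_iter = 10000, seed = 1)$report
#>   statistic observed null_mean direction exceedance significant
#> 1 mA           11.00      7.66 ge            0.0026        TRUE
#> 2 mB            5.00      7.67 le            0.0235        TRUE
#> 3 mC            5.00      7.66 le            0.0221        TRUE
#> 4 mean_size     1.91      2.09 le            0.1490        FALSE
```

`mA` appears in all 11 front models — under random front assignment that
happens 0.26% of the time, so its inclusion is statistically meaningful.

A command-line interface wraps the same pipeline
(`inst/cli/consensustox evaluate|bootstrap|simulate`), and
`generate_panel()` simulates panels with chosen sensitivity, specificity,
coverage, prevalence, and inter-model error correlation for testing.

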