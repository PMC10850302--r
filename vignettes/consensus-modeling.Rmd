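---
title: "Weighted consensus (Q)SAR models and Pareto-front selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted consensus (Q)SAR models and Pareto-front selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(consensustox)
```

## The problem

Binary (Q)SAR models for toxicity endpoints carry an applicability domain
(AD): outside the chemical space spanned by their training sets their
predictions are unreliable and are discarded. A screening programme
therefore juggles two objectives per model — *coverage* (the fraction of
the inventory inside the AD) and *predictive power* — and no single
component model maximizes both. `consensustox` combines component models
into weighted consensus models, evaluates every possible combination, and
lets a Pareto front over the two objectives expose the attainable
trade-offs.

## Metrics

With TP/FP/TN/FN tallied over in-domain predictions only:

$$Sn = \frac{TP}{TP+FN},\qquad Sp = \frac{TN}{TN+FP},\qquad
BA = \frac{Sn+Sp}{2}$$

$$\text{modified score}_1 = BA \cdot \text{coverage},\qquad
\text{predictivity} = 0.7\,BA + 0.3\,(1-|Sn-Sp|)$$

$$\text{ModP} = 0.7\,BA + 0.3\,Sn$$

ModP replaces predictivity's balance term $1-|Sn-Sp|$ with $Sn$: in a
screening tier the costly mistake is the false negative, so the metric
deliberately rewards sensitivity and accepts more false positives. The
0.7/0.3 split keeps BA dominant. Coverage is computed over *all* tested
chemicals, metrics over in-domain predictions only — a discarded
prediction is neither right nor wrong. A model whose in-domain chemicals
contain no actives (or no inactives) has an undefined Sn (Sp); the
package raises an error rather than substituting a default, because such
a value would silently corrupt every weight derived from it.

## Combination schemes

All six schemes share the same mechanics and differ only in the weight
vector:

| scheme | weight of member $m$ |
|---|---|
| majority | 1 |
| ba | $BA_m$ |
| mod_score1 | $BA_m \cdot \text{coverage}_m$ |
| predictivity | $0.7\,BA_m + 0.3\,(1-|Sn_m-Sp_m|)$ |
| modp | $0.7\,BA_m + 0.3\,Sn_m$ |
| knn | per chemical: $1/(1+\bar d_m)$, $\bar d_m$ = mean distance to the $k=12$ nearest reference chemicals of $m$ |

Statistical weights are resubstitution estimates on the training table;
no internal cross-validation is performed. Prediction is per chemical in
two steps. First the **AD rule**: the chemical is inside the consensus AD
iff the members whose ADs cover it carry at least half the total weight
(equality counts as inside — with BA weights 0.8/0.75/0.65/0.6, total
2.8, a chemical covered by the 0.8 and 0.6 members sits exactly at 1.4
and is inside, while 0.75 + 0.6 = 1.35 is outside). Second the **vote**:
active iff the summed weight of active-voting members exceeds that of
inactive-voting members (0.8 + 0.65 = 1.45 beats 0.75 + 0.6 = 1.35);
members that are out of domain for the chemical abstain entirely.

Two genuinely open choices were settled as follows:

* **Vote ties resolve to `active`** (configurable via `tie_break`). The
  method's purpose is hazard screening that minimizes false negatives, so
  the conservative call is toward activity.
* **kNN details**: the distance metric and weight transform are
  configurable (`euclidean`/`manhattan`; `1/(1+d)`, `1/d`, `e^{-d}`) with
  Euclidean and $1/(1+d)$ as defaults — the transform is bounded, equals
  1 at distance zero, and is monotone decreasing, which is all the vote
  requires. The same per-chemical kNN weights feed the AD rule, keeping
  the majority-weight AD requirement uniform across schemes. Each
  member's reference set defaults to the descriptors of its in-domain
  chemicals.

## Exhaustive enumeration

For $n$ component models and $r$ schemes, each subset of size $\ge 2$ is
evaluated once per scheme and each singleton exactly once (a single model
is the same model under every scheme):

$$N_{\mathrm{Models}} = r\,(2^n - 1) - (r-1)\,n$$

At $r = 6$ this gives 70 models for $n=4$, 161 for $n=5$, 348 for $n=6$,
1490 for $n=8$, and 6088 for $n=10$ — desk scale, so `evaluate_all()`
always enumerates fully; there is no sampling mode. Singletons carry the
sentinel scheme `"component"` in outputs. Enumeration order is
deterministic: subsets by size, then lexicographically, schemes in
declaration order.

## Pareto front and the optimal model

A record dominates another when its coverage and ModP are both at least
as high and one is strictly higher; the front is the non-dominated set.
Records sharing an identical non-dominated point are all kept — fronts
are reported by model, not by point. The **optimal** model minimizes the
Euclidean distance to the ideal point (coverage 1, ModP 1), *both axes as
fractions*: with coverage on a percent scale the coverage axis would
dominate the distance ~100-fold. Distance ties resolve to the record
with fewer members, then lexicographically — when performance is equal a
smaller consensus is cheaper to run and easier to interpret.

## Bootstrap of front composition

To judge whether the front's make-up is a chance artefact, the package
keeps the observed number of front records $k$ fixed and repeatedly
draws $k$ records uniformly without replacement from all evaluated
records, recording each component model's appearance count and the mean
member count. The null therefore reflects each model's prevalence among
all evaluated combinations. Exceedance is one-sided and inclusive ("as
extreme or more extreme"), with the side chosen by the observed
deviation from the null mean; both sides are reported for transparency,
and calls use a raw 5% threshold with no multiplicity correction. The
default is 10,000 iterations under a caller-supplied seed; runs are
bit-reproducible.

## Synthetic panels

`generate_panel()` emulates the statistical structure of a real
evaluation set: Bernoulli labels at a chosen prevalence; per model, an
independent in-AD indicator at the target coverage and in-domain
predictions correct with probability $Sn$ (actives) or $Sp$ (inactives);
and error indicators coupled across models through a shared latent
Gaussian factor, because component models trained on overlapping
chemistry do not fail independently. The latent construction preserves
each model's marginal error rates exactly while inducing positive error
correlation. Descriptors come from two Gaussian clusters (one per class,
inter-mean distance 2 at unit noise) so kNN weighting has structure to
exploit.

Defaults — chosen once as a realistic screening panel and not tuned:
2000 chemicals, prevalence 0.2 (actives are the minority class in most
toxicity endpoints), four models spanning $Sn/Sp$ 0.70–0.85 with
coverage 0.65–0.95 (one broad strong model down to one narrow weak one),
latent error correlation 0.25, descriptor dimension 8. What the
generator does **not** emulate: real descriptor distributions, AD
geometry correlated with descriptors (AD membership is independent of
the error process), class-dependent coverage, and systematic (rather
than exchangeable) inter-model disagreement. Tests passing on these
panels validate the combinatorial machinery, not the field performance
of any real model panel.

`ba_weighting_example()` is a deliberately minimal fixture whose four
models achieve balanced accuracies of exactly 0.8, 0.75, 0.65, 0.6 via
symmetric confusion counts ($Sn = Sp = BA$, full coverage) — the
least-assumption construction that realizes those weights — plus three
query chemicals that hit the AD boundary case, the outside case, and the
1.45-vs-1.35 vote.

## Numerical and degenerate-input choices

* Metrics and weights are exact floating-point expressions of integer
  counts; no tolerances enter the pipeline itself.
* The AD rule uses `>=` at exactly half the total weight.
* Empty prediction vectors, single-class label files, non-total
  prediction tables, and duplicate (chemical, model) rows are errors at
  the boundary, not silently repaired.
* `sort(partial = k)` keeps kNN distance extraction $O(n)$ per
  reference set; equal distances beyond the k-th neighbour make no
  difference to the mean of the k smallest.
* Problem sizes in the test suite (panels of 150–5000 chemicals, fronts
  of a few hundred records, 10–20k bootstrap iterations) were chosen as
  the smallest sizes at which binomial/Monte-Carlo error bounds are
  sharp enough to detect real defects.

## Known limitations

* Resubstitution weights flatter every member equally; optimistic bias
  cancels only approximately in the vote.
* The kNN scheme's reference sets default to in-domain training
  chemicals; with very low-coverage members and small $k$ the distance
  estimate is noisy.
* Fronts are two-objective by design; adding a third metric requires a
  different dominance routine.
* The bootstrap tests composition of a *given* front; it does not
  propagate uncertainty in the metrics that produced the front.
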