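---
title: "Moment-displacement classification: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Moment-displacement classification: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdem)
library(dplyr)
```

## The model

MDEM ("minimum displacement in existing moment") is a supervised classifier
for numeric tabular data built on a minimum-perturbation idea: a test point
belongs to the class whose description it disturbs least. The description of
class $c$ is the per-attribute order-$n$ population central moment vector of
its members,

$$\mu_n[k] = \frac{1}{N_c}\sum_{i \in c}(x_{i,k} - \bar x_{c,k})^n ,$$

with the mean vector itself playing that role for $n = 1$. To score a
candidate point $x$, each class temporarily absorbs it ("pseudo-inclusion"),
the Euclidean distance between the class's existing and would-be moment
vector is computed, and that raw displacement is multiplied by the class's
cardinality $N_c$. The point is assigned to the class with the smallest
weighted displacement.

The cardinality weight is essential, not cosmetic. Absorbing one point moves
a class mean by exactly $(x - \bar x)/(N_c + 1)$, so an unweighted rule would
let any sufficiently large class absorb every incoming point regardless of
fit — its moments barely move no matter what joins it. Multiplying by $N_c$
cancels that $1/(N_c+1)$ shrinkage to first order and makes displacements
comparable across classes of different sizes.

Four orders are exposed (`order = 1..4`), corresponding to mean, variance,
unnormalised skewness and unnormalised kurtosis. Which order classifies best
is a property of the data: classes separated in location favour order 1,
classes sharing a centre but differing in spread favour order 2, and so on.
The regime tests in the suite construct exactly these situations with the
synthetic generator and confirm that the matching order wins.

## Sufficient statistics and complexity

Each class keeps only its count and the raw powered sums
$S_l[k] = \sum_i x_{i,k}^l$ for $l = 1..L_{\max}$. All central moments derive
from these via the binomial expansion
$\mu_n = \sum_{j=0}^{n} \binom{n}{j} \mu'_{n-j} (-\mu'_1)^j$ with
$\mu'_l = S_l/N$. Consequences:

* **Training is one pass.** Fitting accumulates powered sums row by row —
  $O(P)$ in the number of training rows, with constants proportional to
  $L_{\max} \times$ attribute count.
* **Prediction is constant-time in the training size.** Scoring touches only
  the per-class statistics, never the stored points, so the cost per
  prediction depends on the number of classes, attributes and $L_{\max}$, not
  on how many points have been absorbed. The suite asserts both contracts
  with timing ratios at a 10× size gap, using medians of repeated runs at
  sizes (2 000 vs 20 000 rows) chosen so each measurement is comfortably
  above clock resolution.
* **Moments divide by $N$, not $N-1$.** The classifier compares moments of
  concrete finite point sets, not unbiased estimates of a parent population;
  the five-point worked example (third central moment $293.76/5 = 58.752$)
  pins this convention down.

A closed-form single-point update is also provided
(`updated_central_moment()`): with $\delta = x - \bar x_N$ and
$h = \delta/(N+1)$,

$$\mu_n(N+1) = \frac{1}{N+1}\Big[\sum_{j=0}^{n}\binom{n}{j} N \mu_{n-j}(N)
(-h)^j + \Big(\frac{\delta N}{N+1}\Big)^{n}\Big],$$

using the conventions $\mu_0 = 1$, $\mu_1 = 0$ (both forced by the identity
$\sum_i (x_i - \bar x_N)^{n-j} = N\mu_{n-j}(N)$ at $j = n$ and $j = n-1$).
One derivation subtlety deserves a flag: it is tempting to factor
$N/(N+1)$ out of the whole bracket after rewriting the last term, but that
regrouping multiplies the new point's own deviation term by an extra
$N/(N+1)$ and is algebraically wrong — the worked update
$\{5,10,15,8,20\} \cup \{17.6\}$ at $n=2$ gives $171.2/6$ under the formula
above and fails under the regrouped one. The implementation follows the
formula above and the tests verify it against two-pass recomputation at
$10^{-9}$ tolerance.

## Numerical behaviour

Deriving central moments from raw powered sums cancels catastrophically when
attribute magnitudes are large (the terms of the binomial expansion grow like
$\text{magnitude}^n$ while the result stays small). The pipeline therefore
normalises attributes to $[0,1]$ before fitting — which the preprocessing
stage does anyway — and on such data the powered-sum route agrees with
two-pass computation to well below $10^{-9}$ absolute. On raw clinical-scale
data only about $10^{-6}$ relative accuracy should be expected; this is a
documented contract, not a target the implementation tunes for.

Other numerical conventions:

* **Tie-breaking.** The argmin over weighted displacements takes the
  earliest class in declaration order. This matters for fully degenerate
  cases (for example, every class a singleton at order ≥ 2, where every
  existing moment is zero); such cases are legal, deterministic and tested,
  not errors.
* **Evolution.** By default each prediction commits the point to its winning
  class before the next row is scored, so batch predictions can depend on row
  order; that is the model's online-learning contract and is stated on
  `predict.mdem()`. `evolve = FALSE` gives a frozen, permutation-invariant
  model. States are immutable values (absorbing returns a new state), so
  pseudo-inclusion needs no rollback and "commit" is just replacing the
  stored state.
* **Cardinality weight.** The weight is the class's *current* count; a
  `count_plus_1` switch is offered because the mean-shift formula scales as
  $1/(N+1)$, but the default matches the canonical testing loop.
* **Margin.** `mdem_margin()` reports the gap between the two smallest
  weighted displacements. An estimation error smaller than half this margin
  can never flip the decision, which makes it a useful per-point confidence
  diagnostic. Only the empirical margin is computed; no population analogue
  is estimated.

## Preprocessing pipeline

`preprocess()` applies three steps in a fixed order — impute, filter, scale:

1. **Mean imputation.** `NA` is always missing; a per-column sentinel
   (typically a coded 0 for physiologically impossible zeros such as a zero
   insulin level) can be declared via `sentinels`. Declaring zero-as-missing
   is opt-in per column because a zero is a legitimate value in many columns
   (pregnancy counts, for instance).
2. **IQR row filtering.** Per attribute, cells outside
   $[Q_1 - f\,\mathrm{IQR},\; Q_3 + f\,\mathrm{IQR}]$ are flagged, with
   separate outlier ($f = 3$) and extreme ($f = 6$) factors — the
   conventional defaults of this filter family; any flagged cell removes the
   row, and the report tallies rows by their worst flag. Quartiles use linear
   interpolation between order statistics (`stats::quantile` type 7,
   configurable). Other tools' quartile rules differ, so row counts from
   other software need not reproduce exactly.
3. **Min-max scaling** to $[0,1]$, constant columns mapping to 0. The
   observed ranges are recorded for reuse on new data.

Scaling parameters are computed on the full table before any
cross-validation split. This mirrors the common whole-dataset filtering
workflow and leaks only the per-attribute range across folds; a strict
per-fold mode is available by passing recorded `params` to `minmax_scale()`
inside a custom classifier spec.

## Cross-validation and metrics

`kfold_assign()` permutes rows once (seeded) and cuts near-equal folds;
`stratified_kfold_assign()` shuffles within class and deals round-robin, so
per-fold class counts match the global proportions to within one row.
`cross_validate()` fits a fresh model per fold — class states never leak
across folds, the standard CV semantic — and predicts the held-out fold with
the model's evolve setting.

Aggregation follows the shape of the usual comparison tables: accuracy is
the mean of per-fold accuracies (one number per algorithm and $k$), while
precision, recall, F1 and MCC are computed on the confusion matrix pooled
over folds, which is stabler than averaging ratios over small folds; per-fold
values are also kept. The positive class defaults to the minority label,
which is the clinically interesting one in imbalanced diagnostic data.
Zero-denominator metrics report 0 with a named flag rather than `NaN`.

Baselines for the `accuracy_grid()` comparison table plug in through the
`classifier_spec` adapter interface, wrapping established implementations
(`stats::glm`, randomForest, e1071, class); none is re-implemented here.

## The synthetic generator

`synth_tabular()` draws each class/attribute cell from a sinh-arcsinh
transformed Gaussian, $S = \sinh((\operatorname{asinh}(Z) + \epsilon)/\tau)$,
which gives independent handles on skewness ($\epsilon$) and tail weight
($\tau$). The transformed variate is standardised by its population mean and
standard deviation — computed deterministically by numerical quadrature —
before location and scale are applied, so two classes can share mean and
variance *exactly* while differing only in skew. That property is what makes
the regime experiments clean: any accuracy difference between moment orders
is attributable to the moment that actually differs. Default experiment
sizes (150 rows per class, 5 seeds, 5-fold CV) were chosen as typical of
small clinical tables while keeping sampling noise well below the effect
sizes being demonstrated.

Missing-value sentinels and gross outliers are injected cellwise/rowwise at
declared rates to emulate coded clinical data. The generator emulates
class-conditional moment structure with independent attributes; it does not
emulate attribute correlation, label noise, or the exact marginals of any
real benchmark. Passing tests on generated data therefore demonstrate
correctness of the machinery and the moment-regime behaviour, not expected
accuracy on any particular real dataset.

The brute-force oracles (`oracle_moments()`, `oracle_displacements()`)
re-materialise full point sets and recompute everything two-pass. They are
deliberately naive and share no code with the incremental route; the suite
drives both over randomized corpora and requires agreement to $10^{-9}$.

One property needed care to state honestly: the magnitude of the
central-moment displacement decays like $1/N$ only once the new point's own
deviation term dominates. Near the cancellation point (for variance, when
$\delta^2 \approx \mu_2$) the signed displacement crosses zero and its
absolute value is briefly non-monotone in $N$. The decay test therefore
fixes $\delta$ at half the attribute range, well inside the dominated
regime, and uses a quantile-grid base sample so the distributional shape is
identical at every $N$.

## Known limitations

* Binary metrics only (a declared positive class); classification itself is
  natively multiclass, but macro/micro-averaged multiclass metrics, ROC/AUC
  and significance tests between algorithms are out of scope.
* No downdating (point removal), point weights, or merging of two states.
* No probability outputs; the margin is the only confidence diagnostic.
* Scoring compares a single moment order at a time, not a concatenation
  across orders — a plausible extension, deliberately not included.
* Exact reproduction of preprocessing row counts or accuracy cells from
  other software depends on their quartile rules and unpublished fold
  shuffles and is not attempted; with a real clinical CSV/ARFF file supplied
  the pipeline runs end-to-end and reports its own grid.
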