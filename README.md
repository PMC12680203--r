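# mdem

Minimum-displacement-in-existing-moment (MDEM) classification for numeric
tabular data — typically clinical tables of the "samples × measurements +
diagnosis" shape, for analysts who want a lightweight, deterministic,
hyperparameter-free alternative to distance- or optimisation-based
classifiers.

## The idea

Each class is summarised by the per-attribute order-*n* population central
moment vector of its members (the mean itself for *n* = 1):

    mu_n[k] = (1/N_c) * sum_i (x_{i,k} - xbar_{c,k})^n

A test point is *pseudo-included* in every class, the Euclidean distance
between the class's existing and would-be moment vector is computed, and the
point goes to the class whose **cardinality-weighted** displacement

    D_c(x) = N_c * || mu_n^{+x} - mu_n ||

is smallest. The weight matters: one inclusion shifts a class mean by exactly
`(x - xbar) / (N_c + 1)`, so without it a big class would swallow every
point. After a prediction the winning class (optionally) absorbs the point —
the model keeps evolving during testing.

Classes are stored as raw powered sums `S_l[k] = sum_i x_{i,k}^l`, so
training is a single O(P) pass over the rows and every prediction costs the
same regardless of how much has been absorbed. Orders 1–4 correspond to
mean, variance, and unnormalised skewness/kurtosis.

Around the classifier the package provides the matching preprocessing
pipeline (mean imputation with per-column missing sentinels, IQR
outlier/extreme row filtering, min-max scaling to [0,1]), k-fold and
stratified k-fold cross-validation with confusion-matrix metrics (accuracy,
precision, recall, F1, MCC), a synthetic generator with independently
controllable per-class mean/variance/skew/tails, CSV and ARFF readers, JSON
model serialization, and a small CLI (`inst/cli/mdem.R`).

## Worked example

The classic five-point class — values 5, 10, 15, 8, 20:

```r
library(mdem)

fit <- mdem(worked_example(), class = "class", order = 3)
tidy(fit)
#> # A tibble: 1 × 5
#>   class attribute count  mean central_moment
#>   <chr> <chr>     <int> <dbl>          <dbl>
#> 1 c2    x             5  11.6           58.8
```

The mean is 11.6 and the population third central moment is
293.76/5 = **58.752**. The closed-form single-point update agrees with full
recomputation — adding 17.6 and asking for the new variance:

```r
st <- fit$states[["c2"]]
updated_central_moment(st, 17.6, 2)
#> [1] 28.53333        # = 171.2 / 6, recomputed over all six points
```

Scoring a point against two classes, A = {0.0, 0.2} and B = {0.9}:

```r
d <- tibble::tibble(x = c(0, 0.2, 0.9), class = c("A", "A", "B"))
m <- mdem(d, order = 1)
mdem_displacement(m, 0.5)
#> # A tibble: 2 × 5
#>   class count   raw weighted chosen
#>   <chr> <int> <dbl>    <dbl> <lgl>
#> 1 A         2 0.133    0.267 FALSE
#> 2 B         1 0.2      0.2   TRUE
```

A's mean moves less (0.133 vs 0.2) but after weighting by class size B wins
— the small class is allowed to claim the point. The decision margin is
0.267 − 0.2 ≈ 0.067 (`mdem_margin(m, 0.5)`).

A full evaluation run on synthetic data:

```r
spec <- generator_spec(n = c(a = 150, b = 150), location = c(0.5, 0.5),
                       scale = c(0.05, 0.2))   # same mean, different spread
d <- synth_tabular(spec, seed = 1)
cross_validate(d, mdem_spec(order = 2), k = 5, seed = 1)
#> MDEM (order 2) — 5-fold CV (seed 1, positive class 'a')
#>   mean accuracy: 0.7133 | pooled precision 0.636, recall 1.000, F1 0.777, MCC 0.521
```

On this variance-separated regime order 2 scores ~0.71 while order 1 sits
below chance (0.46) — the moment that actually differs between classes is
the one that classifies.

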