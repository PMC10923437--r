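# feedbackMR

Estimation of **bidirectional causal effects** between two continuous
phenotypes from one-sample individual-level data, using Mendelian
randomization (MR) with genetic instruments.

When two traits each causally affect the other — obesity and fasting
glucose, inflammation and sleep, depression and pain — the mutual causation
creates a feedback loop. The standard practice of running a unidirectional
MR estimator twice, once per direction, ignores that loop and biases both
estimates. feedbackMR implements feedback-aware estimators alongside their
naive counterparts, plus the simulation machinery to quantify the
difference.

## The model and estimators

The structural system for traits $Y_1, Y_2$ with per-trait instrument sets
$X_1, X_2$ and unmeasured confounder $C$ is

$$Y_1 = \beta_{01} + \beta_{11} X_1 + \beta_{CY1} C + \gamma_{21} Y_2 + \varepsilon_1,
\qquad
Y_2 = \beta_{02} + \beta_{22} X_2 + \beta_{CY2} C + \gamma_{12} Y_1 + \varepsilon_2 .$$

When $|\gamma_{12}\gamma_{21}| < 1$ the feedback loop converges to a reduced
form in which each trait loads on *both* instrument sets and every
coefficient carries the factor $1/(1-\gamma_{12}\gamma_{21})$. The package
provides four estimators of the directed effects $(\gamma_{12}, \gamma_{21})$:

| method | idea | feedback-aware |
|---|---|---|
| `ratio` | per-instrument ratio of marginal regression coefficients, IVW-combined | no |
| `biratio` | same, but every regression adjusts for the opposite instrument set, so the feedback factor cancels in the ratio | yes |
| `liml` | k-class/LIML per direction, opposite instruments omitted | no |
| `biliml` | k-class/LIML with the opposite instruments as included exogenous columns; $\hat k$ = smallest eigenvalue of the projected cross-product matrix | yes |

`biliml` is the default: it inherits LIML's robustness to many weak
instruments (first-stage F below 10).

## Worked example

Simulate a cohort with a strong bidirectional relationship
($\gamma_{12} = -1.9$, $\gamma_{21} = 0.5$, 20 strong instruments per
trait, n = 1000) and estimate both directions:

```r
library(feedbackMR)

p <- bmr_params(gamma12 = -1.9, gamma21 = 0.5, beta11 = 2, beta22 = 2,
                k1 = 20, k2 = 20, n = 1000)
dat <- simulate_bmr(p, seed = 1)

summary(bimr(dat, method = "biliml"))
#> Bidirectional causal effect estimates (n = 1000)
#>
#>  Direction Method          Estimation (95% CI)   P-value Mean F Variance explained
#>       1->2 biliml -1.9123 (-1.9345 to -1.8901) 2.23e-308  39.78             76.14%
#>       2->1 biliml    0.5148 (0.4934 to 0.5363) 3.44e-254  13.91             25.79%

summary(bimr(dat, method = "ratio"))   # the naive comparator on the same cohort
#> Bidirectional causal effect estimates (n = 1000)
#>
#>  Direction Method          Estimation (95% CI)   P-value Mean F Variance explained
#>       1->2  ratio -2.0154 (-2.1539 to -1.8769) 6.22e-179  39.78             76.14%
#>       2->1  ratio    0.3759 (0.3167 to 0.4351)  1.47e-35  13.91             25.79%
```

On this single cohort the feedback-aware fit recovers the truth in both
directions while the naive ratio drifts (0.38 vs the true 0.50): the
reverse effect leaks through the feedback loop. `Mean F` is the achieved mean first-stage
F-statistic of the direction's instrument set; `Variance explained` is the
exposure variance explained by its instruments beyond any covariates.

Benchmarks over many replicates (here 50 for speed; the study design uses
1000) aggregate the accuracy metrics — median estimate, median absolute
bias (MAB) and relative MAB:

```r
run_benchmark(p, "bmr", n_reps = 50, base_seed = 7)
#> True effects              F-stat  ratio:med    MAB   RMAB  biratio:med    MAB   RMAB  liml:med    MAB   RMAB  biliml:med    MAB   RMAB
#> gamma12 = -1.9             41.22     -1.89   0.04     2%     -1.90   0.01     0%     -1.91   0.04     2%     -1.90   0.01     0%
#> gamma21 = 0.5              11.38      0.44   0.06    13%      0.50   0.01     2%      0.50   0.04     9%      0.50   0.01     2%
```

The naive medians reproduce the characteristic opposite-sign bias pattern
(0.44 vs 0.50 for the reverse direction) while the feedback-aware medians
sit on the truth.

Cohorts can also be written/read as tab-delimited tables
(`write_cohort()` / `read_cohort()`), dosages extracted from VCF
(`read_vcf_dosages()`), and everything driven from the shell via the thin
CLI at `inst/scripts/feedbackmr` (`simulate`, `estimate`, `benchmark`
subcommands).

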