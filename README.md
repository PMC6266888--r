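# extmarkov

Estimation of nutrient and chlorophyll-a **reference conditions** — the
concentration levels least impacted by human activity — from monthly
water-quality monitoring series, for lake and water-resource scientists
who need defensible low-quantile baselines with honest uncertainty.

Monthly series of total nitrogen (TN), total phosphorus (TP) and
chlorophyll a are strongly serially dependent: low months cluster after
low months.  Classical extreme-value estimators (annual blocks,
declustered peaks-over-threshold) discard most of the record to buy
independence, which widens the confidence interval of the estimated
quantile.  `extmarkov` instead models the dependence.

## The model

Minima are turned into maxima by negation, $y_t = -x_t$.  Exceedances of
a fixed threshold $u$ follow a generalized Pareto distribution

$$H(y) = 1 - \left[1 + \xi\,(y-u)/\sigma\right]^{-1/\xi}, \qquad y > u,$$

with exceedance rate $\lambda_u$ estimated empirically.  Each value is
mapped to the standard Fréchet scale through $z = -1/\log F(y)$, and
consecutive months are coupled by the bivariate logistic extreme-value
law

$$F(z_t, z_{t-1}) = \exp\!\left\{-\bigl(z_t^{-1/\alpha} +
z_{t-1}^{-1/\alpha}\bigr)^{\alpha}\right\},$$

where $\alpha = 1$ is independence and small $\alpha$ strong dependence
(tail-dependence coefficient $\chi = 2 - 2^{\alpha}$).  Under the
first-order Markov assumption the full record enters a **censored
likelihood**: exact densities above the threshold, probability mass
below, pairwise terms coupling adjacent months.  The level-$p$ reference
condition (conventionally $p = 0.25$) is

$$v = -\left[u + \tfrac{\sigma}{\xi}\left(p^{-\xi} - 1\right)\right],$$

with a parametric-bootstrap confidence interval that resimulates whole
dependent chains from the fitted model.  An independent
peaks-over-threshold (POT) baseline, mean-residual-life threshold
diagnostics, ACF screening and PP/QQ/return-level arrays, and a
simulator with known ground truth round out the toolkit.

## Worked example

Fit a synthetic 8-site × 144-month TN-like record generated with known
truth ($\sigma = 0.23$, $\xi = -0.27$, $\alpha = 0.78$, $u = -1$ mg/L on
the negated scale):

```r
library(extmarkov)
fx  <- make_fixture("TN", seed = 1)          # dataset + generating truth
fit <- fit_markov(fx$dataset, u = -1.0)
fit
#> Extreme-Markov fit: 148 effective observations (of 1152 ) above u = -1
#>   sigma = 0.2658 (se 0.0326)
#>   xi    = -0.2873 (se 0.0781)
#>   alpha = 0.7403 (se 0.0366)
#>   log-likelihood: -287.7734   lambda_u: 0.1284722

bootstrap_ci(fit, fx$dataset, p = 0.25, n_boot = 1000, seed = 1)
#> 25% quantile reference condition: 0.6961  [0.6397, 0.7454] (95% CI)
#>   parametric bootstrap, 1000 replicates (0 failed), seed 1
```

Reading the output: all three generating parameters are recovered within
about one standard error; $\hat\alpha = 0.74 < 1$ says consecutive
months are significantly dependent, so the 148 clustered exceedances
could all be used instead of being declustered away.  The estimated
reference condition is 0.70 mg/L TN with 95% interval 0.64–0.75 mg/L —
the quantity a nutrient-criteria analyst would report as the baseline.

The same pipeline runs from the shell against a CSV with columns
`site,date,variable,value`:

```sh
exec/extmarkov fit --input obs.csv --variable TN --threshold -1.0 \
    --quantile 0.25 --bootstrap-reps 1000 --seed 1 --out report.json
exec/extmarkov compare --reports report_pot.json,report_em.json \
    --external GEV=0.58:0.84 --out comparison.csv
```

Subcommands: `fit`, `simulate`, `diagnose`, `compare`; `--help` on each.

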