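# mtpsens

Sensitivity analysis for multiple testing procedures (MTPs) under
arbitrary dependence between p-values.

## The problem

Given `m` marginal p-values with unknown joint dependence, several valid
procedures compete: Bonferroni, weighted Bonferroni, Holm and Šidák
control the family-wise error rate (FWER); Benjamini–Yekutieli (BY)
controls the false discovery rate (FDR) under arbitrary dependence; and
Benjamini–Hochberg (BH) is the empirically robust FDR workhorse. They can
disagree by a wide margin about how many of the smallest p-values are
significant, and picking one of them hides that uncertainty.

`mtpsens` makes the procedure itself random. Any probability measure
`ν` on the integer rank bins generates an FDR-valid step-up procedure via
its shape function

    β_ν(r) = Σ_{j≤r} j ν_j,      Δ_{α,ν}(r) = α β_ν(r) / m,
    R = max{ r : p_(r) ≤ Δ_{α,ν}(r) },   p_(0) ≡ 0,

which controls FDR ≤ α under arbitrary dependence for *every* ν. Placing
a Dirichlet process prior `ν ~ DP(M ν0)` — baseline `ν0` the BY measure
with masses `1/(r·H_m)`, precision `M ~ Exponential(1)` by default —
induces a prior predictive distribution over the whole space of such
procedures, hence over the discovery count `R`, and gives every
hypothesis a prior predictive probability of significance: the fraction of
procedure draws that reject it.

The package also provides the six classical benchmark procedures, a Gibbs
sampler (with quadrature oracle) for the posterior of the DP precision
parameter `M` given the number of distinct values, a generator of
equicorrelated p-value families with known ground truth, and Monte-Carlo
FDR/FWER/power estimation.

## Worked example

```r
library(mtpsens)

# 500 tests, 80% true nulls, shifted alternatives, strong equicorrelation
fam <- simulate_pvalues(m = 500, pi0 = 0.8, effect = 3, rho = 0.5, seed = 42)

for (meth in c("bonferroni", "holm", "sidak", "by", "bh"))
  print(mtp(fam, meth, alpha = 0.05))
#> Bonferroni procedure at alpha = 0.05: 2 of 500 hypotheses rejected
#> Holm procedure at alpha = 0.05: 2 of 500 hypotheses rejected
#> Sidak procedure at alpha = 0.05: 2 of 500 hypotheses rejected
#> BY procedure at alpha = 0.05: 0 of 500 hypotheses rejected
#> BH procedure at alpha = 0.05: 13 of 500 hypotheses rejected

fit <- dpmtp(fam, alpha = 0.05, n_draws = 1000, seed = 42)
summary(fit)
#> DP-MTP prior predictive distribution of the discovery count
#>   m = 500 , alpha = 0.05 , 1000 draws, mass: Exponential(1)
#>   mean R = 1.4, sd = 2.5
#>   quantiles (0/25/50/75/100%):  0  0  0  2 13
#>   hypotheses significant in every draw: 0
#>   hypotheses significant in at least one draw: 13

df <- as.data.frame(fit)
head(df[order(df$rank), ], 5)
#>            p rank sig_prob
#> 36  3.68e-05    1    0.385
#> 264 6.94e-05    2    0.325
#> 326 1.91e-04    3    0.162
#> 491 2.98e-04    4    0.113
#> 120 3.67e-04    5    0.095
```

The fixed procedures span 0 (BY) to 13 (BH) discoveries on the same
family. The DP-MTP turns that spread into a distribution: across 1,000
random FDR-valid procedures the discovery count averages 1.4 (sd 2.5,
range 0–13), and the per-hypothesis table shows how quickly the
probability of significance decays with the p-value — the smallest
p-value is rejected by 38.5% of the sampled procedures, the fifth smallest
by 9.5%. Probabilities are exactly zero for p-values above `alpha`.

Posterior inference for the DP precision parameter:

```r
post <- sample_m_posterior(k = 500, m = 500, seed = 42)
post
#> posterior of the DP precision M | k = 500 distinct of m = 500
#>   Gamma(1, 1) prior; 10000 burn-in + 10000 retained Gibbs draws
#>   mean 233.25, sd 12.53, median 233.10
```

A command-line interface with subcommands `generate`, `classic`, `dpmtp`,
`mcmc-m` and `simulate` is installed at
`system.file("cli", "mtpsens.R", package = "mtpsens")`; every run writes a
JSON parameter echo sufficient to reproduce it.

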