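---
title: "Dirichlet process sensitivity analysis of multiple testing procedures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dirichlet process sensitivity analysis of multiple testing procedures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtpsens)
```

## The problem

Large-scale studies routinely test thousands of null hypotheses and reduce
each test to a marginal p-value. Because the joint dependence between the
p-values is typically unknown, the analyst must use a multiple testing
procedure (MTP) that is valid under *arbitrary* dependence. Several such
procedures exist — Bonferroni, weighted Bonferroni, Holm and Šidák control
the family-wise error rate (FWER), Benjamini–Yekutieli (BY) controls the
false discovery rate (FDR) — and the widely used Benjamini–Hochberg (BH)
step-up is known to be empirically robust to common dependence patterns.
These procedures can disagree substantially about how many of the smallest
p-values to declare significant, and committing to a single one of them
ignores that source of uncertainty entirely.

`mtpsens` treats the choice of FDR-valid step-up procedure itself as
uncertain. It places a Dirichlet process (DP) prior on the object that
generates such procedures and propagates that prior to a *distribution* of
discovery counts and, for each hypothesis, a prior predictive probability
of being declared significant.

## Step-up procedures and shape functions

Let $p_{(1)} \le \dots \le p_{(m)}$ be the ordered p-values. A step-up
procedure with non-decreasing thresholds $\Delta(r)$ rejects the hypotheses
carrying the $R$ smallest p-values, where

$$R = \max\{\, r \in \{0,\dots,m\} : p_{(r)} \le \Delta(r) \,\},
\qquad p_{(0)} \equiv 0 .$$

For any probability measure $\nu$ on $(0, m]$, discretised here on the
integer bins $(r-1, r]$ with masses $\nu_r$, define the shape function

$$\beta_\nu(r) = \sum_{j \le r} j\,\nu_j .$$

The step-up procedure with thresholds
$\Delta_{\alpha,\nu}(r) = \alpha\,\beta_\nu(r)/m$ controls the FDR at level
$\alpha\pi_0 \le \alpha$ under arbitrary dependence between the p-values,
for *every* choice of $\nu$. Two familiar cases: a measure with linear
shape $\beta(r) = r$ gives the BH thresholds $\alpha r / m$ (valid only
under independence or positive regression dependence), while the measure
with masses $\nu_r = 1/(r H_m)$ — $H_m$ the $m$-th harmonic number — has
shape $\beta(r) = r/H_m$ and reproduces the BY thresholds exactly
(`by_baseline_measure()`, `shape_function()`, `schedule_from_shape()`).

## The DP prior over procedures

A Dirichlet process prior $\nu \sim \mathrm{DP}(M \nu_0)$ makes the measure
$\nu$, hence the shape function, the thresholds and the discovery count
$R_{\alpha,\nu}$, random. Over the integer bins its finite-dimensional
marginal is the Dirichlet distribution

$$(\nu_1, \dots, \nu_m) \sim \mathrm{Dirichlet}_m(M\nu_0(B_1), \dots,
M\nu_0(B_m)),$$

with expectation $\nu_0$ and variance $\nu_0(1 - \nu_0)/(M + 1)$ per bin.
`dpmtp()` samples `n_draws` realisations of $\nu$, computes the step-up
count $R$ for each, and reports

* the prior predictive distribution of $R$ (mean, sd, quantiles,
  histogram), and
* for each hypothesis, the proportion of draws in which its rank was
  rejected — its *prior predictive probability of significance*. Because
  the events $\{r \le R\}$ are nested, that probability is non-increasing
  in the p-value rank, and because every realised threshold is at most
  $\alpha$, it is exactly zero for p-values above $\alpha$.

### Parameters and defaults

* **`alpha`** (default 0.05): the FDR/FWER level every supported procedure
  controls. Unitless, in $(0,1)$.
* **`baseline`** (default `by_baseline_measure(m)`): the DP centre
  $\nu_0$. The BY measure is the natural default because it is the unique
  choice whose prior-expected procedure is itself valid under arbitrary
  dependence; users may supply any `binned_measure`.
* **`mass`** (default `"exponential"`): the DP precision $M$. Small $M$
  means large prior variance around $\nu_0$, i.e. a wide spread of
  procedures; large $M$ collapses the analysis onto BY. The default is a
  standard Exponential(1) hyperprior, re-drawn *for every* $\nu$ draw, which
  mostly supports small $M$ while still covering a wide range of expected
  cluster counts. A fixed positive number may be given instead. The
  expected number of clusters $\sum_{i=1}^m M/(M+i-1)$
  (`expected_clusters()`) is the standard elicitation device for a fixed
  $M$; at $M = 1$ it equals $H_m$.
* **`n_draws`** (default 1000): Monte-Carlo draws of $\nu$. The Monte-Carlo
  standard error of the reported mean of $R$ is
  $\mathrm{sd}(R)/\sqrt{\texttt{n\_draws}}$.

## Inference for the precision parameter

As a complement, `sample_m_posterior()` estimates the posterior of $M$
given the number $k$ of distinct values among $m$ draws, with density
proportional to $\pi(M)\,M^{k-1}(M+m)\,B(M+1,m)$ under a
$\mathrm{Gamma}(a,b)$ prior (default $a=b=1$, the Exponential(1) prior).
The sampler is the classical two-step augmentation: draw
$\eta \mid M \sim \mathrm{Beta}(M+1, m)$, then draw $M \mid \eta$ from a
two-component gamma mixture — $\mathrm{Gamma}(a+k,\, b-\log\eta)$ versus
$\mathrm{Gamma}(a+k-1,\, b-\log\eta)$ with odds
$(a+k-1)/\{m(b-\log\eta)\}$ on the first component.
`m_posterior_moments()` evaluates the same density by deterministic
quadrature and is the oracle against which the sampler is tested. With a
continuous family of p-values $k = m$, the posterior of $M$ concentrates
on large values, and the DP collapses toward its BY baseline — one reason
the package, like the method it implements, emphasises *prior predictive*
inference over posterior inference on $M$.

```{r precision-example}
fit <- sample_m_posterior(k = 50, m = 50, n_burn = 1000, n_keep = 4000,
                          seed = 1)
fit
m_posterior_moments(50, 50)[c("mean", "sd", "median")]
```

## The synthetic p-value generator

`simulate_pvalues(m, pi0, effect, rho, seed)` builds families with known
ground truth for calibration studies. Latent standard-normal statistics
receive exchangeable equicorrelation `rho` through a single shared factor,
$X_i = \sqrt{\rho}\,Z_0 + \sqrt{1-\rho}\,Z_i$; each hypothesis is a true
null with probability `pi0`; null p-values are the upper-tail probability
of the latent normal (exactly uniform marginally — the calibrated boundary
of the super-uniformity condition every supported procedure requires),
and alternatives shift the latent statistic by `effect` standard
deviations, giving stochastically smaller p-values.

The generator emulates the two features that matter for the guarantees
under test — marginally (super-)uniform nulls and positive exchangeable
dependence of tunable strength. It does *not* emulate negative or
block-structured dependence, heavy-tailed test statistics, discrete
(strictly super-uniform) p-values, or composite nulls. Tests passing on
these families therefore demonstrate correctness of the procedures and
their stated error control under exchangeable positive dependence; they do
not certify behaviour under adversarial dependence, where only the
procedures' analytical guarantees apply. The Gaussian one-factor shift
alternative is a package choice; no particular alternative family is
canonical for this purpose.

Error-rate calibration itself is done by `estimate_fdr()`,
`estimate_fwer()` and `mtp_error_study()`, which split replicate seeds
deterministically from a master seed so that competing procedures are
always compared on identical families.

## Numerical choices

* **Dirichlet draws with tiny concentrations.** With the BY baseline and
  $M \sim \mathrm{Exp}(1)$, bin concentrations $M\nu_{0r}$ are far below 1
  for large $r$; draws use the gamma representation (independent
  $\mathrm{Gamma}(M\nu_{0r}, 1)$ normalised by their sum). Individual
  components underflowing to exact zero is expected and harmless; only if
  the *sum* underflows is the draw retried, up to 100 times, after which an
  error advises a larger mass.
* **Ties.** Sorting is stable (ties broken by original position), and
  rejection is rank-based, so tied p-values straddling a rejection boundary
  may split; the count $R$ is unaffected by tie order.
* **Harmonic numbers** are computed by direct summation in double
  precision, exact to rounding at any realistic $m$.
* **$\int_0^1 z^M (1-z)^{m-1}\,dz$** is recognised as $B(M+1, m)$ and
  evaluated through `lbeta()` in log space; no numeric integration occurs
  inside the posterior density.
* **Gibbs auxiliary variable** $\eta$ is clamped to
  $[\epsilon, 1-\epsilon]$ at machine precision so $\log\eta$ stays finite;
  the chain is initialised at the prior mean $M_0 = 1$, with 10,000 burn-in
  and 10,000 retained iterations as defaults.
* **Quadrature** for the $M$ posterior locates the mode by 1-d optimisation
  on the log scale, sizes the grid from the Laplace curvature
  ($\pm 12$ sd, 4001 points by default), and normalises by the trapezoid
  rule; a grid-refinement test checks self-consistency to 0.1%.
* **Bonferroni, weighted Bonferroni and Šidák** are implemented as
  single-step per-hypothesis comparisons (the union-bound logic), not via
  the step-up engine; for constant thresholds the counts coincide.
* **$\pi_0$ is fixed at 1** throughout: adaptive estimators of the
  true-null proportion are unreliable under arbitrary dependence and are
  deliberately excluded. Adjusted p-values are likewise not computed; the
  package reports thresholds and decisions.

## Design choices that were genuinely open

* The hyperprior scheme re-samples $M$ jointly with each $\nu$ draw (one
  $M$, one $\nu$, one $R$ per Monte-Carlo iteration); this is the natural
  single-pass Monte-Carlo integration of the prior predictive over the
  hyperprior.
* The per-hypothesis significance probability is defined through the rank
  indicator $1(r \le R)$, matching the nested step-up geometry, rather
  than through per-hypothesis threshold comparisons.
* Reported numbers in the textual statements of the expected-cluster
  identity read $M = m^{-1}$ for "about one cluster" and $M = m^2$ for
  "about $m$ clusters"; these are the readings consistent with the
  closed-form sum and its logarithmic bounds.
* The `dp_mtp_decision()` single-draw rule exists so that the DP-MTP can
  be placed inside the same Monte-Carlo error-rate harness as the fixed
  procedures, one random procedure per simulated family.

## Problem sizes used by the test suite

The suite exercises exhaustive engine checks at $m \le 12$ against
brute-force enumeration; distributional checks on 1,000–2,000 simulated
families of $m = 50$–$100$; Dirichlet marginal checks with 5,000 draws;
Gibbs-versus-quadrature agreement at $(k,m) \in
\{(10,10), (50,50), (30,100)\}$ and a full-scale run at
$k = m = 28{,}679$; and DP concentration checks at mass $10^6$. These
sizes give Monte-Carlo standard errors small enough for 3-standard-error
assertions while keeping the default run to a few minutes.

## Limitations

* Only exchangeable positive dependence is simulated; the analytical
  guarantees cover arbitrary dependence but the empirical checks do not.
* The DP is discretised on integer rank bins; continuous measures (and DP
  mixtures for continuous hypothesis spaces) are out of scope.
* Weighted hypothesis spaces and online testing are not supported.
* The replication tests against the published 28,679-test PISA analysis
  require the journal's supplementary p-value file, which is not
  redistributed here; without it those three tests report the missing file.
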