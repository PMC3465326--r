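---
title: "Finite-sites polymorphism estimation and neutrality testing under among-site rate heterogeneity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Finite-sites polymorphism estimation and neutrality testing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Single-locus summaries of DNA polymorphism — the number of segregating
sites $S$, the minimum number of mutations $\eta$ (per site, the number
of distinct bases minus one, summed), nucleotide diversity $\pi$, and the
estimators and neutrality tests built on them — assume the infinite-sites
model: every mutation hits a fresh site. Hypermutable loci such as the
mitochondrial control region violate this badly. Site-specific rates vary
over orders of magnitude (well described by a gamma distribution with
shape $\alpha \approx 0.1$), so a small set of fast sites absorbs
repeated mutations. Observed $S$, $\eta$ and $\pi$ then under-count the
mutational history, estimators of the neutral parameter
$\theta = 2 N_{ef} \mu$ are biased down, and tests such as Tajima's $D$
and Fu's $F_s$ are compared against null distributions whose assumptions
the data do not meet.

This package implements the corrected machinery end to end: classical
summaries, gamma-rate finite-sites corrected estimators, a corrected
$D$-type statistic, and Monte-Carlo null distributions generated by a
built-in neutral coalescent simulator with either infinite-sites or
finite-sites (HKY85/GTR + discrete-gamma + invariant-sites) mutation.

## Corrected estimators

The correction inverts exact single-site expectations. Let a site have
relative rate $r \sim \Gamma(\alpha, \alpha)$ (mean 1) and write
$x = \theta r$ for its scaled mutation rate. Under Jukes–Cantor mutation,
a change to one of the three other bases at total rate $x$ (per pairwise
coalescent time unit) is equivalent to a *redraw* of the base uniformly
from all four at rate $4x/3$. On a neutral coalescent genealogy the
redraw events partition the sample into blocks — exactly the Ewens
partition with parameter $\theta_E = 4x/3$ — and each block receives an
independent uniform base. Because the number of blocks $B_n$ satisfies
$E[z^{B_n}] = \prod_{i=0}^{n-1} (i + z\theta_E)/(i + \theta_E)$, the
expected values of all three statistics have closed forms:

$$E[\pi_{site} \mid r] = \frac{x}{1 + 4x/3}, \qquad
  E[S_{site} \mid r] = 1 - \prod_{i=1}^{n-1} \frac{i + x/3}{i + 4x/3}, \qquad
  E[\eta_{site} \mid r] = 3\left(1 - \prod_{i=1}^{n-1}
  \frac{i + x}{i + 4x/3}\right).$$

All three reduce to the infinite-sites expectations ($\theta$ and
$a_1\theta$) as $\theta \to 0$. `expected_site_stats()` averages these
over the rate distribution (adaptive quadrature on the continuous gamma
density, or the mean over discrete category rates), and
`corrected_theta()` solves the resulting monotone equation for $\theta$
by bisection. The test suite verifies the $\eta$ expectation against
direct simulation of the Jukes–Cantor coalescent, and the estimators
recover the true $\theta$ on finite-sites simulations where Watterson's
estimator is detectably biased low.

```{r corrected}
library(finitesites)
m <- gamma_rate_model(0.102)       # strong heterogeneity, continuous
corrected_theta("Sstar", value = 67, n = 31, L = 1208, model = m)
corrected_theta("pi", value = 0.0090, n = 31, L = 1208, model = m)
```

Assumptions worth keeping in view: the expectations are derived under
Jukes–Cantor symmetry. Under strong transition bias (e.g. HKY85 with
$\kappa \approx 17$) multiple hits concentrate between two states and
saturate faster than JC predicts, so the correction is conservative
there. No invariant-sites term exists in this framework; for a locus fit
with `+I`, the convention followed is to use the `+G` shape estimate
for correction and document it.

### The corrected D-type statistic

`ds_star_plus()` contrasts the two corrected estimators on the per-locus
scale, normalized by Tajima's variance estimate at the observed $\eta$:

$$D_{s^*}^{+} = \frac{L\,(\hat\theta_{\pi} - \hat\theta_{S^*})}
  {\sqrt{e_1 \eta + e_2 \eta(\eta - 1)}}.$$

It is zero when the corrected estimators coincide, carries the sign of
their contrast, and reduces to an $\eta$-based Tajima's $D$ as
$\alpha \to \infty$ at low divergence. The exact variance of the
corrected contrast is not available in closed form; using Tajima's
variance at $\eta$ makes the statistic's scale familiar, and inference
against a simulated null (below) does not depend on the normalization.

## Null distributions and test conventions

`simulate_genealogy()` implements the standard $n$-coalescent in units
of $N_0$ generations (haploid, maternally inherited), with exponential
growth handled by closed-form inversion of the cumulative coalescence
intensity under $N(t) = N_0 e^{-gt}$ (backward time, $g$ per coalescent
unit). `mutate_infinite_sites()` drops Poisson mutations on branches;
`mutate_finite_sites()` evolves sites under a reversible HKY85/GTR
matrix scaled so that one unit of branch length yields
$\theta_{locus}/(2L)$ substitutions per site, with equal-probability
discrete-gamma category rates (Yang's category means, computed from the
incomplete-gamma identity) and invariant sites that never mutate
(variable-site rates renormalized by $1/(1 - p_{inv})$ so the locus-wide
mean rate stays 1).

`build_null()` conditions on $\theta$ (not on $S$): replicates are
simulated at a fixed $\theta_{locus}$, the statistic is computed per
replicate, and undefined replicates (no polymorphism) are dropped and
counted — the count is reported because dropping shifts percentiles at
low $\theta$. Finite-sites nulls are parameterized from the data's
Watterson estimate; infinite-sites nulls for $F_s$ conventionally
condition on the pairwise estimate. Empirical quantiles are inverse-rank
order statistics without interpolation, and p-values use
$(r+1)/(m+1)$.

Two tail conventions matter:

* **Tajima's D** is two-tailed; the simulated interval is the central
  $1-\alpha$ interval. The beta approximation
  (`tajima_beta_interval()`) rescales a beta density with mean 0 and
  variance 1 onto $(D_{min}, D_{max})$.
* **Fu's Fs** is one-tailed (lower), but its null is atypical: well
  under half its mass lies below zero, so the cutoff with 5% type-I
  error sits far below the 5th percentile — near the 2nd, as Fu
  observed. The package's critical value at level $\alpha$ is therefore
  the $\alpha/2$ quantile (`critical_values(..., tail = "lower")`), the
  lower endpoint of the same two-sided machinery used for $D$, and
  `evaluate()` calls significance for $F_s$ at $p < \alpha/2$.

```{r nulls}
cfg <- study_profile("CR")
p <- coalescent_params(31, cfg$theta_site * cfg$L)
nd <- build_null("Fs", "IS", p, n_reps = 10000, seed = 1)
critical_values(nd, level = 0.05, tail = "lower")
```

## What the synthetic-data generator emulates

`synth_study_like()` packages two fitted mitochondrial regimes of a
songbird study system: a control-region-like locus (n = 31, L = 1208,
HKY85 with $\kappa = 16.702$, base frequencies
(0.312, 0.285, 0.134, 0.269), $\alpha = 0.102$ with 12 categories,
per-site $\theta = 0.0135$) and a protein-coding ND2-like locus
(n = 31, L = 1041, GTR with exchangeabilities
(5.122, 118.9, 3.560, 8.226e-4, 47.54, 1), frequencies
(0.310, 0.355, 0.098, 0.237), $p_{inv} = 0.723$, per-site
$\theta = 0.0132$). The per-site $\theta$ defaults are the loci's
Watterson estimates, matching the $\theta$-conditioning convention of
the null machinery. Twelve rate categories reproduce the fitted
control-region model (the point at which adding an invariant class
stops improving the fit); simulation nulls are insensitive to 10 vs 12.

The generator reproduces the features the methods react to — gamma rate
heterogeneity, transition bias, invariant sites, coalescent genealogical
variance, optional exponential growth — and deliberately omits others:
no indels (the `I` column of summaries is input-data-only), no
recombination, no population structure, no among-lineage rate variation.
Tests passing on these simulations therefore validate the finite-sites
and rate-heterogeneity machinery, not robustness to structure or
selection on real data.

## Numerical choices

* Gamma-density expectations integrate over
  $[q_{10^{-14}}, q_{1-10^{-14}}]$ of the rate distribution, keeping the
  quadrature honest for both very peaked (large $\alpha$) and extremely
  skewed (small $\alpha$) densities; $\alpha = \infty$ and finite
  category models bypass quadrature entirely.
* `corrected_theta()` brackets its root adaptively and refuses inputs at
  or above the saturation ceiling of the relevant expectation
  ($3/4$ for $\pi$; $3(1 - (3/4)^{n-1})$ for $\eta$) rather than
  extrapolating.
* Stirling numbers for the Ewens distribution use the log-space
  recursion $|s(n,k)| = |s(n-1,k-1)| + (n-1)|s(n-1,k)|$ with
  log-sum-exp, stable to a few hundred sequences. $S'$ is clamped away
  from 0 and 1 with a warning if it underflows.
* $D$ at $S = 0$ and $F_s$ at $\pi = 0$ return an explicit `NA`
  (never a silent 0), and `evaluate()` reports such cases as
  "not evaluable".
* Missing data follow complete deletion by default (columns with gaps or
  ambiguity codes are excluded from nucleotide statistics; gap runs with
  identical presence/absence patterns collapse into single indel
  events); pairwise deletion is available by flag. Haplotype identity is
  computed over included columns only. Columns are 1-based everywhere.
* Reproducibility: every simulating function takes a seed; replicate
  $i$ of a null uses a deterministic substream derived from the master
  seed, so nulls are reproducible and extendable.

## Problem sizes in the shipped checks

The test suite runs its Monte-Carlo checks at sizes chosen to give
3-sigma Monte-Carlo margins around the tested expectations: 3000–4000
genealogies for coalescent moment checks, 500 finite-sites data sets for
estimator recovery and for type-I calibration against a shared
1000-replicate matched null (all 500 calibration data sets share the
null built at the true simulation parameters — what is being tested is
the type-I error of the evaluation machinery, for which a shared null at
the true parameters is the matched choice), 700-replicate paired nulls
for directional comparisons, and a 6000–10000-replicate infinite-sites
null for the $F_s$ critical value.

## Known limitations

* The corrected estimators are Jukes–Cantor-based; they under-correct
  under strong transition bias and carry a small Jensen-type upward bias
  at coalescent-scale sampling variance (well inside the 5% recovery
  margin at the study scale).
* Finite-sites nulls default to constant population size. Growth is a
  supported parameter of the simulator, but nulls built under
  growth-inclusive, genealogy-integrated parameter estimates (the kind
  MCMC machinery produces) can be far more extreme for $F_s$ than the
  constant-size nulls built here; comparisons of such published
  percentiles with this package's defaults will differ accordingly.
* $\alpha$ is a required input, never estimated (tree-likelihood
  machinery is out of scope); hotspot detection by the percentile rule
  uses parsimony change counts, which are lower bounds and not
  site-rate estimates, and the criterion name is stored with each flag
  so the two are not conflated.
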