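---
title: "Wavelet-based regional screening for differentially methylated regions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wavelet-based regional screening for differentially methylated regions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wavescreen)
```

## The problem and the model

An epigenome-wide association study asks whether the methylation profile of
a genomic region differs with a trait — case/control status, a continuous
exposure, a count. Testing CpGs one at a time ignores the spatial structure
of methylation and pays a heavy multiple-testing price; bump hunting models
only a single contiguous shift. `wavescreen` instead treats each region's
methylation as a function sampled at its CpGs and tests all resolutions of
that function at once.

The pipeline per region is:

1. **Dyadic regridding.** CpGs are irregularly spaced, so each individual's
   values are linearly interpolated onto $2^J$ evenly spaced grid points
   spanning the region (positions min–max normalized to $[0,1]$; grid
   $t_i = i/(2^J-1)$ with endpoints included, so a region that already has
   $2^J$ evenly spaced probes is passed through unchanged).
2. **Unnormalized Haar pyramid.** Each individual's grid vector is
   decomposed by Mallat's pyramid algorithm into adjacent differences of the
   running adjacent-sum cascade: the finest scale holds local differences,
   coarser scales hold differences of block sums, and scale 0 holds the
   total sum. No $1/\sqrt2$ normalization is applied — the next step makes
   coefficient scale irrelevant.
3. **Quantile transform.** Every coefficient is mapped, across individuals,
   to normal scores $\Phi^{-1}((r_k-0.5)/n)$ (average ranks for ties). This
   robs outliers and marginal distribution quirks of their influence and
   fixes each transformed coefficient's variance by construction.
4. **Reverse regression and Bayes factors.** Each transformed coefficient is
   regressed *on* the phenotype (plus covariates), so the design
   $X = (\mathbf 1, \Phi, C)$ is identical for every coefficient of every
   region. With a normal prior $\beta \sim N(0, \sigma^2 V_b)$,
   $V_b = \mathrm{diag}(\sigma_b^2)$, and $\sigma^2 \sim IG(a, b)$, the
   Bayes factor of including versus excluding $\Phi$ has a closed form in
   terms of $\log\det(X^tX + V^{-1})$ and the residual quadratic forms
   $S(X, V) = y^ty + 2b - y^tX(X^tX+V^{-1})^{-1}X^ty$.
5. **Mixture likelihood ratio.** With $\pi_j$ the proportion of scale-$j$
   coefficients associated with the phenotype,
   $\Lambda(\pi) = \prod_{j,l}\left[\pi_j BF_{jl} + (1-\pi_j)\right]$ is
   maximized over $\pi \in [0,1]^{J+1}$ by EM. The objective factorizes
   across scales and each factor is concave in $\pi_j$, so the EM maximum
   is global.
6. **Simulated null instead of permutations.** Because the design is fixed,
   under the null each $2\log BF$ approximately follows
   $\lambda_1\chi^2_1 + \log(1-\lambda_1)$, where $\lambda_1$ is the
   largest eigenvalue of $X(X^tX+V_b^{-1})^{-1}X^t$ — one number for the
   whole screen. The null distribution of $\log\hat\Lambda$ is obtained by
   drawing $M$ vectors of $2^J$ such Bayes factors and re-maximizing each;
   a region's Monte Carlo p-value is
   $(\#\{m: \log\hat\Lambda_m \ge \log\hat\Lambda_{obs}\}+1)/(M+1)$, and
   Benjamini–Hochberg adjustment across regions yields q-values.

Reverse regression trades interpretability of effect sizes for speed and
generality (binary and count traits enter the design directly); the package
is a screening tool, and regions it flags deserve targeted follow-up
modeling.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `min_cpgs` | 10 | minimum CpGs per region (segmentation) |
| `max_gap` | 500 bp | maximum adjacent-CpG distance within a region |
| `max_run` | off | optional chunking of very long probe runs |
| `sigma_b` | 1 | prior sd of regression effects (intercept, phenotype, covariates) |
| `nig_a`, `nig_b` | 0, 0 | inverse-gamma hyperparameters on $\sigma^2$ |
| `null_sims` | $10^6$ | simulated null statistics per depth $J$ |
| EM `tol` | $10^{-6}$ | sup-norm stopping rule on $\pi$ |

The depth is $J = \max_j\{2^j < \kappa\}$ for a region of $\kappa$ CpGs, so
the default segmentation (at least 10 CpGs) gives $J \ge 3$; the dyadic
grid is never finer than the observed probes. Regions with different
depths get separate null models at the same $\lambda_1$.

`sigma_b = 1` sits in the middle of the 0.1–5 range explored in the prior
sensitivity sweep of `power_experiment()`; region rankings are stable
across that range (adjacent-prior Spearman correlations above 0.9 in the
test suite), so the choice mostly affects absolute q-values, not which
regions lead.

The prior on $\sigma^2$ defaults to the Jeffreys-type limit $a = b = 0$.
The intercept (and covariates) carry the same $\sigma_b$ prior as the
phenotype effect; `prior_on_intercept = FALSE` switches to an effectively
flat intercept prior. These choices are pinned by a numerical-integration
oracle in the tests, not trusted from the algebra.

## Numerical choices

* **All Bayes-factor computation is in log space**; determinants come from
  Cholesky factors of the small $(X^tX + V^{-1})$ matrices, and the mixture
  terms $\log(\pi_j BF_{jl} + 1 - \pi_j)$ are evaluated by log-sum-exp so
  enormous Bayes factors cannot overflow.
* **$\lambda_1$** is computed from the symmetric similar matrix
  $R^{-T}(X^tX)R^{-1}$ with $X^tX + V_b^{-1} = R^TR$, never by inverting
  the $n \times n$ projector. It is bitwise identical across regions.
* **The statistic is the EM-converged objective, not an exactly resolved
  boundary maximum.** Since $\pi \equiv 0$ is feasible, the theoretical
  maximum is never negative, but when every Bayes factor in a scale is
  small the maximizer lies at $\pi_j = 0$ and EM approaches it
  geometrically, stopping within `tol`. The returned value can therefore
  undershoot zero by a tolerance-sized amount. This is deliberate: exact
  boundary resolution would place a point mass at 0 (probability ≈ 0.7
  per region at typical $\lambda_1$) in both the observed and simulated
  statistics, making Monte Carlo p-values pile up at 1. With the
  continuous EM value, null p-values are uniform on $(0,1)$ — the property
  the calibration tests assert — while rejection decisions at any
  practical threshold are identical.
* **Degenerate coefficients** (identical across individuals, e.g. a region
  of constant methylation) quantile-transform to all-zero scores and are
  assigned $\log BF = 0$: no evidence either way.
* **Ties** in coefficients use average ranks; the plotting position
  $(r-0.5)/n$ keeps scores bounded away from $\pm\infty$.
* **Phenotype standardization in the simulation experiments** uses the
  population ($1/n$) variance, so $\sum \Phi_k^2 = n$ exactly. Then the
  phenotype column's eigenvalue coincides with the intercept's $n/(n+1)$
  and $\lambda_1$ is exactly the null-law parameter of the tested
  coefficient under orthogonal columns. This matters more than it looks:
  the null law's density is unbounded at its left endpoint
  $\log(1-\lambda_1)$, so even an $O(1/n)$ eigenvalue mismatch costs
  ~0.02–0.03 in Kolmogorov–Smirnov distance. It also makes $\lambda_1$
  identical (to $10^{-12}$) across replicates that redraw the phenotype,
  so one simulated null is shared by a whole experiment; a replicate whose
  $\lambda_1$ deviates beyond $10^{-12}$ gets its own freshly simulated
  null.

## What the synthetic data emulate — and what they do not

`simulate_null_population()` reproduces the classical benchmark design for
type-I studies: individual functions $a\,T(x) + \varepsilon$ built from the
four Donoho–Johnstone test signals (blocks, bumps, heaviSine, doppler; the
standard breakpoints and heights are tabulated in the source) on a
$2^6 = 64$-point grid, with an independent standard-normal trait. The grid
length is a package choice — calibration is insensitive to it, which the
suite checks at two grid lengths.

The amplitude $a$ is drawn **once per population** by default. Read
literally as one amplitude per individual, the shared function component
correlates the wavelet coefficients across individuals, and the
independence assumption behind the simulated null then inflates the test:
we measure rejection ≈ 0.02 at $\alpha = 0.01$, $n = 100$ (and deflation
at $n = 500$) — the same order of miscalibration the method shows on real,
spatially correlated methylation data. Only the population-level reading
yields the uniform, $n$- and function-independent calibration that a clean
null study exhibits (the rank-based quantile transform removes a constant
column shift entirely, so all four test functions give *identical*
p-value streams under a common random seed). Both modes are available via
`amplitude =`; the per-individual mode is the honest stress test of the
independence assumption, not a calibration benchmark.

At small $n$ the calibration of the screen itself is finite-sample
limited: with $a = b = 0$ the exact null of $2\log BF$ has a slightly
heavier right tail than the asymptotic $\lambda_1\chi^2_1$ law (the
relative deviation of the tail grows as the $-(n+2a)\log(1-x)$ curvature
correction becomes non-negligible), and at $n = 100$ we measure rejection
≈ 0.013 at $\alpha = 0.01$. By $n = 500$ the law is accurate and the
acceptance checks run there. Users screening cohorts of a few dozen
samples should interpret borderline q-values cautiously — the same caveat
the method carries on real data.

`synth_dnam_dataset()` emulates a two-group methylation study: probe runs
separated by large gaps, baseline beta values in $(0.1, 0.9)$, Gaussian
noise of sd 0.1 on the beta scale, and a planted mean shift (default 0.2,
directed away from the nearer boundary) at a contiguous block of CpGs in
10% of regions, with group sizes 13 + 13. What it does **not** emulate:
spatial correlation of methylation along the genome, heteroscedastic and
bounded beta-value noise, batch effects, or repeated measures. Passing
tests on these data therefore demonstrate correctness of the machinery and
the qualitative power gradient (power rising with the number of shifted
CpGs per region), not field performance on arrays.

## Problem sizes used in the checks

The packaged acceptance analyses use 10,000 null replicates against
100,000 simulated null statistics per type-I cell ($n = 500$), 2,000
replicates for p-value uniformity ($n = 1000$), 10,000 draws for the
Bayes-factor law comparison, 500 random vectors for the EM-versus-grid
check, and 200 regions × 1,000 permutations for the
simulation-versus-permutation comparison. These sizes give Monte Carlo
standard errors comfortably below the tolerances being asserted while
keeping a full run on a single CPU in the minutes range; production
screens default to $M = 10^6$ null simulations.

## Known limitations

* Dependence between wavelet coefficients is ignored by design; on data
  with strong spatial correlation the test is anti-conservative at small
  $n$ (use the permutation validation mode to spot-check).
* Repeated measures / paired designs are not modeled; samples are assumed
  independent.
* The permutation mode permutes phenotype and covariates jointly; exchange
  ability under the null is the user's responsibility when covariates are
  present.
* Effect sizes are not returned — the reverse regression shrinks them and
  they are not interpretable as methylation differences. Follow up flagged
  regions with a direct model.
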