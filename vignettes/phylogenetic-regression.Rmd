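---
title: "Phylogenetic signal, phylogenetic regression, and model comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylogenetic signal, phylogenetic regression, and model comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phyloregress)
```

## The statistical problem

Cross-species regressions treat species as data points, but species are
related by descent. If a trait evolves gradually along a phylogeny, closely
related species carry similar values, and the residuals of a species-level
regression are correlated rather than independent. An ordinary least-squares
(OLS) regression silently assumes a phylogeny of its own: it is the special
case of generalized least squares (GLS) whose residual covariance is
proportional to the identity matrix — exactly the covariance a *star phylogeny* (a single
polytomy with equal branch lengths) would generate under Brownian-motion
evolution. When residuals are in fact phylogenetically correlated, OLS
understates the sampling variance of the slope and rejects true null
hypotheses far too often; this package exists to make that failure, and its
remedies, measurable.

The package implements four connected pieces:

1. **Phylogenetic signal** — Blomberg's K with a randomization test of the
   mean squared error, for raw traits and for regression residuals.
2. **Three regression families** — OLS, PGLS (Brownian-motion residual
   covariance; equivalent to independent contrasts), and RegOU (residual
   covariance from a one-parameter Ornstein–Uhlenbeck family, its parameter
   estimated by REML) — with ML log-likelihoods on a shared constant
   convention so they can be ranked directly.
3. **Model comparison** over a grid of alternative topologies ×
   branch-length schemes × models, with likelihood-ratio tests of RegOU
   against OLS, plus phylogenetic ANCOVA for threshold-style group effects.
4. **A synthetic-data generator** that produces trees and traits with
   exactly the covariance structure the models assume, so every stage is
   validated by simulation rather than by appeal to any external dataset.

## Models

### Tip covariance under Brownian motion

For a rooted tree with branch lengths, `bm_covariance()` returns the matrix
\(V\) with \(V_{ij}\) the shared root-to-MRCA path length of tips \(i, j\)
and \(V_{ii}\) the tip depth. Brownian-motion trait evolution with rate
\(\sigma^2\) gives tip values distributed \(\mathrm{MVN}(\mu 1, \sigma^2 V)\).
A star tree of depth 1 gives \(V = I\).

### The OU transform

`ou_covariance()` connects the star and BM structures through one
dimensionless parameter \(d \ge 0\) (the transform of the OU restraining
force \(\alpha\) via \(d = e^{-2\alpha}\) per unit branch length). With
shared depth \(s_{ij}\) and tip depths \(t_i\),

\[ V_{ij}(d) = d^{(t_i + t_j)/2 - s_{ij}} \, \frac{1 - d^{s_{ij}}}{1 - d}, \]

with analytic limits \(V(1) = V_{BM}\) and \(V(0) = I\)-structured
(diagonal). Values \(d > 1\) make relatives *more* similar than Brownian
motion predicts. This fixed-root parameterization was chosen because it
reproduces every limit the analysis relies on — \(d = 1\) recovers PGLS,
\(d = 0\) recovers OLS, and \(d > 1\) expresses stronger-than-BM similarity —
while remaining a smooth scalar family amenable to bounded scalar
optimization. Other software parameterizes the OU residual model
differently (and may normalize the matrix differently), so interior
estimates \(\hat d\) are comparable across implementations only up to that
reparameterization; the limits and the likelihood ordering are not affected.
Near \(d = 1\) the ratio \((1 - d^s)/(1 - d)\) is evaluated with `expm1`
for stability, and within \(10^{-10}\) of the limits the analytic limit
matrices are used. For non-ultrametric trees (e.g. substitution-rate branch
lengths) the generalized exponent \((t_i + t_j)/2 - s_{ij}\) is used and a
warning notes that the \(d = 0\) limit is a unit-diagonal matrix rather
than the tree's own star covariance.

### Blomberg's K and the MSE randomization test

With the GLS phylogenetic mean
\(\hat a = (1'V^{-1}1)^{-1} 1'V^{-1} y\), define
\(\mathrm{MSE0} = (y-\hat a)'(y-\hat a)/(n-1)\) (identity metric) and
\(\mathrm{MSE} = (y-\hat a)'V^{-1}(y-\hat a)/(n-1)\) (GLS metric). K is the
observed ratio \(\mathrm{MSE0}/\mathrm{MSE}\) scaled by its Brownian-motion
expectation \([\mathrm{tr}(V) - n/(1'V^{-1}1)]/(n-1)\): K \(\approx 0\)
means no signal, K \(= 1\) matches the BM expectation, K \(> 1\) stronger
similarity. On a star tree the two metrics coincide and K is identically 1.

The randomization test permutes trait values across tips (preserving the
multiset, destroying the tree association) and counts permutations whose
GLS-metric MSE is at most the observed one — a one-sided test, since
genuine signal makes the observed MSE small. The p-value uses the add-one
convention \((1 + \#\{\mathrm{MSE}_\pi \le \mathrm{MSE}_{obs}\})/(n_{perm}+1)\),
so it can never be 0 and its floor is \(1/(n_{perm}+1)\); the default 999
permutations resolve \(p = 0.001\). Raw trait values are permuted, without
prior standardization.

### GLS fitting and likelihoods

All three families share one engine:
\(\hat\beta = (X'V^{-1}X)^{-1}X'V^{-1}y\) with
\(\hat\sigma^2_{ML} = e'V^{-1}e/n\) and

\[ \ln L = -\tfrac{n}{2}\left[\ln 2\pi + \ln \hat\sigma^2_{ML} + 1\right]
   - \tfrac{1}{2}\ln |V|. \]

Because OLS is fitted as GLS with \(V = I\) (\(\ln|I| = 0\)), the constant
convention is shared and log-likelihoods can be ranked across models — the
property the comparison grid depends on. Coefficient standard errors use
the unbiased \(e'V^{-1}e/(n-p)\), and slope p-values use the t distribution
with \(n - p\) degrees of freedom, the appropriate small-sample reference
for comparative datasets of 15–30 species. \(r^2\) is reported in each
model's own GLS metric (1 minus the ratio of the model's weighted residual
sum of squares to the phylogenetic-mean model's); it is **not** comparable
across covariance models, and reports say so.

All solves go through a Cholesky factorization of \(V\); explicit inverses
appear only in the test oracles. A covariance that fails factorization
receives one round of diagonal jitter bounded by \(10^{-10}\times\) the mean
diagonal (logged), small enough never to mask a genuinely indefinite matrix.

### RegOU estimation

The OU parameter is estimated by REML — maximizing

\[ \ln L_R(d) = -\tfrac12\left[(n-p)\ln\hat\sigma^2_R(d) + \ln|V(d)| +
   \ln|X'V(d)^{-1}X| + (n-p)(1+\ln 2\pi)\right] \]

— so the variance-structure estimate is free of fixed-effect bias, while
the *reported* likelihood is the ML log-likelihood evaluated at \(\hat d\),
keeping it comparable with the OLS and PGLS columns. Slope inference
conditions on \(\hat d\) (the extra uncertainty from estimating \(d\) is
not propagated; this is documented behavior, not an oversight). The search
is bounded scalar optimization on \([0, 5]\) with tolerance \(10^{-6}\)
from three starts (0.01, 1, 3); ties resolve toward smaller \(d\)
(parsimony toward OLS), and estimates on a search bound are flagged.

### Model comparison

RegOU nests OLS at \(d = 0\), so the two are compared by a likelihood-ratio
test with 1 degree of freedom. Because the null value lies on the boundary
of the parameter range, the plain \(\chi^2_1\) reference is conservative;
this convention is retained deliberately rather than switching to a mixture
reference. PGLS and OLS are *not* nested (different fixed \(V\)), so they
are compared by raw log-likelihood only, with no p-value attached. An
optional RegOU-vs-PGLS LR test (nesting at \(d = 1\)) is available through
`lr_test()` but is not part of the default grid output.

`select_best()` ranks by ML log-likelihood; ties within \(10^{-8}\) break
toward fewer estimated parameters, then toward PGLS over RegOU.

### Residual diagnostics

The model-choice criterion tests the OLS fit's **response-scale** residuals
\(y - X\hat\beta\) for phylogenetic signal: signal there means phylogeny
still structures the response after the predictors act, so a phylogenetic
model is warranted. Response-scale residuals are the only meaningful choice
for this purpose — GLS-whitened residuals have their signal removed by
construction. Conversely, response-scale residuals of a *correctly
specified* PGLS retain signal by construction, so for the best-ranked model
`grid_report()` runs the complementary *adequacy* diagnostic on its
whitened residuals, which are i.i.d. exactly when the fitted covariance is
right; remaining signal there flags an inadequate structure.

### Phylogenetic ANCOVA

`ancova_fit()` adds a two-level group indicator (optionally its interaction
with the covariate) to the GLS design — e.g. "high" versus "low" classes of
a predictor split at a threshold. Group coefficients are tested with the
same t reference as slopes. The balance report warns whenever the smaller
group has fewer than 5 members, because severely unbalanced splits (13/2,
15/3) cannot support confident ANCOVA inference under *any* covariance
model; a singleton group is refused outright and only the counts are
reported.

## The synthetic-data generator

`simulate_regression_dataset()` draws
\(y = a + b x + \varepsilon\), \(\varepsilon \sim
\mathrm{MVN}(0, \sigma^2 V(d))\) via a Cholesky factor, with the predictor
itself Brownian on the tree by default — comparative predictors typically
carry signal, and this is what makes OLS anti-conservative under the null.
The defaults emulate the geometry of a species-level genome-size regression
on the log10 scale: 29 taxa, slope \(-1.17\), intercept 0.4, residual SD
0.9, BM residuals (\(d = 1\)). The slope and sample size mirror a published
comparative analysis as a *realistic setting*; nothing in the tests treats
them as quantities to be re-estimated from real data. Root states are fixed
at 0 (location is absorbed by the intercept), and pure-birth trees are
rescaled to unit depth so \(d\) means the same thing across replicate
trees.

What the generator deliberately does **not** emulate: measurement error in
the predictor (real \(\pi_s\)-based population-size estimates are noisy, and
that error is unquantified), non-Gaussian trait evolution, correlated
missingness across traits, and mechanistic genome dynamics (transposable
element proliferation, insertion/deletion bias). Passing simulation tests
therefore demonstrates that the *statistical machinery* is correct under
its own assumptions — not that those assumptions hold for any particular
empirical dataset.

### Calibration conditions and problem sizes

Validation simulations use a 64-tip balanced tree with all branch lengths 1
(depth 6). Two reasons, both scientific:

* its regular structure gives a known, strong phylogenetic covariance, and
  1000 BM replicates put the mean of K within a tight band around 1;
* the OU parameter is well identified on it. On unit-depth pure-birth
  trees \(d\) is only weakly identified (the profile likelihood is nearly
  flat, and median REML estimates drift far from the truth), whereas on the
  depth-6 balanced tree median \(\hat d\) over replicates recovers
  \(d \in \{0.3, 1, 1.5\}\) well within \(\pm 0.25\).

Replicate counts (1000 for type-I-error calibration and the K mean, 500 for
slope-recovery, 200 per value for \(d\)-recovery, 99–999 permutations for
randomization tests) were chosen so Monte-Carlo error is small against each
test's acceptance band.

## Numerical and design choices

* **Species matching** is exact string equality after trimming outer
  whitespace, case-sensitive; mismatches are summarized, never silently
  dropped. Missing data are handled by complete-case analysis per fit — the
  per-trait sample sizes in reports legitimately differ — never imputation.
* **log10 transforms** are base 10, applied only to strictly positive
  values; offenders are named in the error.
* **Polytomies** are handled as-is through the covariance matrix; no
  zero-length binary expansion is needed because GLS only consumes \(V\).
* **Determinism**: every stochastic operation takes an explicit seed or
  derives one deterministically from the caller's; report writers embed the
  seed and package version, so identical configurations give byte-identical
  outputs.
* **Degenerate inputs**: constant traits are a hard error in signal tests
  (K is undefined); trees without branch lengths must receive a scheme
  before covariance construction; negative or missing lengths are rejected
  with the offending edge named.

## Known limitations

* Interior \(\hat d\) values are parameterization-specific (see above);
  only the limits and likelihood orderings transfer across OU
  implementations.
* Slope inference in RegOU conditions on \(\hat d\).
* The LR test of RegOU against OLS is conservative at the \(d = 0\)
  boundary.
* Measurement error in predictors is not modeled, and \(r^2\) values are
  not comparable across covariance models.
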