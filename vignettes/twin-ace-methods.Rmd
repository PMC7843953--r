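---
title: "Liability ACE models for OCS and suicidality: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Liability ACE models for OCS and suicidality: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twinace)
```

## The scientific problem

Obsessive-compulsive symptoms (OCS) occur on a continuum in the population
and are associated with suicidal ideation and attempts well below the
diagnostic threshold for OCD. Two questions follow. First, is the
phenotypic association between OCS severity and suicidality robust to
co-occurring depression and anxiety? Second, to what extent is the
association driven by shared genetic liability versus environmental
exposure? `twinace` implements the full analysis stack for both questions
on population twin-cohort data: a phenotypic layer of cluster-robust
logistic regressions, and a biometric layer of ACE liability-threshold
models fitted by raw-data full-information maximum likelihood (FIML).
Because registry cohorts cannot be redistributed, the package also ships a
synthetic twin-cohort generator with the same statistical structure, so
every stage is testable offline.

## The classical twin design

Monozygotic (MZ) twins share all segregating genetic variants; dizygotic
(DZ) twins share half on average. A phenotype's variance is decomposed
into additive genetic (A), shared-environment (C) and non-shared
environment (E, which absorbs measurement error) components with
standardized paths $a$, $c$, $e$ satisfying $a^2+c^2+e^2=1$. The implied
correlation between co-twins is $a^2+c^2$ for MZ pairs and
$\tfrac12 a^2+c^2$ for DZ pairs — the MZ/DZ contrast identifies A.

For two traits the correlated-factors solution adds aetiological
correlations $r_A$, $r_C$, $r_E$ between the traits' factors. The implied
within-person cross-trait correlation is

$$ r_{Ph} = r_A\,a_1 a_2 + r_C\,c_1 c_2 + r_E\,e_1 e_2, $$

and each term's share of $r_{Ph}$ is reported as %A, %C, %E. The
cross-twin cross-trait correlation scales the A term by 1 (MZ) or 0.5
(DZ) and drops the E term; its MZ > DZ pattern is the raw signal of
genetic covariance. `implied_structure()` assembles these $2p \times 2p$
matrices, and the test suite verifies them against an independent
chain-enumeration path-tracing oracle to $10^{-10}$.

Binary and ordinal phenotypes (suicide attempt, the suicidality
composite, ordinal symptom subscales) are modelled as discretizations of
a standard-normal liability at free thresholds. Age and sex can enter the
threshold equations as linear shifts; continuous traits are expected to
be log-transformed, standardized and sex-regressed upstream
(`log_standardize()` and ordinary regression), mirroring how such scores
are prepared in practice.

## Likelihood and numerics

Each twin pair contributes a $2p$-dimensional normal likelihood in which
continuous dimensions appear as densities and ordinal dimensions as
rectangle probabilities between consecutive thresholds; missing
dimensions are marginalised (FIML), so pairs observed at one wave only,
or with one co-twin missing, still contribute.

Mixed continuous/ordinal pairs are factored exactly as (continuous
marginal Gaussian) × (conditional ordinal rectangle with shifted mean and
reduced covariance), which avoids high-dimensional integration in the
common bivariate case. Rectangle probabilities use:

* dimension 1: the normal CDF;
* dimension 2: an exact bivariate-normal CDF computed by fixed
  Gauss-Legendre quadrature of the tetrachoric integral representation
  (48 nodes, absolute error below $10^{-9}$ for $|\rho| \le 0.99$),
  vectorised across pairs; one-sided rectangles — the binary-trait case —
  reduce to a single CDF call by reflection;
* dimension 3-4 with pair-specific bounds (the trivariate model): Genz's
  separation-of-variables transform evaluated on a fixed 256-point
  Richtmyer lattice, vectorised across pairs. The point set is
  deterministic, so repeated evaluations are bit-identical; absolute
  accuracy is of order $10^{-4}$, which is validated in the tests against
  both a deterministic grid integrator (Miwa) and brute-force Monte-Carlo
  integration. This is a deliberate trade: a dense deterministic grid at
  $10^{-6}$ makes the trivariate fit roughly two orders of magnitude
  slower for a precision far below the statistical noise at any
  realistic cohort size;
* pure-ordinal blocks with no covariates collapse to the handful of
  distinct category cells, each integrated once per likelihood
  evaluation with the Miwa grid algorithm.

Probabilities are floored at $10^{-300}$; an observed category with
numerically zero probability under the current thresholds contributes a
large finite penalty and a warning rather than `NaN`.

### Parameterisation and optimisation

Free parameters are boxed transforms chosen so every candidate structure
is valid: variance shares via spherical angles
($a = \cos\varphi_1$, $c = \sin\varphi_1\cos\varphi_2$,
$e = \sin\varphi_1\sin\varphi_2$, so the unit-variance constraint holds
by construction and the boundary $c \to 0$ is well-behaved), factor
correlations boxed in $(-0.999, 0.999)$, thresholds as a free first cut
plus log-increments (monotone by construction), and continuous scales on
the log scale. Trivariate models use lower-triangular Cholesky path
matrices; the likelihood standardises each liability to unit variance, and
a small quadratic penalty pins the (otherwise likelihood-flat) row scale.
Reported Cholesky paths are row-standardized, so a path's square is its
variance contribution.

Optimisation is `nlminb` with data-driven starting values (thresholds
from observed margins, shares from the Falconer reading of the MZ/DZ
correlations, factor correlations from the observed cross-trait
correlation) plus deterministic jittered restarts from a fixed sub-seed;
the best converged solution is reported, and a fit that never converges
carries an explicit failed status rather than a silent partial result.
`fit_model(n_starts = )` controls the restart count: the default of 5 is
appropriate for the moderate cohort sizes of routine use, while the
large simulated cohorts used for calibration (20,000 pairs per zygosity)
have likelihood surfaces smooth enough that the data-driven start alone
converges, which keeps those runs inside a few minutes.

### Confidence intervals and model comparison

Significance is judged by 95% likelihood-based intervals: a parameter's
bound is where $-2\mathrm{LL}$ rises by 3.841 with all other parameters
re-optimised. Parameters that map monotonically to a single free
coordinate (factor correlations, thresholds, means, scales, heritability
shares in the AE and ACE forms) are profiled by root-finding on the
profile deviance; derived quantities such as %A are profiled as functions
of the parameters with an exterior-penalty constrained optimiser.
Intervals truncated at a natural bound (a share at 0, a correlation at
±1) are flagged. Model comparison reports the chi-square test on
$\Delta(-2\mathrm{LL})$ and $\Delta$AIC, with an AIC difference of 3 or
more read as support for the lower-AIC model. The pipeline codifies the
reduction rule used in this literature: fit ACE first; when every C share
is below 5% (and the likelihood-ratio test finds no significant loss),
accept the AE model.

## The synthetic cohort generator

`simulate_twin_cohort()` draws per-pair liabilities from the exact
multivariate normal the models assume (cross-twin A coefficient 1.0 for
MZ, 0.5 for DZ; C coefficient 1.0 for both; E uncorrelated across twins),
adds covariate effects, then thresholds ordinal traits and rescales
continuous ones. Defaults mirror a Swedish young-adult twin register
wave: ~30% MZ / ~66% DZ with a small unknown-zygosity fraction (excluded
by model fitting, as in practice), a slight female majority, assessment
near age 18 with a later wave near 24, a 6% suicide-attempt prevalence at
the first wave, and positively skewed OCS totals produced by an
exponential transform of the liability scaled to a target mean and SD
(floored at zero, as count-like questionnaire totals are) — so the
log-transform step is exercised round-trip. Attrition at the later wave
is pairwise (both co-twins drop together), reflecting the strong family
clustering of registry follow-up response; whether real attrition is
pairwise or individual is not identified from published tables, and this
is an explicit assumption. Per-item missingness is independent Bernoulli,
included to exercise FIML.

What the generator does **not** emulate: item-level measurement (scores
are simulated at the scale level, except for the binary-item factor
fixture used to test the tetrachoric PCA), informant effects
(parent-report), sex-limitation of the genetic architecture (sex enters
only as a covariate; DZ pairs are pooled), and selective attrition
related to the phenotypes. Passing tests therefore demonstrate that the
estimators recover the generating process they assume — not that real
registry data satisfy those assumptions.

## The phenotypic layer

`cluster_robust_logistic()` pairs ordinary ML logistic regression with a
family-clustered sandwich variance, since co-twins are not independent
observations; odds ratios carry Wald intervals on the robust standard
errors (the convention for robust-cluster output). Missing covariates are
dropped listwise per model, with the n reported. The suicidality
composite is an OR-combination with three-valued logic: endorsement of
either item is positive, and a missing item alongside an observed zero
leaves the composite missing, because endorsement cannot be ruled out.
`tetrachoric()` uses two-step ML (thresholds fixed from the margins, then
Brent search on the correlation, tolerance $10^{-8}$), and
`pca_tetrachoric()` eigendecomposes the pairwise matrix with a
nearest-PSD repair (flagged) when pairwise assembly breaks positive
semi-definiteness; component retention is fixed by configuration
(default 4), since checklist analyses of this kind report a fixed
solution rather than a retention rule.

## Design choices made where the design was open

* **Log transform.** The literature says only "log-transformed";
  $\ln(x+1)$ is used because the scales include zeros.
* **Ordinal resolution.** Symptom subscales enter the liability models as
  binary by default, with k-category support through the thresholds
  vector, since the category count used in the original analyses is not
  published.
* **Thresholds across models.** Each model estimates its own thresholds;
  nothing is carried over between the bivariate and trivariate fits.
* **Correlation gate.** Bivariate decompositions run only when the latent
  phenotypic correlation exceeds 0.2 (configurable): decomposing weaker
  associations yields unstable solutions. The gate correlation is
  computed on the liability scale (Pearson, biserial-rescaled, or
  tetrachoric as appropriate).
* **Multiple testing.** None applied; per-model significance stars are
  reported as is, matching field convention for these tables.
* **Attrition.** Pairwise, as discussed above.
* **Identification of continuous traits.** A free mean and scale per
  continuous trait, with shares constrained to the unit sphere — the data
  are expected standardized, and the free scale simply absorbs any
  departure.

## Problem sizes used in the shipped checks

The calibration checks fit the bivariate AE model to 20,000 MZ + 20,000
DZ simulated pairs (where estimates of $r_A$ and %A are tight enough to
compare against published values), univariate models to 10,000 + 10,000,
and the trivariate model to roughly 850 pairs with 70% later-wave
retention — chosen to exercise the FIML machinery at realistic scale
while keeping a full run in the minutes range. Profile-interval coverage
is checked on 20 scaled-down replicates (250 pairs per zygosity).

## Known limitations

* No sex-limitation, dominance (D), or rater-bias models; no definition
  variables beyond the threshold covariates; no WLS fitting path.
* The correlated-factors form is limited to two traits; larger systems
  use the Cholesky form.
* Percentage-share intervals from the penalty profiler are accurate to
  roughly the optimizer tolerance, not to the root-finding precision of
  the single-parameter profiles.
* The lattice integrator's $\sim 10^{-4}$ accuracy bounds the
  reproducibility of trivariate $-2\mathrm{LL}$ values across platforms
  at around that level (within a platform it is bit-reproducible).

## A worked example

```{r example, eval = FALSE}
cfg <- sim_config(
  n_mz_pairs = 2000, n_dz_pairs = 3000,
  traits = list(
    trait_spec("ocs", "continuous", a2 = 0.37, e2 = 0.63,
               mean = 1.8, sd = 2.2, skew = 0.8),
    trait_spec("att", "binary", a2 = 0.61, e2 = 0.39, prevalence = 0.06)
  ),
  rA = 0.42, rE = 0.13, seed = 1
)
sim <- simulate_twin_cohort(cfg)
sim$ocs_z <- log_standardize(sim$ocs)

fit <- fit_model(
  sim,
  ace_model(rbind(model_trait("ocs_z", "continuous"),
                  model_trait("att", "binary")), components = "AE")
)
decompose_correlation(fit)
```
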