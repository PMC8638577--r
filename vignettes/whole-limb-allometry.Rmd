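---
title: "Methods: whole-limb muscle allometry by phylogenetic regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: whole-limb muscle allometry by phylogenetic regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(limbscale)
```

## The model

Muscle architecture is summarised per muscle by physiological
cross-sectional area, $\mathrm{PCSA} = m\cos\alpha / (\rho\,\ell)$, with
belly mass $m$ (kg), pennation $\alpha$ (degrees, converted to radians at
computation time), fascicle length $\ell$ (m) and tissue density
$\rho = 1060$ kg m$^{-3}$. PCSA assumes all fascicles act in parallel, so
their cross-sections sum; it is the standard proxy for maximal isometric
force once multiplied by the maximal isometric muscle stress
$\sigma = 3\times10^5$ N m$^{-2}$. Limb-level quantities are the total
muscle mass $\Sigma m$, the total/mean/median PCSA expressed as
body-weight-normalised strength
$F^*_{max} = \mathrm{PCSA}\,\sigma/(m_{body}\,g)$, and the characteristic
fascicle length $L^* = \Sigma m/(\rho\,\Sigma\mathrm{PCSA})$ — the mass-
and pennation-weighted harmonic mean of the fascicle lengths, i.e. the
fascicle length of a single muscle equivalent to the whole limb.

Each comparison is fitted on the log10 scale,
$\log_{10}Y = \log_{10}A + B\log_{10}X$, by generalized least squares with
residual covariance $\sigma^2 V(\lambda)$: $V$ is the Brownian-motion
expectation on a time-calibrated ultrametric tree (entry $i,j$ = shared
root-to-tip path length), and Pagel's $\lambda \in [0,1]$ multiplies the
off-diagonals. $\lambda$ is estimated by profiling the Gaussian
log-likelihood (ML variance $\hat\sigma^2_{ML} = e^\top V^{-1}e/n$) over a
21-point grid followed by bounded scalar optimisation (tolerance $10^{-6}$).
Standard errors and 95% confidence intervals use the unbiased variance
$e^\top V^{-1}e/(n-p)$ with $t$ quantiles on $n-p$ degrees of freedom. A
fitted slope is classified against its geometric-similarity expectation
(1, $-\tfrac13$, $\tfrac13$, $\tfrac23$ depending on the comparison): the
expectation outside the CI means significant negative or positive
allometry at the CI's level.

Slope estimates are invariant to multiplying $V$ by any positive constant,
so the absolute time-scaling of the tree (Ma versus unit depth) is
immaterial; the test suite asserts this at scale factors 0.1 and 10. They
are likewise invariant to the value of $\sigma$, which only shifts
intercepts of the strength comparisons by $\log_{10}k$.

## Group comparisons (ANCOVA)

Differences between mammals, reptiles and bipeds are tested by nested GLS
F-tests after whitening by the Cholesky factor of $V$. The model pairs are
a design decision (the tests are conventionally named S, I and S + I but
their nested pairs are rarely spelled out):

* **S** — group slopes + group intercepts *vs* common slope + group
  intercepts (a pure slope test);
* **I** — common slope + group intercepts *vs* one common line (an
  intercept test at a shared slope);
* **S + I** — group slopes + intercepts *vs* one common line.

This keeps $df_1$ equal to the number of released parameters and makes
each F non-negative by RSS monotonicity. $P$ comes from
$F(df_1,\,n-p_{full})$ with no multiple-testing correction (per-cell
reporting). The phylogenetic variant scales $V$'s off-diagonals by the
$\lambda$ estimated for the pooled fit of the same comparison and cell;
the non-phylogenetic variant sets $\lambda = 0$. With noiseless identical
lines both models interpolate and the F ratio is formally $0/0$; it is
defined as $F = 0$, $P = 1$ (no evidence of difference), guarded by a
machine-precision threshold on the RSS difference.

## Predictive equations, intervals and %PE

Pooled ("pan-amniote") equations are fitted after dropping bipeds by
default, the convention for quadruped-oriented prediction. Prediction for
a new taxon treats it as phylogenetically independent of the sample: zero
covariance with every tip and own variance equal to the mean root-to-tip
depth of the training tree (exactly 1 on the unit-depth trees used here),
giving
$\hat y_0 \pm t_{1-\alpha/2,\,n-2}\sqrt{\hat\sigma^2\,(\bar v_0 + x_0^\top
(X^\top V^{-1}X)^{-1}x_0)}$. Back-transform to original units is a plain
antilog with no log-normal bias correction (a `bias_correct` flag exists,
default off), matching how allometric prediction equations are normally
reported. The mean percent prediction error,
$\%PE = \mathrm{mean}\,100\,|10^{r_i}-1|$ over in-sample log10 residuals,
is offered as an alternative margin; the in-sample (not leave-one-out)
convention is deliberate and documented — leave-one-out values would be
slightly larger.

## Synthetic data: what it emulates and what it does not

The generator reproduces the statistical structure the analysis assumes:

* **Trees** — pure-birth clades grafted onto a fixed backbone so each
  group (mammal/reptile/biped) is monophyletic, ultrametric with unit
  depth; group proportions default to 0.55/0.30/0.15, similar to broad
  comparative samples.
* **Traits** — log10 body masses uniform on $(-1.5, 3.5)$ (five orders of
  magnitude); $\log_{10}\Sigma m$ and $\log_{10}L^*$ linear in log10 body
  mass with group-specific coefficients (defaults near isometry: mass
  slopes 1.00/0.92/1.10, hindlimb intercept about $-1.3$, i.e. ~5% of body
  mass in hindlimb muscle; $L^*$ slopes near $\tfrac13$, ~2.7 cm at 1 kg);
  residuals multivariate normal with covariance
  $sd^2\,V(\lambda_{true})$, defaults $sd = 0.08$ log10 units and
  $\lambda_{true} = 1$. These values were fixed once as field-realistic
  and are not tuned.
* **Muscles** — each species × limb total is partitioned by a Dirichlet
  draw (concentration 1 by default; lower values mimic the skewed
  per-muscle mass distributions of real limbs), pennation uniform on
  $[0, 35]^\circ$, and effective fascicle lengths are lognormal
  multipliers rescaled by a closed-form constant so aggregation recovers
  $\Sigma m$ and $L^*$ exactly (machine precision) — an exact solver, so
  no rejection/retry loop is needed. One reptile hindlimb muscle is marked
  as the caudofemoralis longus carrying 15% of hindlimb muscle mass.
* **Seeding** — tree, traits and muscles draw from distinct seed streams
  (`seed + 1/2/3`), so enlarging one stage never perturbs another;
  outputs are byte-identical across runs.

The `isometric_fixture()` builds the noiseless geometric-similarity case
(muscle masses $\propto m_{body}$, lengths $\propto m_{body}^{1/3}$,
constant pennation): every comparison's fitted slope equals its isometric
expectation to machine precision, for any $\lambda$, which anchors the
end-to-end pipeline test.

What the generator does **not** emulate: real anatomical muscle counts and
names, limb-specific intercept differences (fore and hind share trait
coefficients; the forelimb simply lacks bipeds), measurement error
structure of dissection data (mass-only literature records, investigator
splitting of muscle complexes), and non-ultrametric trees. Passing tests
on synthetic data therefore demonstrate correctness of the estimators
under the assumed model, not robustness to the messiness of curated
literature data.

## Numerical choices and degenerate inputs

* $\lambda$ ties (flat profile, e.g. zero residuals) resolve to the
  smallest candidate $\lambda$, deterministically. Noiseless data are
  detected by a scaled RSS threshold ($RSS \le 10^{-20}\max(1,\|y\|^2)$ at
  $\lambda = 0$) and reported with `degenerate = TRUE`, $\hat\lambda = 0$.
* Isometry verdicts use a $10^{-8}$ guard band around the CI so that
  zero-width degenerate intervals are not misclassified by float
  round-off.
* Collinear whitened designs are rejected with a condition-number
  diagnostic; non-positive-definite $V$ is rejected at the Cholesky.
* Medians over an even number of muscles are the midpoint of the central
  pair (the conventional choice).
* $g = 9.81$ m s$^{-2}$; all constants are overridable via
  `limb_constants()`.
* Taxon matching is exact after underscore/whitespace normalisation;
  species substitutions belong in the caller's configuration, never in
  fuzzy matching.

## Design choices where the design was open

* Mean $F^*_{max}$ is computed as mean PCSA passed through the
  body-weight normalisation; with a common body mass this is identical to
  averaging per-muscle $F^*_{max}$.
* The muscle-table CSV dialect repeats `body_mass` on every row
  (validated consistent within species) rather than carrying separate
  body-mass rows; mass-only records are rows with missing architecture
  fields and participate only in the total-mass comparison (skipped with
  a notice elsewhere).
* Degrees of freedom in ANCOVA output are reported as the explicit
  $(df_1, df_2)$ pair of the nested comparison; published tables in this
  area sometimes print ambiguous df values, so the convention here is
  stated rather than reverse-engineered.
* No REML option: $\lambda$ and coefficients are ML, with unbiased-variance
  inference on top — the common pGLS practice; REML is a possible
  extension point.
* The analysis functions are deterministic; randomness exists only in the
  generator, which is fully seed-driven.

## Problem sizes used by the test suite

Unit and property tests run on trees of 6–50 tips; estimator-calibration
simulations use $n = 150$–200 species with 10–50 replicates (slope
recovery, $\lambda$ classification, CI coverage), 200 replicates for the
pANCOVA type-I error under a shared-line $\lambda = 1$ null, 1000
replicates for the ordinary-ANCOVA size under an OLS null, and 12,000
Monte-Carlo draws for the residual-covariance check on a 6-tip tree. These
sizes were chosen so each check has enough resolution for its stated
tolerance while the whole suite stays quick to run.

## Known limitations

* Only bivariate allometries are modelled; no multivariate or
  Ornstein–Uhlenbeck alternatives.
* Prediction assumes the new taxon is phylogenetically independent of the
  training sample — appropriate for distant extinct taxa, conservative
  otherwise.
* %PE is in-sample; cross-validated error would be modestly larger.
* Non-ultrametric trees are accepted with a warning ($\lambda$ scaling
  remains defined), but the diagonal of $V$ then differs across species
  and the $\lambda = 0$ path becomes weighted, not ordinary, least
  squares.
```{r example}
d <- isometric_fixture(20, seed = 1)
agg <- aggregate_limbs(d$muscles)
xy <- comparison_xy(agg[agg$limb == "hind", ], "mass_v_body")
fit <- pgls(y ~ x, data = xy, tree = d$tree)
coef(fit)
```
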