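---
title: "Threshold random regression for litter size across parities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Threshold random regression for litter size across parities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(litterRRM)
```

## The model

Litter size in sheep is a small ordered count recorded repeatedly over a
ewe's reproductive life. `litterRRM` treats it as a *threshold trait*: an
unobserved Gaussian liability determines the observed category (1, 2, >2
lambs in a prolific population; 1 vs >1 in a low-prolificacy one) through
fixed cutpoints. The liability of ewe $l$ at parity $t$ is modelled as a
random-regression animal model on a normalized Legendre basis:

$$
y_{ijlt} = YL_i + ML_j + \sum_{k=0}^{2}\beta_k \phi_k(x_t)
          + \sum_{k=0}^{2}\alpha_{lk} \phi_k(x_t)
          + \sum_{k=0}^{2}\mu_{lk} \phi_k(x_t) + e_{ijlt},
$$

where $YL$ and $ML$ are year- and month-of-lambing effects,
$\phi_k(x) = \sqrt{(2k+1)/2}\,P_k(x)$ are normalized Legendre polynomials
evaluated at the standardized parity
$x_t = -1 + 2(t - 1)/5 \in [-1, 1]$ (parities beyond 6 are collapsed to 6),
$\alpha_l \sim \mathrm{MVN}(0, G)$ with $\mathrm{var}(\alpha) = A \otimes G$
over the pedigree relationship matrix $A$, $\mu_l \sim \mathrm{MVN}(0, P)$
per recorded ewe, and $e$ has a parity-class-specific residual variance
(three classes per line). Variance components are estimated by Gibbs
sampling with liability augmentation, and the per-parity genetic parameters
follow from the usual random-regression expressions

$$
\sigma^2_a(t) = \phi_t' G \phi_t,\qquad
r_g(t,s) = \frac{\phi_t' G \phi_s}
                {\sqrt{(\phi_t' G \phi_t)(\phi_s' G \phi_s)}},\qquad
h^2(t) = \frac{\sigma^2_a(t)}{\sigma^2_a(t)+\sigma^2_p(t)+\sigma^2_e(t)},
$$

computed *per posterior draw* and then summarized (posterior mean, 95% HPD
interval, exceedance probability $P(h^2 > 0.10)$, and the lower limit $k$
with 95% posterior mass above it). Summaries of derived quantities are
never computed by plugging in posterior means.

## Identifiability

A threshold model has no intrinsic location or scale, so some coordinates
must be anchored. The package fixes:

* the first threshold $\tau_1 = 0$ (always), and drops the reference month
  dummy from the fixed effects; all year levels are kept, which mirrors
  how such models are usually run — the resulting flat direction between
  the year block and the constant regression column affects only the
  (unreported) fixed effects, not liabilities or variance components;
* with **three categories**, the second threshold $\tau_2 = 1$, which pins
  the liability scale everywhere; all three residual-class variances are
  then estimable and free;
* with **two categories**, *every* residual-class variance at 1.0. A binary
  likelihood depends on $\eta/\sigma$ only, so per-class residual scales
  are not usable as free parameters: leaving them free creates a flat
  ridge along which a Gibbs chain random-walks without bound (we observed
  residual draws drifting by two orders of magnitude, dragging the
  coefficient covariances along, at both balanced and low incidence).
  With the scales anchored, parity heterogeneity is still expressed — by
  the genetic and permanent-environment variance trajectories.

The repeatability model is the degenerate configuration: a single raw
constant covariate (not $\phi_0$) per random effect and a single residual
class, so $h^2$ is parity-constant and $r_g \equiv 1$ by construction.

## Sampler

One iteration sweeps, in order: liabilities (inverse-CDF truncated-normal
draws — no rejection loops, so extreme tails are safe), year and month
effects (jointly per block; the records of different levels are disjoint),
fixed-regression coefficients (single site), additive-genetic coefficients
of animals without records (blocked per animal, using the sparse
$A^{-1}$ built by Henderson's rules with Meuwissen–Luo inbreeding), and a
*joint* $(\alpha_l, \mu_l)$ block per recorded ewe. The joint block matters:
a ewe's genetic and permanent-environment coefficients are strongly
confounded given her few records, and alternating single-block updates mix
that partition poorly. Covariance matrices are then drawn from their
inverse-Wishart full conditionals and residual classes from scaled
inverse-chi-square conditionals. All randomness uses R's RNG stream, so a
chain is bit-reproducible from its seed and can be checkpointed and
resumed exactly.

Default chain settings mirror a production run (500,000 iterations,
100,000 burn-in, thinning 100, 4,000 retained draws). The examples and
tests use much shorter chains; the parameter-recovery study described
below uses 20,000 iterations with 5,000 burn-in and thinning 10 on
datasets of 400 ewes (~1,200 records), which one fit completes in well
under a minute.

## Priors

Two prior presets are provided:

* `prior = "weak"` (default): inverse-Wishart with df $= q+2$ and scale
  $0.1 I$ for $G$ and $P$; scaled inverse-chi-square with df 4 and scale 1
  for free residual classes. Proper, and essentially data-dominated
  whenever the data are informative.
* `prior = "flat"`: the improper flat priors often used with
  threshold-model Gibbs software (covariances: df $= -(q+1)$, zero scale;
  residuals: df $=-2$).

For low-information binary data the two presets genuinely differ: the weak
prior concentrates the posterior of $G$ near small values (heritability
pulled low), while the flat prior yields broad, honestly diffuse
posteriors. The package's recovery studies on binary data therefore use
`prior = "flat"`; with balanced 3-category data the choice matters little.
Fixed effects get flat priors by default (`fixed_prior_var = Inf`); a
finite value adds a Gaussian ridge, which the test suite uses to make its
small mixed-model-equation oracles nonsingular.

## The synthetic-data generator

No public litter-size records exist for the populations that motivated
this package, so `make_paper_like_scenario()` fabricates datasets with the
same statistical anatomy:

* a family-rotation breeding scheme — seven ram families, one sire per
  family per generation, dams systematically mated into the next family —
  which measurably lowers inbreeding relative to a no-rotation control;
* breeding values propagated down the pedigree with inbreeding-adjusted
  Mendelian-sampling variances (so $\mathrm{cov(vec}\,a) = A \otimes G$);
* order-2 true $G$ and $P$ obtained by projecting per-parity variance
  trajectories of published magnitude onto the basis (a congruence, so
  positive-semidefiniteness is automatic); residual classes and thresholds
  per line; fixed-regression coefficients calibrated so per-parity
  category frequencies match the descriptive statistics of each line
  (~45–60% singles in the prolific line, ~3–8% multiples in the
  conventional one);
* sequential parity retention tuned to give ~2.8–3.0 lambings per ewe and
  declining records per parity, and once-per-year lambing-year effects
  (SD 0.3) with small fixed month effects.

Every dataset is written with a truth file from which each record's
liability reconstructs bitwise (`liability = systematic + residual`), plus
a JSON manifest (seed, sizes, digests) sufficient to regenerate it.

What the generator does *not* emulate: a segregating major prolificacy
gene (the real prolific population carries one); non-random culling;
across-line pedigree links; recording errors. Passing recovery tests on
these data therefore show that the estimator is consistent with its own
model assumptions at realistic sizes — not that real litter-size data meet
those assumptions.

## Numerical choices

* Truncated-normal sampling by CDF inversion with clamping in negligible-
  mass intervals.
* Small per-block systems (up to $2q \le 16$) solved by hand-rolled
  Cholesky on stack arrays; the per-ewe and per-animal loops dominate the
  sweep cost.
* HPD intervals are the shortest contiguous window over sorted draws, ties
  broken toward the lowest left endpoint; the lower credible limit `k` is
  the type-7 empirical quantile (the quantile convention is stated because
  published tables rarely state theirs).
* Effective sample size uses the AR-spectral estimator at frequency zero.
* Model comparison across polynomial orders reports DIC
  ($\bar D + p_D$) as the primary criterion and a plug-in AIC analogue
  (deviance at the posterior-mean linear predictor plus twice the
  dispersion-parameter count) as a labelled secondary, the deviance being
  the ordered-probit likelihood of the observed categories.
* Reported tables round to 2 decimals; machine outputs keep full
  precision.

## Problem sizes used by the automated studies

The packaged parameter-recovery study simulates the 2-category line scaled
to 400 ewes (~1,200 records, ~480 animals) and fits 20,000-iteration
chains across 20 replicates, checking that 95% HPD intervals for $h^2(t)$
cover the generator's truth in at least 70% of replicate-by-parity cells.
The pedigree-algebra oracle checks $A^{-1} A = I$ and Meuwissen–Luo
inbreeding against a brute-force tabular $A$ on random pedigrees of up to
100 animals; sampler components are checked against closed forms
(truncated-normal moments, inverse-Wishart means) and against a direct
sparse mixed-model-equations solve on a 10-record toy.

## Known limitations

* Single-chain inference only; no Gelman–Rubin diagnostics (use several
  seeds if you need them).
* Binary (2-category) data carry little information about variance
  partitions at realistic sizes; expect wide HPDs, prior sensitivity, and
  slow mixing of the genetic/permanent-environment split even with the
  joint per-ewe blocks.
* No genetic groups, genomic relationships, or multi-line joint fits.
* The AIC analogue is a heuristic; order selection should lean on DIC and
  on stability of the fitted trajectories.
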