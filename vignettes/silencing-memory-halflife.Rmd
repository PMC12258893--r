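---
title: "Estimating the half-life of transgenerational RNAi silencing memory"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the half-life of transgenerational RNAi silencing memory}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

## The assay and the quantity of interest

In *C. elegans*, feeding animals bacteria that express double-stranded RNA
against a germline GFP transgene silences the transgene, and the silenced
state is inherited for several generations after the trigger is removed.
The assay that `rnaimem` analyses scores, at every generation after trigger
removal, ~100 individuals per replicate into OFF, DIM and ON fluorescence
categories.  OFF and DIM are grouped as GFP-negative — DIM animals are
considered to still inherit the silencing signal — so the per-time-point
statistic is the percent of fully ON (desilenced) individuals.

Generation indexing anchors at trigger removal: G0 is the last generation
exposed to the RNAi trigger (fully silenced), G1 the first trigger-free
generation.  Rows at G-1 (the first trigger generation) may be present in
a scoring table but are ignored by the analysis.

The central statistic is the **half-life of silencing memory**: the
interpolated generation (or day) at which 50% of scored individuals are
GFP-positive.  For each replicate series we select the two scoring points
closest below and closest at-or-above the 50% line and solve the line
through them for the 50% crossing:

\[
\hat{t}_{1/2} = x_b + (50 - v_b)\,\frac{x_a - x_b}{v_a - v_b}.
\]

Three conventions make this estimator total and deterministic:

* **Threshold ties.**  A point exactly at 50% is its own "above" point and
  the half-life equals its coordinate (continuity from above).  Equally
  close candidate points resolve toward the crossing — the latest below
  point and the earliest above point — which on a monotone series yields
  the adjacent crossing pair.
* **Oscillation smoothing.**  When the series crosses the threshold more
  than once (or the closest pair is misordered), the bracket is widened:
  the above point is the first point from which the series stays
  at-or-above 50%, the below point the last sub-threshold point before
  it.  The estimate is flagged `smoothing = TRUE`.
* **Left anchoring and right censoring.**  A series already above 50% at
  its first scored point is interpolated against full silencing at G0
  (0% at coordinate 0); an observed G0 row, when present, takes precedence
  over the assumption.  A series that never reaches — or does not end
  at-or-above — 50% is right-censored: it carries no value, is excluded
  from model fitting and is reported separately.  No extrapolation beyond
  the scored grid is performed.

### Why tie-breaks matter

A natural invariant of a desilencing half-life is *monotone dominance*: a
series that is pointwise more desilenced should never yield a longer
half-life.  That invariant holds for monotone series under the
toward-the-crossing tie-break, and it is one reason we adopted it:
breaking ties toward the first scored point instead violates dominance on
plateaus (two equal sub-threshold values).  For non-monotone series the
closest-pair rule can violate dominance regardless of tie-break — raising
a late point can move the "closest above" point to a later generation —
so the property is asserted (and tested) only on monotone series, the
regime actual desilencing trajectories occupy.

## The generation schedule and the day axis

Half-lives can be expressed in generations or in days.  A
`generation_schedule()` assigns each temperature a base generation time
(defaults: 3.5 d at 20 °C, 2.5 d at 25 °C — configurable; only relative
and arrest arithmetic is asserted by tests, since generation times vary
with conditions) and inserts developmental arrests at given generations:
a 6-day L1 starvation arrest at G1, or a dauer diapause (default +5 days;
reported induction protocols vary between roughly 3 and 7 days, so the
duration is a free schedule parameter).  An arrest at generation *g* adds
its extra days to the day coordinate of every generation ≥ *g* and leaves
the generation axis untouched — which is exactly how diapause can shorten
memory in generations while lengthening it in days.

## The comparison model

Half-life values are positive and block/replicate variation acts
multiplicatively, so strains and environments are compared with a Gamma
generalized linear mixed model with log link:

\[
\log \mu_{ijk} = X\beta, \qquad
\mathrm{Value}_{ijk} \sim \Gamma(\nu, \nu/\mu_{ijk}),
\]

with random intercepts for block ($\sigma^2_B$) and replicate nested in
block ($\sigma^2_R$) added to the linear predictor.  The fixed part is
`strain` for genetic comparisons, or `strain * environment` for
environmental ones.  Fitting is maximum likelihood with a Laplace
approximation (the `glmmTMB` engine).  Numerical conventions:

* Reference coding with the alphabetically first level as baseline;
  contrasts are coding-invariant.
* Single-block data drop the block intercept automatically.
* Strains observed in only one block are excluded from strain-effect fits
  by default (their strain effect is confounded with the block), with
  `include_singleton_strains = TRUE` as an override.
* Test statistics use the asymptotic normal/chi-square reference.  There
  is no agreed finite-sample degrees-of-freedom recipe for this model
  class; this is a documented limitation, and omnibus tests are available
  both as Wald (default) and likelihood-ratio versions.
* The Gaussian identity-link family is available for sensitivity checks
  (environmental comparisons are sometimes run that way); the Gamma log
  link is the package default for both model forms, and the family used
  is recorded in the fit object and the run manifest.
* Exactly constant responses make the Gamma shape likelihood unbounded;
  such fits honestly report `converged = FALSE`.

Marginal means are computed on the link scale by averaging cell
predictions with equal weights over the levels of the other fixed factor;
their differences are log ratios of half-lives.  Pairwise contrasts carry
a **single-step family-wise adjusted p**: the probability that the maximum
absolute standardized contrast in the family exceeds the observed one,
obtained by quasi-Monte-Carlo multivariate-normal integration under the
estimated contrast correlation (fixed internal seed, accuracy ~1e-5, so
reported p-values are deterministic for practical purposes).  With a
conditioning factor (`by = "strain"`), each stratum's pairs form their own
family.  A family of one contrast is returned unadjusted.

Model adequacy is checked with simulation-based randomized quantile
residuals: responses are re-simulated from the fitted model (re-drawing
the random intercepts), each observation's scaled residual is its
tie-randomized quantile position among its simulations, and uniformity is
tested by Kolmogorov–Smirnov alongside a simulated dispersion ratio.  At
least 20 simulations are required; the default is 250.

## What the synthetic generator emulates

`simulation_design()` emulates the study design so that every stage is
testable without laboratory data: lettered blocks (default 4, lettered
C–F), 3 replicates per strain per block, ~100 scored individuals per time
point, scoring at generations 1–8, and a fully silenced G0 (an optional
`g0_leak` emulates partially refractory strains).  Desilencing follows a
logistic curve in generation index,
$p_{\mathrm{ON}}(g) = 1/(1+e^{-k(g-H)})$ — a monotone sigmoid matching
observed recovery shapes, whose latent parameter $H$ is identified with
the 50% crossing.  The default slope $k = 1.5$/generation produces
recovery over roughly 3–4 generations, as observed for the reference
strain; default half-lives $\{0.7, 1.5, 3.0, 5.5\}$ generations span a
non-transmitting isolate to a long-memory isolate.  Block and replicate
intercepts (defaults $\sigma_B = 0.15$, $\sigma_R = 0.10$) act additively
on $\log H$ — the same scale the analysis model assumes — and are shared
across strains and environments within a block, as in the real design.
Counts are drawn binomially ($n_{\mathrm{ON}}$, then DIM among the
remainder with constant probability $\delta = 0.2$; DIM kinetics are not
modelled).  Random streams split hierarchically by group key, so editing
one arm of a design never perturbs another arm's draws.

Features of real data deliberately *not* modelled: extra-binomial scoring
dispersion, selection/mortality (mortal-germline phenotypes), DIM
kinetics, and within-generation dynamics.  Passing recovery tests on
synthetic data therefore demonstrates correctness of the estimation
machinery under the stated generative assumptions, not robustness to
these unmodelled features.

## What "parameter recovery" targets

The chord through two scoring points is not the logistic curve, so the
population value of the half-life statistic differs slightly from the
latent $H$ — most visibly for a left-anchored short-memory strain
($H = 0.7$: the chord from (G0, 0%) to (G1, ~61%) crosses 50% near 0.82).
This chord-versus-curve offset is a property of the *estimand* the
procedure defines, not an estimation error, and it is bounded by the
bracket width.  Recovery and coverage studies in the test suite therefore
measure the model's pairwise log-ratio estimates against the population
value of the statistic under the full generative design (computed by a
brute-force Monte-Carlo oracle, conditional on a replicate being
estimable), which is the quantity the fitted intervals actually estimate.

## Problem sizes and numerical tolerances

The test suite exercises the half-life estimator against an
exhaustive-search oracle on 1,000 random noisy trajectories (bit-equal
agreement), enumerates all threshold sign patterns up to length 6 for the
smoothing rule, checks the GLM limit of the mixed model (variances pinned
at zero) against `stats::glm` to 1e-6 relative on 50 tables, and runs
recovery (100 experiments), type-I error (500 null experiments), CI
coverage, Tukey-adjustment (±0.005 against a 200,000-draw max-statistic
simulation) and residual-calibration (100 trials) studies at the default
design.  These sizes were chosen to keep Monte-Carlo error comfortably
inside each assertion band.

## Limitations

* **Finite-sample calibration.**  With the asymptotic normal reference and
  a design of a few dozen half-life values in a dozen replicate groups,
  omnibus Wald tests are mildly anticonservative and contrast intervals
  somewhat narrow; the package's own simulation studies (in the test
  suite) quantify this at the default design.  A second contributor is
  heteroscedasticity: the relative noise of an interpolated half-life is
  larger for fast, left-anchored desilencers than for strains bracketed
  between well-separated scoring points, while the Gamma family assumes a
  constant coefficient of variation.  Strongly significant contrasts are
  unaffected in practice; p-values near the significance boundary should
  be read with this in mind.  Finite-sample df corrections
  (Kenward–Roger/Satterthwaite style) are deliberately out of scope.
* No parametric curve fitting: the half-life is deliberately the paper-style
  interpolated crossing, not a logistic regression estimate; no
  uncertainty is attached to a single replicate's half-life.
* Censored replicates are excluded from models rather than modelled
  (no survival-style likelihood contribution).
* Random effects are nested intercepts only — no crossed effects, random
  slopes, REML, or finite-sample df corrections.
* Day-axis arithmetic treats generation time as constant per temperature
  between arrests.
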