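---
title: "Roaming entropy, curiosity and cognitive-map precision: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Roaming entropy, curiosity and cognitive-map precision: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its models and the design
choices behind them. It covers the roaming-entropy statistics, the
hierarchical Bayesian model battery, the sketch-map scoring layer, and —
because everything here must be testable without human data — the
synthetic-cohort generator and exactly what passing its tests does and
does not establish about real data.

## The scientific setting

In free-exploration experiments, participants walk through a series of
novel virtual rooms (16 m × 16 m), rate their anticipatory curiosity
(1–10) before entering each room and the room's interestingness (1–10)
after leaving it, and later draw sketch maps of the rooms from memory.
Position and head direction are logged at 60 Hz while walking speed is
fixed at 3.4 m/s. The questions the package's model battery addresses:

1. Do trial-to-trial fluctuations in curiosity predict *spatial*
   exploration, and fluctuations in interest predict *visual*
   exploration (a double dissociation)?
2. Do curiosity traits — particularly Stress Tolerance — moderate the
   curiosity–exploration link?
3. Do curiosity and spatial exploration predict the precision of the
   cognitive map, and is the curiosity effect mediated by exploration?

## Roaming entropy

Exploration is summarised per trial by *roaming entropy* (RE): the
Shannon entropy of the empirical occupancy distribution over a discrete
bin space, normalised to [0, 1],

$$\mathrm{RE} = -\sum_j \frac{p_j \log_2 p_j}{\log_2 k},$$

where $p_j$ is the fraction of the trial's samples falling in bin $j$
and $k$ is the number of available bins. RE is 0 when the agent never
leaves one bin and 1 when its time is spread uniformly over all $k$
bins.

*Path RE* uses the room's 32 × 32 grid of 0.5 m cells, restricted to
the cells not occluded by furniture; $k$ is the room's accessible-cell
count (1024 for an empty room). *Head-direction RE* uses an 18 × 36
grid of 10° × 10° bins over pitch (−90°…90°, egocentric) and yaw
(−180°…180°, relative to the room's entry direction); $k = 648$ always,
regardless of which bins are visited, because the bin space — not the
visited set — defines the normaliser.

Numerical conventions, chosen once and enforced by tests:

- Cells are half-open; a coordinate exactly on the far wall (or pitch
  exactly +90°) is clamped into the last bin rather than dropped.
- Samples landing in occluded cells are dropped and counted, never
  snapped to the nearest accessible cell: the simulator cannot produce
  them, so on real data they indicate logging glitches that should not
  silently distort occupancy.
- A degenerate one-cell room returns RE = 0 ($\log_2 1$ guard).
- Every 60 Hz sample counts equally, so occupancy mass is dwell time;
  there is no temporal weighting or kernel smoothing.
- One RE value summarises the whole trial; `re_over_time()` provides a
  cumulative variant for plots but no reported analysis uses it.

## The model battery

All models are Bayesian multilevel regressions sharing one centring
scheme, built by `build_design()`: each trial-level predictor $x_{it}$
is split into a within-person deviation $x_{it} - \bar x_i$ (isolating
intra-individual dynamics) and a person mean $\bar x_i$ centred at the
grand mean (carrying inter-individual differences). Duration in seconds
enters grand-centred as a covariate. Adding a constant to any predictor
therefore changes nothing — a property the tests check.

The four analyses:

- **Exploration model** — a bivariate multilevel regression with
  (path RE, head RE) as joint outcomes; fixed effects are the
  within-person curiosity and interest deviations, their person means
  and duration, per outcome; participants contribute random intercepts
  and (by default) random slopes for the within-person predictors; the
  two outcomes' trial-level residuals are correlated, with the residual
  correlation a reported parameter. Cross-outcome contrasts (e.g. the
  curiosity weight on path RE minus the curiosity weight on head RE)
  are computed draw-wise.
- **Trait moderation** — path RE only, adding the four grand-centred
  5DCR subscales (Joyous Exploration, Deprivation Sensitivity, Stress
  Tolerance, Thrill Seeking) and their interactions with the
  within-person curiosity deviation.
- **Cognitive-map model** — the composite sketch score regressed on
  within/between terms of curiosity, interest, path RE and head RE,
  plus duration.
- **Mediation** — mediator (within-person path RE on curiosity) and
  outcome (composite on curiosity and path RE) submodels fitted
  *jointly* in one MCMC run, so the indirect effect is the draw-wise
  product $a \cdot b$ over the joint posterior — not the product of
  posterior means, a distinction that matters for skewed posteriors and
  that the tests assert.

### Priors, sampling and summaries

Coefficients get normal(0, 1) priors (intercepts normal(0, 5); scales
configurable through `prior_settings()`) — effectively weakly
informative on the scales involved, where rating effects on
unit-interval RE are of order 10⁻³–10⁻². Residual and random-effect
SDs get uniform(0, 2) priors and the residual correlation
uniform(−1, 1).

Sampling uses JAGS with a hierarchically centred parameterisation:
participant intercepts are drawn around the person-level regression on
the person-mean predictors, which removes the strong posterior coupling
between random intercepts and between-person coefficients and roughly
triples the effective sample size per iteration in our fits. The
`"full"` preset runs 4 chains × 4800 iterations (half warm-up), the
budget used for the headline analyses; `"reduced"` (2 × 2250, used
by the bundled analyses and the acceptance script) and `"test"` give
the same posteriors to within Monte-Carlo error on the problem sizes
here, at a fraction of the cost. Every fit reports split-$\hat R$ and
effective sample size per parameter and warns when structural
parameters miss $\hat R \le 1.01$ or ESS ≥ 400.

Posteriors are summarised by the mean and the 93% highest posterior
density interval — the shortest window containing ⌈0.93 n⌉ sorted
draws, by exhaustive scan. The 93% level is a summary convention, not a
test threshold. Our implementation is cross-checked in the tests
against an exhaustive-window oracle and against `coda::HPDinterval`
(which rounds instead of ceilings the window size; the two agree to the
local draw spacing).

### Random-effect structure

The default is participant random intercepts plus independent random
slopes for each within-person predictor (`random = "slopes"`), with an
intercept-only fallback. We deliberately use *independent* (diagonal)
random-effect components rather than a full correlation matrix across
intercepts and slopes: with ≤ 60 participants the correlation
parameters are weakly identified, they slow Gibbs mixing considerably,
and none of the reported quantities depend on them. This mirrors the
`(x || id)` form familiar from multilevel software.

## Sketch-map scoring

Each map is scored by two raters on four 1–5 dimensions in 0.5 steps:
Object Presence, Spatial Distortion and Rotation of features, Relative
Positioning, and Spatial Proportion. The composite precision score
averages raters within dimension, then dimensions. Reliability is
reported both as a Pearson correlation and as a two-way consistency
intraclass coefficient, ICC(C,1), across participant × room units —
the rubric itself does not pin down which coefficient a given study
reports, so both are labelled explicitly and the ICC is the default.

Internal consistency of the four dimensions is Cronbach's alpha,
$\alpha = \frac{k}{k-1}\bigl(1 - \sum_j s_j^2 / s_\text{total}^2\bigr)$
with $k = 4$, on rater-averaged scores. Its uncertainty is a
nonparametric bootstrap over units, reported as a 93% percentile
interval to parallel the model summaries. A fully Bayesian alpha would
need a measurement model that the rest of the package does not
otherwise require; the bootstrap keeps the scoring layer
dependency-free while providing an interval of comparable meaning.

## The synthetic-data generator

The generator is first-class, tested code; it defines the conditions
under which every downstream stage is validated. It emulates:

- 16 m × 16 m rooms with furniture-like rectangular occlusions
  (rejection-sampled so the accessible region stays 4-connected and the
  entry stays free);
- per-participant trait scores (four correlated subscales on 1–7) and
  mean rating levels; per-trial bivariate-normal latent (curiosity
  drive, interest level) with correlation 0.4, discretised to 1–10
  ratings by rounding and clipping — the simplest monotone link;
- log-normal dwell times with mean 33.1 s and SD 22.8 s, clipped to
  8–120 s — the spread reported for free exploration of such rooms;
- trial-level path/head RE drawn from a linear bivariate ground-truth
  model (participant intercepts, participant slope deviations,
  correlated trial residuals), with two-rater sketch scores depending
  linearly on the curiosity rating and realised path RE plus
  participant effects, dimension-specific noise and per-rater noise
  rounded to the 0.5 grid.

Ground-truth effect sizes default to the order of magnitude such
studies report: curiosity → path RE 0.006 per rating point and
interest → head RE 0.005 on unit-interval RE, residual correlation
0.3, Stress-Tolerance moderation 0.004 per trait point, map-score
effects 0.066 per rating point and 0.8 per unit path RE, and rater
noise (SD 0.32 before rounding) chosen so the inter-rater ICC falls in
the low 0.7s and alpha near 0.93. The behavioural drive that shapes a
trial is the *observed* rating, not the underlying latent: the models
use the rating as predictor, and generating outcomes from the latent
would build errors-in-variables attenuation into the ground truth,
making "recovery" systematically unattainable at any sample size.

### Two trajectory engines

`simulate_trajectory()` is a mechanistic agent: a correlated random
walk at fixed speed, confined to accessible cells, that re-chooses its
heading every 0.1 s among candidates weighted by persistence, by
avoidance of already-visited cells (weight rising with drive) and by
attraction back to the entry (for low drive), with pause probability
falling in drive. It produces the qualitative signature the RE
statistic is meant to capture — high-drive agents strictly out-roam
low-drive agents on matched seeds — and is what the monotonicity checks
exercise.

`generate_cohort()` instead synthesises each trial's trajectory to
*realise* the RE values drawn from the linear ground-truth model: a
random connected region of the accessible grid is grown from the entry,
a randomised depth-first walk traverses it cell-centre to cell-centre
at walking speed (9 samples per 0.5 m move, so the per-sample step
stays under the 3.4 m/s limit), and an integer occupancy-count solver
(water-filled ↔ concentrated interpolation plus single-sample
refinement, tolerance 5 × 10⁻⁴ bits) allocates dwell so the realised
entropy matches the drawn target; head direction is built the same way
on the 18 × 36 bin grid. Binning the emitted samples reproduces the
constructed histogram exactly, so the analysis-side RE equals the
generator-side RE to ~10⁻⁴ and every model coefficient has an exactly
known ground truth — including the residual correlation, which an
agent-only generator could not define. The price is a kinematic
ceiling: a short trial cannot realise a very high path RE (covering
$m$ cells costs about $9m$ samples of transit), so extreme
target/duration combinations are clipped to the feasible range. At the
default settings this touches ~1% of trials and is, if anything,
realistic — at 3.4 m/s you genuinely cannot cover half a room in
eight seconds.

All noise is drawn before any coefficient is applied, so two
configurations differing only in an effect size share identical noise
realisations — this is what makes the monotone-link property (raising
the drive–coverage coupling never lowers the recovered slope) exactly
testable.

### What passing tests shows — and does not

The generator produces linear-Gaussian outcomes on the RE scale,
perfectly matched model structure, and missingness-free logs. Passing
recovery and calibration tests therefore shows that the statistics,
centring, samplers and estimands are implemented correctly — not that
the model is well-specified for human exploration data, where RE is
bounded, residuals may be skewed, ratings are used ordinally, and
trial-order effects exist. Those are questions for the real data, which
the package reads through the same I/O layer.

## Problem sizes used by the bundled checks

The bundled analyses and acceptance checks run the full battery on one
60 × 16 cohort with the `"reduced"` sampler, drive-monotonicity
comparisons on 100 matched trajectory pairs, and null-generator
calibration (all rating, duration and trait effects zero) on 20
replicate cohorts of 12 × 8 with the `"test"` sampler, checking that
~93% of 93% HPDIs cover zero (80–100% tolerated at 20 replicates).
These sizes give posterior SDs small enough that sign errors or scale
errors in any coefficient would be detected, while the whole battery
completes in minutes.

## Known limitations

- Reported RE defaults to the 0–1 scale; a ×100 percentage view is a
  switch (`as_percent`), and coefficient magnitudes scale accordingly.
- The mediation estimand is the simplest within-person
  product-of-coefficients; no moderated or multi-mediator paths.
- No model comparison or leave-one-out machinery; sensitivity analysis
  is limited to prior-scale and random-structure switches.
- The sketch-scoring layer treats the human rubric as given; it does
  not process drawings.
- Ratings are modelled as continuous predictors and RE as a Gaussian
  outcome — adequate in the interior of their ranges, questionable at
  the bounds.
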