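---
title: "Normative centile modelling for the FLI-P: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normative centile modelling for the FLI-P: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flipnorms)
```

## The measurement problem

The Functional Listening Index--Paediatric (FLI-P) is a 64-item parent-report
checklist of listening skills for children aged 0--72 months. Items are
ordered developmentally across six hierarchical areas, from sound awareness
to advanced open-set listening; each is rated "mostly" (the child
demonstrates the skill regularly, across places and people) or "rarely"
(occasionally, a few times, or not at all). A child's score is the count of
"mostly" ratings, 0--64. Because listening skill precedes spoken language,
tracking a child's FLI-P trajectory against typically hearing peers gives
clinicians and families early, frequent evidence about whether intervention
(device fitting, implantation, medical management) is keeping development on
course.

The package implements the full analysis chain around this instrument:
scoring with the basal/ceiling administration rules, a normative centile
model of score against age, refitting machinery for new cohorts, a Monte
Carlo procedure for judging how large a normative sample must be, a
synthetic-cohort generator, and descriptive comparison of individual
trajectories against the normative envelope.

## Scoring rules

`score_assessment()` counts "mostly" responses. Two administration rules are
tracked but deliberately given no arithmetic role:

* **Ceiling** -- scoring stops once a run of consecutive "rarely" responses
  occurs. The published description does not fix the run length; the package
  defaults to 4 consecutive "rarely" responses, mirroring the four-item
  basal window, and exposes `run_length` so services that administer the
  checklist with a different convention can match it.
* **Basal** -- the four highest-indexed "mostly" items, re-checked between
  administrations for regression. It is reported, never scored.

"Mostly" responses above the ceiling and unanswered items below it are
counted according to the plain definition of the score (only explicit
"mostly" counts) and surfaced as warnings rather than errors, since both
occur in real administrations and the analyst, not the scorer, should decide
what to do with them.

## The centile model

Score against age is modelled per centile by a four-parameter logistic
curve,

$$f(x) = a_1 + \frac{a_2 - a_1}{1 + e^{-a_3 (x - a_4)}},$$

with $x$ age in months, $a_1/a_2$ the lower/upper asymptotes in score
points, $a_3$ the growth rate per month and $a_4$ the inflection age in
months. The sigmoid shape matches the data's fast early skill acquisition
(most skills before 30 months) and flattening thereafter; $a_2$ is the
ceiling the curve approaches and can never exceed the instrument maximum of
64.

`load_reference_table()` packages the normative study's published parameter
estimates for the 5th, 10th, 16th, 50th, 84th, 90th and 95th centiles as
the default norm. The 16th and 84th levels are included because under a
normal distribution they sit closest to one standard deviation below and
above the median, so the 16th--84th band reads as the "&plusmn;1 SD"
envelope. Values are stored as plain 4-decimal JSON and loaded exactly.

Three reporting conventions follow the study's recommendations:

* Centile values are reported clamped to $[0, 64]$ (the 5th-centile curve
  is negative below roughly one month of age, where the instrument cannot
  score below zero); unclamped values remain accessible for fitting.
* Ages are continuous decimal months, never rounded.
* Norms are reported from a minimum age of 3 months -- very few children
  under 3 months could be observed, since newborn hearing screening
  precedes enrolment -- but queries below it compute and carry a
  `below_min_age` flag rather than erroring.

Centiles fitted independently can in principle cross;
`check_non_crossing()` verifies coherence of a table on an age grid
(non-decreasing in level at every age, tolerance $10^{-9}$) and reports
violations without re-ordering curves, since any repair would amount to a
different estimator than the one published.

### Score to centile

`score_to_percentile()` inverts the family at a given age by interpolating
in normal-score space: level $\tau$ is placed at $\Phi^{-1}(\tau)$ and the
observed score is located by piecewise-linear interpolation of curve values
against these normal scores. Linear-in-$z$ rather than linear-in-$\tau$
behaves sensibly in the tails and is the construction consistent with
reading the 16th/84th centiles as &plusmn;1 SD. Scores outside the fitted
5th--95th range return the boundary level with an `outside_fitted_range`
flag -- the model deliberately does not manufacture extreme centiles it
never estimated.

## Refitting: nonlinear quantile regression

`fit_quantile_curve()` estimates a centile curve from cohort records by
direct minimisation of the check (pinball) loss
$\sum_i r_i(\tau - \mathbf{1}[r_i < 0])$, the defining objective of
quantile regression, with the four-parameter logistic as the regression
function. Design choices:

* **Optimiser.** The loss is non-smooth in the parameters, so a
  derivative-free simplex (Nelder--Mead) search is used, multi-started from
  16 deterministic jittered starts around a moment-based guess ($a_2$ from
  the maximum score, $a_1$ from the minimum, $a_4$ at the age where the
  score passes half-range, $a_3$ from the global slope via the identity
  that the maximal 4PL slope is $a_3(a_2-a_1)/4$). Starts are jittered with
  SD 0.5 in the transformed space under a caller-supplied seed, making fits
  bit-reproducible.
* **Bounds.** The search runs in a logit-transformed space of the box
  $a_1 \in [-40, 30]$, $a_2 \in (a_1 + 1, 64]$, $a_3 \in (0, 1]$,
  $a_4 \in [1, 60]$, so constraints (including $a_2 \le 64$, visibly active
  in the published 84th/90th/95th rows, which all print $a_2 = 64.0000$)
  are structural rather than penalised.
* **Convergence.** Each start runs to relative tolerance $10^{-10}$ or
  2000 simplex iterations; the best start wins. `brute_force_fit()`
  provides an independent grid-search oracle (ties broken in enumeration
  order $a_1, a_2, a_3, a_4$ ascending) used by the test-suite to confirm
  the optimiser never returns a loss above the best grid point.
* Records below 3 months are included in fitting; the 3-month rule governs
  reporting, not estimation. Centiles are fitted independently per level
  (`fit_all_percentiles()`), and the resulting table carries a
  non-crossing report.

No standard errors are produced: the published norms carry none, and the
bootstrap a practitioner would want here is a study-design question outside
this package's scope.

## Synthetic cohorts

The normative dataset itself is under commercial arrangement, so the
package ships a generator rather than data. `quantile_function()` turns the
seven packaged centile curves into a full conditional law of score given
age: curve values at the age are interpolated against $\Phi^{-1}(\tau)$ as
above, extrapolated linearly in normal-score space beyond the 5th/95th
levels from the outermost segment, and clamped to $[0, 64]$.
`generate_cohort()` then emulates the study's cross-sectional design: ages
uniform within each 6-month recruitment block (twelve blocks over 0--72
months), one latent uniform rank per child, scores through the conditional
quantile function. Two block designs are packaged: the minimum-recruitment
design (36 children per block, 432 total) and the achieved per-block counts
of the normative study. The study's youngest participant was 1.5 months, so
the generator's minimum child age defaults to 1.5 months. The achieved
per-block counts as published sum to 526 although the published row total
prints 536 and the study text reports 561 records overall; the packaged
design carries the per-block counts as printed, and this discrepancy is
inherent to the source, not to the package.

Continuous scores are the default because estimation experiments should not
carry rounding bias; `rounding = "integer"` matches the instrument's actual
output. What the generator does **not** emulate: item-level response
patterns, repeated measurements of the same child within a cross-sectional
cohort, enrolment-site effects, bilingual-exposure covariates, or any
hearing-loss population. Passing recovery tests on these cohorts therefore
demonstrates correctness of the estimation machinery under the normative
model, not robustness to real-data artefacts.

`generate_longitudinal_child()` adds the two variability components used in
sample-size reasoning: a child-specific rate multiplier
$r \sim \text{LogNormal}(0, \sigma_b)$ acting on effective age (a literal
"variation between children in the rate of increase"), and independent
$N(0, \sigma_w)$ assessment noise. No values for $\sigma_b, \sigma_w$ were
published; the defaults $\sigma_b = 0.15$ (children one SD fast/slow develop
about 15% ahead/behind their age) and $\sigma_w = 2$ score points (about
the test-retest wobble a 64-item two-level checklist plausibly shows) are
documented choices used only where the source is silent, and both are
plain arguments.

## Monte Carlo sample-size machinery

The normative study sized itself so that the estimated median curve would
err by no more than 2 score points at every age 1, 2, ..., 72 months with
probability at least 90%. `replicate_max_error()` reproduces one replicate
of that machinery: simulate a cohort, refit the median centile, record the
maximum absolute error against the generating median over integer ages
1--72. `estimate_probability()` estimates the probability as the proportion
of replicates meeting the bound (with binomial standard error), counting
failed fits as exceedances (conservative) and reporting them;
`find_min_sample_size()` scans candidate sizes for the smallest meeting a
target probability.

Replicates default to the cross-sectional generator -- cross-sectional data
is what the centile fits consume -- with the longitudinal two-component
model available via `generator = "longitudinal"`. Evaluation uses ages
1--72 exactly as the criterion states, even though reporting elsewhere
starts at 3 months. That choice has a visible cost: ages 1--2 months lie
below the youngest generatable child (1.5 months), so the error there is
pure extrapolation. At the achieved study size, 200-replicate runs estimate
the probability at roughly 0.83--0.92 depending on seed (about 0.88 on
average, standard error ~2 points per run), with nearly all exceedances
occurring at age 1; restricting evaluation to ages 3--72 raises the
estimate to about 0.94. The original study's simulation assumptions
(distributions and parameter values of its two variability components) were
not disclosed, so its exact sample-size figure is not reproducible; the
machinery, criterion, and monotone improvement with sample size are what
the package delivers.

## Validation and trajectory comparison

`binned_sample_percentiles()` implements the standard rough check of fitted
curves: sample percentiles in 6-month age bins, plotted at bin midpoints
against the continuous curves. Bins are lower-open/upper-closed
($0 < \text{age} \le 6$, ...), percentiles use the linear-interpolation
order-statistic estimator with plotting position $p(k) = (k-1)/(n-1)$ (the
common default in scientific software; the source does not name its
estimator), and bins under 5 records report no values.
`segmented_linear_fit()` provides the descriptive three-segment linear
summary (segments $(0,30]$, $(30,54]$, $(54,72]$ months; the published
segment labels leave boundary months ambiguous, so half-open segments are
used and stated).

`trajectory_report()` places each assessment of a child on the centile
scale and raises three descriptive flags with configurable thresholds:
*divergence* (at least $k = 2$ consecutive assessments below the
16th-centile curve), *plateau* (score gain under $d = 2$ points across a
span of at least $m = 6$ months while the median curve gains at least
$2d$), and *converging* (centile band improves over the last two
assessments). The defaults encode the qualitative clinical patterns the
norms are designed to surface -- a child drifting out of the envelope, a
stalled trajectory against a steeply rising norm, recovery after
intervention -- and are deliberately conservative; they are descriptive
analytics, not clinical decision rules. Two synthetic demonstration
trajectories (`demo_trajectory("A")`, `demo_trajectory("B")`) illustrate
the early-implant catch-up pattern and the plateau-and-recovery pattern.

## Numerical notes and test scale

* All randomness flows through caller-supplied integer seeds; derived
  per-replicate seeds stay within 32-bit range. Identical inputs, seeds and
  options give bit-identical outputs, including across the
  simulate-fit-validate pipeline.
* The logistic saturates at double precision for large $a_3(x - a_4)$;
  monotonicity is therefore guaranteed non-strictly in tests.
* Degenerate inputs (empty designs, single-level tables, constant bins,
  one-point trajectories) return well-defined results or named errors, as
  documented per function.
* The test-suite's problem sizes are chosen to make statistical assertions
  sharp but cheap: parameter recovery uses one 20,000-child continuous
  cohort (recovering the median curve's $a_2$ within half a point and
  pinning the 95th centile's $a_2$ at the 64 bound), empirical-centile
  checks use 50,000 draws at a fixed age, the study-scale probability uses
  200 replicates, and oracle comparisons use 25 random 50--60-record
  instances against a grid oracle.

## Limitations

The package reproduces the *analysis*, not the *data*: every quantitative
claim about recovery and precision is conditional on the synthetic
generator's assumptions, which are themselves derived from the published
centile family. The packaged norms inherit the study's own caveats -- a
single metropolitan recruitment area, English-language items,
parent-reported ratings, no audiometric confirmation of typical hearing --
and the norms' applicability outside that population is a question the
package cannot answer.
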