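---
title: "Quantifying tactile direction discrimination: staircase scoring, normative thresholds and node-level lesion mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying tactile direction discrimination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tactdd)
```

## The measurement problem

Tactile direction discrimination (TDD) — telling which way a probe moves
across the skin — depends on distributed cortical processing and degrades
with neurological disease, including stroke. The clinical test implemented
here is a two-alternative forced-choice adaptive staircase: a probe is moved
over the dorsum of the hand or foot across one of seven distances drawn from
an approximately logarithmic series (3, 6, 10, 18, 32, 56, 100 mm), starting
at 18 mm. An incorrect answer makes the task easier (next longer distance);
three consecutive correct answers make it harder (next shorter distance),
with the series clamped at both ends. The test runs 32 trials with equal
numbers of the two movement directions in pseudo-random order. Probe speed
(10 mm/s) and load (16 g) are recorded as metadata; they do not enter the
computation.

## The staircase score

Each trial contributes the 0-based index of its distance within the series
("boxes to the left" on the paper scoring sheet), and the score is the sum
over the 32 trials, approximating the area under the staircase trace. Higher
scores mean worse discrimination. Two design readings fix the scoring rule
unambiguously against the protocol's printed extremes:

* the consecutive-correct counter resets on every incorrect answer *and* on
  every level change — the simplest consistent reading of "three correct
  responses in a row";
* incorrect trials are scored exactly like correct ones, through the
  distance visited.

Under these rules an always-correct observer scores exactly
`r run_staircase(function(d) 1, seed = 1)$score` (3 trials at 18 mm, 3 at
10, 3 at 6, then 23 at 3 mm) and an always-failing observer exactly
`r run_staircase(function(d) 0, seed = 1)$score` (18, 32, 56, then 29 trials
at 100 mm); any response sequence lies in [18, 186]. Direction scheduling is
an independent balanced shuffle (an optional maximum-run-length constraint
exists but is off by default, since the protocol specifies only
"pseudo-random") and never affects the score.

Because the staircase is a small Markov chain over (level,
consecutive-correct counter), the exact expected score of any observer is
computable by forward dynamic programming (`expected_score_dp()`), with no
sampling. This is the oracle the simulation tests compare Monte-Carlo means
against, and the tool used to calibrate the synthetic observers below.

## Observers and the synthetic normative cohort

Simulated participants are psychometric observers: P(correct at distance d)
= 0.5 + (0.5 − lapse) · logistic((ln d − ln α)/β). Chance is 0.5 (forced
choice), α is the distance at the inflection, β the log-distance slope, and
the lapse rate caps asymptotic performance; the log-distance logistic was
chosen because the distance series is near-geometric (a Weibull form is
available). A 3-down/1-up staircase equilibrates where P(correct) ≈ 0.79, so
the score is most sensitive to α in that region.

The normative generator draws ages uniformly on 22–68 years, gives each
subject a lognormal sensitivity deviate (sdlog 0.45), and, on the foot,
degrades α multiplicatively with age. Its defaults were calibrated once
against the DP expectation: foot α = 3.0 mm at age 44 with a 5% sensitivity
loss per year, β = 0.5, lapse = 0.01, giving a mean foot score ≈ 41 at the
cohort mean age and an emergent score-vs-age slope ≈ 1.2 points/year; hand
α = 0.55 mm with no age effect, giving a mean ≈ 21.5 close to the score
floor (the hand version of the task shows a floor effect in healthy adults).
Default sample sizes are 43 (foot) and 34 (hand). Sex is assigned at random
and has no effect, matching the null sex difference the thresholds assume.

What the generator does *not* emulate: real skin mechanics, attention
fluctuations beyond a constant lapse, within-session learning, or any
correlation between sites within a subject. Passing tests therefore show
that the analysis machinery recovers what it should under its stated
assumptions, not that the assumptions hold on patients.

## Thresholds and classification

The impairment cutoff is the 90th percentile of the normative sample.
Two model forms are provided:

* **flat** — the percentile within 10-year age bands (20–29 … 60–69), or
  pooled; used when scores do not vary with age (the hand). Quantiles use
  linear interpolation between order statistics (R type 7) — the common
  scientific-software default; the rule is configurable because no single
  convention is universal.
* **linear** — for the age-dependent foot: OLS of score on age with the
  intercept shifted up by the 90th percentile of the residuals, so 90% of
  normative points lie below the line `threshold(age) = a·age + b`. This
  derivation is one reasonable reconstruction (a quantile regression would
  be another); the published coefficients for the standard protocol
  (hand 27.7 flat; foot 1.786·age − 11.77) are available directly via
  `reference_thresholds()` for classification use.

Thresholds extrapolate beyond the normative age range — patients extend to
82 vs a normative maximum of 68 — linearly for the linear model and by
nearest band for the flat one, consistent with the roughly linear decline of
tactile function with age.

The relative score is (raw − threshold)/threshold; a site is abnormal when
its relative score is **strictly** greater than 0 or when a side-difference
flag is set, and a patient is abnormal when any site is. The strict boundary
is a declared convention: the packaged cohort contains a site printed as
exactly 0.00 whose patient is abnormal through other sites, so the boundary
case is unobservable in the data. The numeric side-difference criterion
behind the flags is not computable from the table; flags are accepted as
input, not derived.

As an alternative classification strategy, Crawford-style single-case tests
are provided: the Crawford–Howell comparison against a small normative
sample (t = (case − mean)/(sd·√((n+1)/n)), df = n − 1) and the regression
variant against an age-predicted value with the usual prediction-error
leverage term (df = n − 2). "Worse than 90% of controls" is operationalised
as an estimated percentile above 90 (point estimate, one-tailed toward
higher = worse scores); `compare_classification_strategies()` reports
per-patient concordance between the two rules, which differ only in a
narrow borderline band.

## Group-level statistics

The association between lesion location and impairment is tested with a
one-sided Fisher exact test: conditional on the margins of the 2×2 table
(target-area lesion × impaired), the upper hypergeometric tail P(X ≥ a).
The one-sided orientation is fixed so that the hypothesis is "target-area
lesions increase impairment incidence". The accompanying interval is the
conditional exact one-sided 95% bound: the odds parameter of Fisher's
noncentral hypergeometric distribution at which the upper tail of the
observed count equals 0.05, found by monotone root-solving on the log-odds
scale; the upper limit is ∞ when the observed count is at its conditional
maximum (as in the packaged table, where all 9 target-lesion patients are
impaired). Mid-p variants are deliberately not used.

Change between the acute and 3-month examinations is a classical paired t
test on relative scores pooled over left and right within a site type,
differenced as acute − follow-up so a positive mean difference means
improvement. Multiplicity over the node-level tests is controlled by
Holm–Bonferroni (k-th smallest p against α/(m − k + 1)); with two tests the
critical alphas are 0.025 and 0.05.

## Node-level lesion-symptom mapping

Voxel-level mapping is out of reach when lesions are scattered (few patients
overlap at any voxel), so the mapping operates on *nodes*: contiguous
components of a parcellation, obtained by connected-component labelling
within each parcel label. Components use 6-connectivity (faces only) by
default — the conservative choice, configurable to 18/26 — and node ids are
stable (parent label, then size descending). Three eligibility criteria
gate the analysis: nodes must exceed 100 voxels (strict: a 100-voxel node is
excluded — the inclusive reading is equally defensible but the strict one is
implemented); a patient counts as lesioned in a node when the overlap
reaches min(100, ⌈10% of node size⌉) voxels (the ceiling keeps the criterion
integer-valued); and only nodes with at least four such patients are
analysed. Lesion-node overlap ignores hemisphere; laterality enters only
through which side's composite score (left = left hand + left foot relative
scores, likewise right) is tested. Per analyzable node and side, lesioned
patients are compared to the rest with a one-tailed pooled-variance t test
(lesioned worse, i.e. higher; Welch optional), Holm-corrected across the
tests performed. Volumes must already share one grid — no resampling or
spatial normalisation is performed; registration to a common space is
upstream of this package.

The phantom generator builds parcellations from non-overlapping cuboids or
spheres so every component and voxel count is known by construction; the
default phantom has two 1728-voxel nodes and one 64-voxel (ineligible) node
on a 30³ grid. The synthetic patient cohort places 8-cube lesions inside the
designated deficit node for ~30% of 28 patients and 6-cube background
lesions for the rest, so exactly one node is analyzable — the structure of
the motivating study. In fast mode, deficit patients' left-side relative
scores are shifted by 1.5 pooled composite standard deviations; in full
mode the deficit degrades the observer's α and scores arise from actual
staircase runs against the reference thresholds.

## Numerical and design notes

* RNG: every generator takes an integer seed and is bit-reproducible;
  seeded evaluation is scoped (the ambient RNG stream is restored), and
  staircase sheets store their seed.
* The odds-ratio root-solve brackets log ψ in [−50, 50] with `uniroot` at
  tolerance 1e−12; the bound at the conditional support minimum is 0.
* Degenerate inputs are conventions, not errors, where the field expects a
  result: Fisher p = 1 for degenerate margins; paired t with zero-variance,
  zero-mean differences reports p = 1 with an undefined t; a perfect
  zero-slope fit reports F = 0, p = 1. Genuine contract violations
  (non-binary masks, mismatched grids, constant predictors, thresholds ≤ 0,
  observer probabilities outside [0, 1]) fail loudly.
* Problem sizes in the test suite were chosen to make simulation checks
  sharp but quick: 10⁴ staircase runs against the DP oracle, 10⁴ Crawford
  null replicates, 500 node-mapping replicates for power (≥80% at the
  documented effect) and family-wise error, 400 replicates for the age-test
  size. These are the package's own verification scales.
* The printed foot-site time comparison in the motivating cohort carries a
  t/p pair that is internally inconsistent at df = 55; the package reports
  recomputed statistics and treats only the mean difference as a
  reproduction target.

## Known limitations

Real lesion anatomy, atlas geometry and MNI-space registration are outside
scope: the lesion-mapping module requires pre-aligned volumes and the
phantom stands in for an atlas in all tests. The side-difference criterion
is an input flag, not a computed rule. Single-case methods are frequentist
point-percentile versions; Bayesian variants and percentile interval
criteria are not implemented.
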