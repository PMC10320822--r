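---
title: "Methods: inferring matrix-completion strategies from gaze"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: inferring matrix-completion strategies from gaze}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gazemat)
```

# The measurement model

A matrix completion trial presents a 3×3 matrix with the bottom-right
cell missing above an array of answer options. We label gaze with ten
areas of interest: matrix cells 1–9 in row-major order (1–3 across the
top, 1/4/7 down the left), and the whole solution array as AOI 10. All
strategy inference operates on the trial's time-ordered sequence of
AOI-labelled fixations.

**Fixation parsing.** Raw samples (nominally 50 Hz) are classified by a
velocity threshold computed per participant from that participant's own
velocity distribution — median + 3×MAD, floored at 100 px/s — because
signal quality differs systematically between young children and adults,
and a fixed threshold would confound age with parsing quality. Runs of
sub-threshold samples shorter than 100 ms are discarded; invalid gaps
under 75 ms inside a stationary run are bridged (single dropped samples
are routine at 50 Hz); fixations after the response are dropped, and one
straddling the boundary is truncated to it. A fixation's duration is its
sample span plus one sample period. The floor, the MAD rule and the
bridge length are configurable; the defaults are stated here once and
used everywhere.

**Response time** is the total detected fixation time on the AOIs, not
wall-clock time: saccades, signal loss and off-screen looking carry no
information about processing and would otherwise penalise participants
with poorer signal. The per-trial **valid fraction** (AOI fixation time
over full trial time) quantifies exactly that loss and drives trial
exclusion; the threshold defaults to 0.20 because published exclusion
counts in this literature do not come with a printed criterion, so it
must be a configurable analyst decision.

**The seven indices.** Encoding requires three *consecutive* fixations
covering the three distinct items of one row or column; any visiting
order counts, because consecutiveness and coverage — not order — are what
distinguish a deliberate sweep, and an order-strict variant is available
behind a flag for sensitivity analysis. Off-AOI and solution-array
fixations break encoding windows (a sweep is an unbroken scan of the
matrix) but are transparent for toggle adjacency (a blink between matrix
and array still reflects one consultation); both choices are flags.
Consecutive fixations on the same AOI are collapsed before toggle
counting only, so re-fixations within a cell neither create transitions
nor break sweeps. Toggle rate divides the toggle count by response time.
Time to first toggle is the AOI time strictly before the first
solution-array fixation; on array-free trials it is censored at the
response time and flagged rather than dropped — dropping would bias the
index against pure constructive matchers. The matrix time distribution
index contrasts time on cells {1,2,4,5} with time on {3,6,7,8,9},
normalised by matrix time: near 0 means even coverage, negative means
dwelling on the final row/column.

**Reliability** treats the task's trials, in fixed order, as items of a
scale and reports raw Cronbach's alpha per index, with listwise handling
of participants missing trials.

# The statistical pipeline

Outliers are trimmed per analysis at >2.5 SD from the group mean (single
pass, full-group mean and SD). Group comparisons use Welch's t by
default — pooled variance is a flag — plus a Brown–Forsythe variance test
(group-median-centred absolute deviations; mean-centring is a flag,
since the naming convention in the literature does not fix the centring).
Index–performance associations are Pearson correlations with t-based
p values and 95% CIs, computed per group, with a sensitivity variant that
first removes participants below the 100/n-options chance level.

Trial-level specificity is assessed with one mixed logistic model per
index, `accuracy ~ index + difficulty + (1 | participant)`, with item
difficulty (100 − group mean percent correct, so higher = harder) as a
covariate. Difficulty is centred at 50 and scaled to tens inside the
fitter for numerical stability; coefficients are rescaled to original
units before reporting. A boundary (singular) random-effects fit is
reported; only optimizer failure flags non-convergence.

Strategy adaptation is measured by
`index ~ difficulty + (difficulty | participant)`, fitted *within each
group* — pooling groups with different baselines shrinks everyone toward
one fixed slope and measurably degrades per-participant slope recovery.
Binary indices (encoding, integration) use a logistic link, continuous
ones a linear link; the random intercept accompanies the random slope by
default, and both link and intercept choices are arguments because the
field's reporting conventions leave them open. Per-participant
conditional slopes (fixed + BLUP) are the adaptation indices; if a mixed
fit fails the fallback is independent per-participant regressions,
flagged as such. No multiple-testing correction is applied by default,
matching the analysis tradition this mirrors; `p.adjust` can be applied
to any result table by the user.

# What the synthetic generator emulates

The generator exists so that every downstream stage has a ground truth.
A trial is built on the axis of detected AOI time:

- Total AOI time is lognormal around `rt_mean` (mean 7.6/8.9/21.7 s for
  the three preset groups), multiplied by a difficulty factor
  (+1.2%/point, normalised to the item-bank mean so `rt_mean` keeps its
  task-average meaning).
- The first solution-array visit occurs at a Beta-distributed fraction
  of the trial's AOI time, with mean `first_toggle_mean / rt_mean`
  (shape 8). This guarantees the visit falls inside the trial and makes
  the measured time-to-first-toggle exactly unbiased for
  `first_toggle_mean` (2.2/3.9/7.5 s presets).
- Later matrix↔array transitions form a Poisson stream whose rate is
  solved per trial so that the expected toggle count equals
  `toggle_intensity × T` given the realised trial length and first-visit
  time — hence the measured toggle rate is unbiased for
  `toggle_intensity` (0.47/0.38/0.27 s⁻¹ presets). Array dwells are
  compressed relative to matrix dwells by `array_dwell`, which sets the
  proportion of time on the matrix without touching toggle counts.
- With probability `p_scan` a row sweep is planted at the start of the
  trial, and independently a column sweep; the first dwell is extended
  to hold a planted sweep when needed. Between sweeps the gaze dwells
  (stay probability 0.62) and jumps among cells, favouring cells
  {1,2,4,5} with probability `first_block_bias` — this sets the matrix
  time distribution index. Dwell-and-jump wandering keeps *accidental*
  sweeps rare (8–26% of trials depending on trial length); planted
  events are recorded in the truth table so tests can separate them.
- Off-AOI time is injected between fixations so the valid fraction
  equals exactly `1 − missing_frac` (43/31/24% presets).
- Difficulty shifts `logit(p_scan)` by `adapt_scan_slope`
  (mean 0.03/point, between-participant SD ≈ 0.028) and
  `log(toggle_intensity)` by `adapt_toggle_slope` (mean −0.006/point,
  SD ≈ 0.009), the simplest monotone links that reproduce monotone
  item-level trends. The slope SDs were chosen so that individual
  adaptation differences are identifiable from 24 trials — roughly, the
  true-slope SD should not be small against the per-participant
  least-squares slope error (≈0.0034 for toggle rate at this item
  spread).
- Responses come from a logistic accuracy model increasing in realised
  encoding, integration and time-to-first-toggle and decreasing in
  toggle rate and difficulty; incorrect mass is split over distractor
  types, with the duplicate option's weight growing with the trial's
  toggle rate. A standard-normal competence factor loads positively on
  scanning, first-toggle latency, adaptation and accuracy and negatively
  on toggle intensity, producing the between-person structure in which
  constructive matchers both perform and adapt better.
  `sim_config(coupled = FALSE)` zeroes all couplings for null
  calibration.

The item bank is three sets of eight problems of increasing anticipated
difficulty; per set, three one-relation, three two-relation and two
three-relation items (the final item stands in for a logical-rule
problem and is counted as three-relation). Anticipated difficulties span
12–80 in percent units.

Participant-level parameters are drawn around the group presets on
log/logit scales with mean correction, so configured values are true
cohort expectations — this is what makes the calibration checks (cohort
means within 3 Monte-Carlo SEs at 40×24 trials) meaningful rather than
approximate.

**What the generator does not emulate.** Real scanpaths have spatial
saccade dynamics, drift, pupil artefacts, anticipatory fixations and
item-specific salience; fixation durations correlate with processing
load; encoding can happen peripherally without a literal three-fixation
sweep; and real strategy mixes change within a trial. Passing the
recovery tests therefore shows that the pipeline measures what the
indices define, under behaviour with the assumed statistical structure —
it does not validate the indices as exhaustive measures of human
strategy.

# Calibration choices and known limits

Cohort-level calibration (simulated study: three groups of 40, 24
trials) verifies that measured toggle rate, time to first toggle and
1 − valid fraction recover their configured values within 3 Monte-Carlo
SEs. Correlation sign-structure checks run 500 simulated studies; the
correlation is computed over the pooled 120 participants, because at
n = 40 the null sampling SD of r is ≈ 0.16 and no implementation could
keep |r| < 0.2 in 95% of samples — at n = 120 the null SD is 0.092 and
the 0.2 calibration band is meaningful. The null generator uses one
group replicated to the same study size so group mean differences cannot
masquerade as individual-level correlation.

Adaptation recovery separates two claims. For the continuous toggle-rate
index, extracted random slopes correlate ≈ 0.86 with the generator's
true slopes. For binary encoding, 24 Bernoulli trials bound the
extractable information: the analogous correlation plateaus near 0.66
regardless of extractor, so the check asserted is sign recovery —
≥ 90% of participants whose true slope exceeds the population SD get the
correct extracted sign (measured ≈ 99%). Both numbers are reported by
the acceptance script. Recovery is evaluated against the design (item
bank) difficulty; using the realised difficulty estimate instead adds
measurement noise and costs roughly 0.05–0.25 of correlation depending
on the index.

Type-I calibration of the trial-level Wald test uses 5,000 replicates at
a reduced size (24 participants × 12 trials, `nAGQ = 0`); the measured
rate is slightly conservative (≈ 0.04) and within ±2 percentage points
of the nominal 0.05. The Brown–Forsythe test is calibrated at n = 20 per
group.

Numerical details worth knowing: AOI rectangles are half-open so shared
edges cannot tie; with a positive margin, multiply-eligible points go to
the nearest rectangle centre; zero response time, zero AOI time or zero
matrix time make the respective ratio indices undefined — the trial is
flagged and dropped from that analysis with a warning rather than
silently zeroed; and `toggle_rate × response_time = n_toggles` holds
exactly by construction, which the tests assert.
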