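# gazemat

Eyetracking strategy analysis for matrix completion (Raven's-style) tasks.

People solve matrix completion problems with two broad strategies.
**Constructive matching**: scan the rows and columns of the 3×3 matrix,
encode and integrate the relations among its items, predict the missing
entry, then look for it among the answer options. **Response elimination**:
shuttle between the answer array and the matrix, testing each option in
turn. Which strategy someone uses — and whether they adapt it as problems
get harder — is visible in their gaze, and predicts how well they perform.
This package implements the full analysis chain for inferring these
strategies from eyetracking data in children and adults, together with a
calibrated synthetic scanpath generator so every stage can be tested
without human data.

The pipeline:

1. **Gaze preprocessing** — velocity-threshold fixation parsing with an
   adaptive per-participant threshold (median sample velocity + 3×MAD,
   floored), a 100 ms minimum fixation duration, bridging of short signal
   dropouts, truncation at the response, AOI assignment (matrix cells 1–9
   row-major, solution array = 10), and data-quality exclusion rules.
2. **Strategic indices**, per trial, from the AOI fixation sequence:
   - *encoding* — three consecutive fixations covering all items of one
     row or column;
   - *integration* — a row event and a column event in the same trial;
   - *number of toggles* — gaze transitions between matrix and answer
     array;
   - *toggle rate* — toggles per second of detected looking time
     (response time = total AOI fixation time);
   - *time to first toggle* — AOI looking time before the first fixation
     on the answer array;
   - *proportion of time on the matrix* — matrix time over matrix + array
     time;
   - *matrix time distribution* — the proportion of matrix time on cells
     {1,2,4,5} minus that on {3,6,7,8,9}.
3. **Performance scoring** — percent correct, relational credit for
   partially correct answers, error typing
   (duplicate / novel-feature / partial), item difficulty
   (100 − group mean percent correct), chance level (100 / n options).
4. **Statistics** — >2.5 SD outlier trimming; Welch t and Brown–Forsythe
   variance tests; Pearson index–performance correlations with t-based
   CIs; trial-level mixed logistic models
   `accuracy ~ index + difficulty + (1 | participant)`; item-level
   difficulty regressions; and per-participant random difficulty slopes
   `index ~ difficulty + (difficulty | participant)` — the
   strategy-adaptation indices — correlated with overall performance.
5. **Synthetic cohorts** — a semi-Markov scanpath generator with planted
   row/column sweeps (probability `p_scan`), a Poisson stream of answer
   consultations whose rate is solved per trial so the measured toggle
   rate is unbiased for `toggle_intensity`, a Beta-fraction first array
   visit matching `first_toggle_mean`, exact missing-data injection, and
   a logistic accuracy model in which constructive matching causes
   correct responses. A truth table records every latent parameter for
   recovery testing.

## Worked example

```r
library(gazemat)

coh <- simulate_cohort(sim_config(n_per_group = 40, seed = 42))
coh
#> Simulated matrix-completion cohort
#>   participants: adult=40, nine=40, six=40
#>   trials: 2880  fixations: 121440
#>   mean accuracy: 50.4 %

an <- run_strategy_analysis(coh$trial_indices, coh$responses)
an$index_performance[an$index_performance$group == "six", ]
#>                     index group      r  ci_lo  ci_hi      t     p  n
#>              pct_encoding   six  0.717  0.518  0.842  6.250 0.000 39
#>           pct_integration   six  0.717  0.519  0.842  6.261 0.000 39
#>                 n_toggles   six -0.300 -0.559  0.013 -1.937 0.060 40
#>               toggle_rate   six -0.729 -0.849 -0.537 -6.475 0.000 39
#>      time_to_first_toggle   six  0.715  0.515  0.841  6.213 0.000 39
#>          prop_matrix_time   six  0.067 -0.254  0.375  0.408 0.686 39
#>  matrix_time_distribution   six  0.218 -0.100  0.496  1.379 0.176 40
```

Read: in the simulated 6-year-old group, the constructive-matching
indices (encoding, integration, time to first toggle) correlate strongly
and positively with percent correct, while the response-elimination index
(toggle rate) correlates negatively — the sign structure the analysis is
built to detect. At the single-trial level the same holds, adjusting for
item difficulty:

```r
an$trial_models$toggle_rate
#> Trial-level mixed logistic model: accuracy ~ toggle_rate + difficulty + (1 | participant)
#>         term       B      se      z        p   ci_lo   ci_hi
#>  toggle_rate -1.7700 0.25200  -7.03 2.08e-12 -2.2600 -1.2800
#>   difficulty -0.0617 0.00409 -15.10 2.26e-51 -0.0698 -0.0537
```

Strategy *adaptation*: each participant's random slope of an index on
item difficulty measures how much they shift that behaviour on harder
problems, and these slopes again predict performance:

```r
an$adaptation_fits$encoding
#> Adaptation slopes: encoding ~ difficulty, method glmm (logistic link)
#>   fixed slope: 0.0334 per difficulty point; 120 participants

subset(an$adaptation_performance,
       index %in% c("encoding", "toggle_rate") & group == "adult")
#>        index group      r  ci_lo  ci_hi      t     p  n
#>     encoding adult  0.689  0.481  0.824  5.868 0.000 40
#>  toggle_rate adult -0.362 -0.608 -0.053 -2.364 0.023 39
```

Raw gaze samples can be taken through the same chain:

```r
smp  <- synthesize_samples(coh$fixations)   # or read your own sample table
prep <- preprocess_gaze(smp, layout = default_aoi_layout())
ti   <- trial_indices(prep$fixations)
```

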