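# rtcump

Item-level response-time thresholds for detecting rapid guessing on
dichotomously scored tests, via the **cumulative proportion correct (CUMP)**
rule, with descriptive mean / mean+1SD companion cutoffs, person-level
aberrance flagging, engagement profile plots, and a 2PL + lognormal
response-time simulator with known ground truth.

## Who this is for

Psychometricians and testing programs that collect per-item response times
(RTs) alongside scored responses and need to screen for disengaged,
rapid-guessing respondents before those responses contaminate item
statistics, reliability estimates or person scores.

## The method

For item *j*, let CUMP<sub>j</sub>(t) be the proportion correct among all
responses given in at most *t* seconds. Blind guesses are fast and correct
only at the chance level *g* (0.25 for four options), so the curve starts
near *g* and climbs toward the item's overall proportion correct as engaged
responses accumulate. The item threshold is

```
C_j = max { t : CUMP_j(t) <= g }
```

— the largest time at which the curve is still at or below chance.
Responses faster than C<sub>j</sub> are treated as rapid guesses. Items
whose curve never reaches down to *g* (status `no_crossing`) or never rises
above it (`all_below`) are reported with explicit statuses, and thresholds
can be clipped to configured lower/upper limits.

A respondent is **flagged** when their RT falls outside
`center_j ± 1.3 · SD_j` (center = the item's mean RT by default, the CUMP
threshold optionally; SD = the item's RT standard deviation) on **50% or
more** of the items they answered. Fast and slow deviations are counted
separately; a fast-only mode targets rapid guessing specifically.

## Worked example

```r
library(rtcump)

# simulate 200 respondents on the built-in 9-item 2PL bank:
# engaged responding at a 30 s median, 25% rapid guesses at a 2 s median
sim <- simulate_sample(sim_design(n_persons = 200), seed = 42)

fit <- cump_analysis(sim$rt, sim$score)   # thresholds + CUMP curves
tidy(fit)
```

```
# A tibble: 9 x 9
  item_id n_used p_correct     g cump_threshold cump_status mean_rt sd_rt mean_plus_1sd
  <chr>    <int>     <dbl> <dbl>          <dbl> <chr>         <dbl> <dbl>         <dbl>
1 RE41M09    200     0.6    0.25          12.6  ok             26.9  23.1          50.0
2 RE41M05    200     0.605  0.25           5.96 ok             26.7  21.4          48.1
3 RE41M07    200     0.51   0.25           8.95 ok             27.0  23.0          50.0
4 RE41M10    200     0.535  0.25           3.05 ok             26.2  21.9          48.1
5 RE41M13    200     0.435  0.25           1.21 ok             24.9  21.6          46.5
6 RE41M15    200     0.485  0.25           1.35 ok             26.1  26.0          52.2
7 RE41M02    200     0.375  0.25          20.0  ok             25.7  20.6          46.2
8 RE41M11    200     0.41   0.25           2.07 ok             25.2  23.2          48.4
9 RE41M14    200     0.14   0.25         148.   ok             24.3  20.5          44.8
```

Each row gives the item's CUMP threshold in seconds (responses faster than
it look like guesses), its status, and the descriptive mean and mean+1SD
cutoffs. The run also warns that item `RE41M14` scores *below* chance
overall (0.14 < 0.25) — its 148 s "threshold" is the curve wandering under
*g* late, not a guessing boundary, which is exactly why hard items carry a
warning and are excluded from threshold-based classification.

```r
flags <- flag_sample(sim$rt, fit)
#> Flagged 1 of 200 respondents (0.5%).
flags[flags$flag == 1, ]
```

```
# A tibble: 1 x 7
  person_id n_items_used n_aberrant prop_aberrant n_fast n_slow  flag
  <chr>            <int>      <int>         <dbl>  <int>  <int> <int>
1 89                   9          6         0.667      0      6     1
```

Respondent 89 was slower than the 1.3-SD band on 6 of 9 items. A per-person
profile (RT per item over the three threshold lines, markers coloured by
correctness) shows what the flag means:

```r
prof <- build_profile(sim$rt, sim$score, fit, person = "89")
autoplot(prof)                       # or render_profile(prof, "p89.png")
```

File-based pipelines use the same functions (`run_analyze`, `run_flag`,
`run_plot`, `run_simulate`) or the bundled command-line script:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "rtcump.R", package = "rtcump"))') \
  analyze --rt rt.csv --responses resp.csv --out-dir out
```

Inputs are two comma-delimited person-by-item matrices (RT seconds and 0/1
scores), header row of item ids, optional leading person-id column, empty
cells or `NA` for missing.

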