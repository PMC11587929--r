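---
title: "Response-time thresholds and rapid-guessing flags: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Response-time thresholds and rapid-guessing flags: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rtcump)
```

## The problem

On computer-administered tests, the time a respondent spends on an item
carries information beyond the answer itself. Respondents who *rapidly
guess* — answering far faster than any plausible solution process, with
accuracy near the blind-guessing chance level — produce scores that do not
reflect their ability and can bias item statistics, reliability estimates
and test norms. Separating rapid guessing from engaged solution behavior
requires an item-specific response-time (RT) threshold: responses faster
than the threshold are treated as guesses.

`rtcump` estimates such thresholds with the *cumulative proportion correct*
(CUMP) rule, computes two descriptive companion cutoffs (the item mean RT
and mean + 1 SD), flags respondents whose RT pattern deviates from their
sample on a configurable share of items, and renders per-person engagement
profiles. A joint simulator of responses and response times with known
ground truth makes the whole pipeline testable without any external data
set.

## The CUMP rule

For item $j$, let $\mathrm{CUMP}_j(t)$ be the proportion correct among all
responses to $j$ given in at most $t$ seconds. If the fastest responses are
blind guesses, the curve starts near the chance level $g$ (0.25 for a
four-option item) and, as slower, engaged responses accumulate, rises
toward the item's overall proportion correct. The threshold is

$$C_j = \max\{\, t : \mathrm{CUMP}_j(t) \le g \,\},$$

the largest time at which the curve is still at or below chance. Unlike
thresholds read off the raw RT distribution, $C_j$ uses correctness
jointly with speed, and it adapts to item difficulty because the curve's
ceiling is the item's own proportion correct.

### Numerical choices

* **Evaluation grid.** The curve is evaluated at the distinct observed RTs
  of the item, with no binning: cumulative counts are exact on observed
  data, and the maximum in the rule is taken over observed times. No
  interpolation between grid points is attempted.
* **Inequality.** The comparison is $\le g$, not $< g$, so a time where the
  curve sits exactly at chance still qualifies.
* **Ties.** Responses sharing an RT enter the counts together: the curve is
  a function of the closed set $\{RT \le t\}$, which is the only
  well-defined reading when times repeat.
* **Degenerate curves.** Two regimes get explicit machine-readable statuses
  rather than silent numbers. When the curve never drops to $g$ (easy items,
  or accurate fast responders) the status is `no_crossing` and the reported
  value is the configured `lower_limit` (default 0): the threshold
  genuinely approaches zero when the chance assumption fails. When the
  curve never rises above $g$ (items at or below chance-level difficulty)
  the status is `all_below`, the value is the largest observed RT, and a
  warning is emitted — the threshold is unreliable there, which is also why
  the recovery study below excludes items whose proportion correct is
  within 0.1 of $g$.
* **Limits.** Optional `lower_limit` / `upper_limit` clipping (statuses
  `clipped_low` / `clipped_high`) guards against implausible thresholds on
  very easy or very hard items. The defaults are permissive
  ($[0, \infty)$): the limits are a property of the instrument and the
  administration, so they are configuration, not constants.
* **Missing data.** Pairwise (per-item) deletion: a cell missing either its
  RT or its score is dropped from that item's curve and never imputed.
  Persons with missing cells remain in the analysis for their other items.

### Descriptive companions

Next to $C_j$ the package reports the item's mean RT and mean + 1 SD
(sample SD by default, `sd_ddof = 1`; population SD available). A
mean − 1 SD cutoff is deliberately not produced: RTs are right-skewed, so
that quantity can be negative, outside the natural range of a response
time. With a single observation the SD is defined as 0.

## Flagging aberrant respondents

A person is flagged when, on at least a proportion `p` (default 0.5) of
the items they actually have usable data for, their RT falls outside the
band

$$\text{center}_j \pm k \cdot SD_j,$$

with `k = 1.3` by default and $SD_j$ the item's observed RT standard
deviation. Band-edge comparisons are strict, so a value exactly on the edge
is not aberrant (deterministic tie-break); with $SD_j = 0$ the band is
degenerate and any departure from the center is aberrant. The denominator
of the criterion is the number of usable items, not the test length, so
missingness does not mechanically shield a person from flagging. Fast and
slow deviations are counted separately (`n_fast`, `n_slow`), and a
fast-only mode (`sided = "fast"`) restricts the criterion to the rapid
side, the direction rapid-guessing detection is about. Under normality,
$k = 1.3$ marks roughly the outer 10 % of the RT distribution on each
side.

### Why the band centers on the item mean

Two readings of "deviates from the item's threshold by $k$ SD" are
defensible: center the band on the CUMP threshold $C_j$, or on the item's
mean RT. The package defaults to the **mean** (`center = "mean"`) and keeps
`center = "cump"` as an option, for a structural reason: RT distributions
are strongly right-skewed, so $SD_j$ is typically several times larger
than $C_j$ itself. A band $C_j \pm k\,SD_j$ then has its fast edge below
zero, and *no* response, however fast, can ever be flagged as fast — the
criterion would be blind to exactly the behavior it exists to find. Centered
on the mean, the fast edge sits in the gap between guessing-speed and
solution-speed responses, and both unusually fast and unusually slow
responding are detectable. The simulation study below confirms this
quantitatively.

## The synthetic data generator

The generator emulates the standard two-process view of test taking:

* **Engaged cells.** Correctness follows a two-parameter logistic (2PL)
  model, $P(\text{correct}) = \mathrm{logit}^{-1}(a_j(\theta_i - b_j))$
  with ability $\theta_i \sim N(0,1)$; the default item bank is a
  published nine-item reading-comprehension 2PL calibration
  (`default_item_bank()`, discriminations 0.35–2.42, difficulties −0.93 to
  +1.62). Log RTs are normal: $\log RT_{ij} \sim N(\beta_j - \tau_i,
  \sigma_j^2)$, with a person speed shift $\tau_i \sim N(0,
  \sigma_\tau^2)$.
* **Guessed cells.** Correctness is Bernoulli at the chance level $g$,
  independent of ability; log RTs are normal around a much faster median.
* **Regimes.** Guessing is planted either per response (each cell flips to
  a guess with probability $\pi$ — within-person switching, e.g. a
  respondent who gives up partway) or per person (a fraction $\varphi$
  guesses on the whole test).

Defaults, in units: `n_persons = 494`; engaged median RT
$e^{\beta} = 30$ s with spread $\sigma_j = 0.5$ log-seconds; guessing
median $e^{\mu_g} = 2$ s with spread $\sigma_g = 0.3$; person-speed spread
$\sigma_\tau = 0.2$ log-seconds (a moderate, realistic between-person
speed variance — at $\pm 2\sigma_\tau$ a person is about 1.5× faster or
slower than average); $\pi = 0.25$, $\varphi = 0.05$, $g = 0.25$. The 2 s
vs 30 s medians put the two lognormal components clearly apart, the regime
the CUMP method is designed for; all of these are surfaced in
`sim_design()` so the assumption is inspectable and changeable.

What the generator does **not** emulate, and what passing recovery tests
therefore do not establish about real data: *wandering* (disengaged slow
responding with poor accuracy, which can distort the upper part of the
CUMP curve); partial engagement within a single response; any dependence
of time-intensity $\beta_j$ on item difficulty (the default is a common
$\beta$ across items); speed–accuracy trade-offs within the engaged
process (engaged RT and correctness are conditionally independent given
$\theta_i, \tau_i$); and guessing accuracy different from the nominal
chance level. On real data the separation between components is also
rarely this clean.

## Recovery studies

Two simulation studies, run by `threshold_recovery_study()` and
`flag_recovery_study()` and re-executed by both the test suite and
`scripts/acceptance.R`, quantify the pipeline at a study size of 500
persons × 9 items × 20 replicate seeds (a size chosen to estimate the
rates stably while keeping a full run in tens of seconds):

* **Threshold recovery.** Under 25 % per-response guessing, classifying
  every cell as a guess iff $RT < C_j$ and scoring against the generator's
  truth, items with proportion correct more than 0.1 above chance achieve a
  mean accuracy above 0.9 (about 0.92 in our runs; the flattest item in the
  bank, discrimination 0.35, is the weakest at roughly 0.87).
* **Flag recovery.** With 5 % planted whole-test guessers, the fast-only
  flag at the `k = 1.3`, `p = 0.5` defaults attains sensitivity ≈ 1 with a
  false-positive rate ≈ 0 — the planted guessers' times sit far below the
  mean-centered band on every item.

## Limitations

* The chance level is assumed fixed per item; option-elimination or cue
  familiarity can push guessing accuracy above $1/\text{options}$, which
  drags $C_j$ toward zero (status `no_crossing` is the visible symptom).
* Sparse data at short RTs limit threshold precision on short instruments;
  the cumulative formulation mitigates but does not remove this.
* Very easy and at-or-below-chance items have no informative crossing;
  their statuses say so, and downstream flagging simply has less signal.
* The flag rule is a descriptive screen, not a person-fit statistic: it
  identifies candidates for inspection (e.g., with the profile plots), not
  respondents to be removed automatically.
* Ability annotation on profiles is user-supplied; the package does not fit
  the 2PL to data (the item bank is used only for simulation).

## A worked mini-run

```{r pipeline}
sim <- simulate_sample(sim_design(n_persons = 200), seed = 42)
fit <- cump_analysis(sim$rt, sim$score)
tidy(fit)
glance(fit)
flags <- flag_sample(sim$rt, fit)
head(flags)
```

```{r profile, fig.width = 7, fig.height = 4.5}
prof <- build_profile(sim$rt, sim$score, fit, person = "7")
autoplot(prof)
```
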