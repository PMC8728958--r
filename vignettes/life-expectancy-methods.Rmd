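---
title: "Estimating life expectancy at 65 by medication exposure: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating life expectancy at 65 by medication exposure: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`ibdlife` estimates period life expectancy at age 65 for elderly people
with inflammatory bowel disease (IBD), stratified by medication exposure
derived from prescription-claims-style dispensing records. This vignette
documents the statistical model, every analysis parameter and its
default, the design of the synthetic cohort generator, the numerical
conventions, and the limitations of the approach.

## The scientific question

Administrative health data can follow everyone in a jurisdiction with
IBD from age 65 until death, emigration, or the end of the study window.
Within that follow-up, dispensing records reveal which medication a
person is on at any time. The question is: how long can a 65-year-old
expect to live while managed with each therapy, and how do the
therapies differ? Because the comparison is descriptive (exposure groups
are not randomized), the estimand is the *period life expectancy of the
person-time observed in each exposure group*, not a causal effect of
treatment.

## Analysis chain

### 1. Follow-up

Each person enters at the latest of their 65th birthday, their IBD
diagnosis date, and the study start, and exits at the earliest of death,
emigration, and the study end (`follow_up_intervals()`). A sensitivity
analysis truncates follow-up at the first intestinal surgery
(`apply_surgery_censoring()`).

### 2. Exposure episodes

A dispensing covers the half-open interval from its dispense date for
`days_supplied` days. Same-drug dispensings whose gap does not exceed
the drug class's *grace window* are merged into one episode, with the
bridged gap counted as exposed; no grace tail is appended after the
final supply runs out (`build_drug_episodes()`). The windows are:

| class | grace window | rationale |
|---|---|---|
| mesalamine, immunomodulator, systemic steroid | 30 days | monthly oral refill cycle |
| infliximab / ustekinumab / vedolizumab | 84 days | agents given about every 8 weeks |
| other biologics | 42 days | agents given every 2–4 weeks |

Five exposure groups are formed: mesalamine, immunomodulator
monotherapy, biologic monotherapy, combination (day-level intersection
of immunomodulator and pooled biologic coverage), and systemic steroid;
the remainder of follow-up is *no therapy*
(`assign_exposure_intervals()`). Mesalamine and steroid coverage may
overlap other groups — the groups are not mutually exclusive, matching
how concomitant 5-ASA or steroid use is usually reported. The
monotherapy/combination split *is* exclusive by construction, and
no-therapy time is disjoint from all drug coverage, so no-therapy plus
coverage tiles follow-up exactly.

IBD subtype (Crohn's disease vs ulcerative colitis) is read off the
last nine outpatient visits: at least five concordant diagnoses give a
definite call; shorter histories fall back to simple majority and are
flagged (`classify_subtype()`).

### 3. Person-time and deaths

Exposure intervals are split at each person's 70th, 75th, 80th, 85th
and 90th *calendar birthdays* into the bands 65–69 … 90+ and summed as
person-years (`split_by_age_bands()`, `tabulate_person_time()`). A death
is attributed to every group whose interval covers the death date; an
interval ending exactly on the death date also counts, because follow-up
itself ends there and a death on the last covered day belongs to the
therapy.

### 4. Abridged life table

Band death rates $m_i = D_i / PY_i$ are converted to death
probabilities. Two conversions are available
(`build_life_table(q_method=)`):

* **Chiang** (default): $q_i = n_i m_i / (1 + n_i (1 - a_i) m_i)$ with
  $a_i$ the average fraction of the band lived by those dying in it;
* **exponential**: $q_i = 1 - \exp(-n_i m_i)$, exact when the hazard is
  constant within a band.

$a_i = 0.5$ by default; `a_method = "exponential"` instead solves
$a_i$ from the exponential within-band person-years, which together
with the exponential conversion makes the whole table *algebraically
exact* for piecewise-constant hazards — this is the configuration the
package tests against a closed-form oracle. The open 90+ interval is
closed as $L_\omega = l_\omega / m_\omega$; the closure is a named
option (`open_method`) so an alternative treatment of the final age
group can be swapped in, since published analyses differ on this point.

Life expectancy at 65 is $e_{65} = T_{65} / l_{65}$
(`life_expectancy()`). Its analytic variance uses the classical
decomposition over band death probabilities,
$\sum_i l_i^2 [(1-a_i) n_i + e_{i+1}]^2 \mathrm{Var}(q_i) / l_{65}^2$
with $\mathrm{Var}(q_i) = q_i^2 (1-q_i)/D_i$, plus an open-interval term
$l_\omega^2 / (m_\omega^2 D_\omega) / l_{65}^2$. A parametric bootstrap
(`bootstrap_ci()`, Poisson resampling of band deaths) provides an
independent interval; the two agree closely at realistic death counts.
Group differences use independent-strata normal intervals
(`le_difference()`, `difference_matrix()`), flagged significant exactly
when the 95% interval excludes zero.

### 5. Direct standardization

Age/sex-standardized mortality rates per 1000 person-years use weights
from a prevalent-case snapshot (alive, diagnosed, resident, aged 65+ on
a July-1-style reference date, default 2016-07-01), normalized within
sex (`reference_weights()`, `standardized_rate()`). The default
confidence interval is a Fay–Feuer-type gamma interval, which remains
valid at low death counts; a normal interval is available. Each sex is
standardized to its own prevalent distribution ("sex-specific" rates);
this is a documented assumption, as published reports rarely state
which convention they used.

## The synthetic cohort generator

Real claims databases cannot be shipped, so `simulate_cohort()` builds
cohorts whose *ground truth is known*, letting every estimator be
checked against closed-form answers.

Each person's history from entry is a semi-Markov walk over the six
exposure states with exponential dwell times (`mean_dwell`, years;
`Inf` freezes a state). Death, emigration, and surgery compete as
piecewise-constant hazards; mortality is specific to sex, age band, and
current state, so the *true* life expectancy of any (sex, state) pair
is available in closed form (`true_life_expectancy()`) and is written
into every bundle's `truth` table. While in a drug state the person
accrues dispensings with class-appropriate supplies and refill gaps;
8% of gaps are drawn to straddle the grace-window boundary so the
episode-merge logic is genuinely exercised. Surgery moves the person to
a post-surgery state and multiplies their subsequent mortality hazard
by `post_surgery_hr` (default 0.75), making censoring at surgery
informative in the direction reported for real cohorts: truncating
follow-up discards the favourable post-operative tail, so censored
life-expectancy estimates dip slightly.

Key defaults and why:

| parameter | default | why |
|---|---|---|
| `n_persons` | 28,260 | scale of a province-wide elderly IBD cohort |
| `p_female` | 0.519 | typical sex split in elderly IBD |
| study window | 1997-07-01 – 2017-06-30 | twenty-year claims horizon |
| `initial_probs` | mesalamine .39, no-therapy .465, immunomodulator .06, steroid .06, biologic .015, combination .01 | person-time shares concentrated in mesalamine/no-therapy, sparse biologic use in the elderly |
| base female hazards | 0.012, 0.019, 0.032, 0.055, 0.095, 0.18 /y | plausible elderly all-cause mortality by band |
| state multipliers | mesalamine 0.75 … steroid 3.2 | orders groups from healthiest (mesalamine users) to sickest (steroid-dependent) |
| male factor | 1.4 | male excess mortality |
| `post_surgery_hr` | 0.75 | surgery resolves refractory disease |

The absolute hazard levels are invented — real administrative rates are
not public — so only *structural* properties (ordering, recovery of
designed truths, calibration) are meaningful, never agreement with any
published point estimate. `frozen_config()` produces degenerate
single-state cohorts (fixed birth date, no emigration/surgery, 45-year
window) whose life expectancy is known exactly; these are the oracle
inputs for the parameter-recovery and interval-calibration tests.

### What the generator does *not* emulate

Real claims features deliberately out of scope: dose and days-supplied
miscoding, hospitalization episodes (drug use in hospital is invisible
to outpatient claims), switching driven by disease activity rather than
a Markov clock, secular trends in prescribing, clustering by
prescriber, and any confounding structure linking treatment choice to
frailty beyond the state-specific hazards themselves.

## Numerical conventions

* All intervals are half-open `[start, end)` at day resolution; a
  one-day dispensing covers exactly one day.
* Years are days / 365.25 everywhere (a single package constant).
* Age bands cut at *calendar* birthdays, not at day-count multiples of
  365.25, so band edges land exactly on dates.
* Zero-death bands contribute zero variance — an acknowledged
  underestimate, surfaced as a manifest warning rather than silently.
* Inversion sampling of death times redraws the measure-zero boundary
  draws rather than clamping them.
* Normal intervals use 1.96; gamma intervals use exact quantiles.

## What the tests establish — and what they cannot

The test suite verifies, on synthetic data: exact agreement of the
life-table chain with a closed-form oracle; recovery of designed band
rates and life expectancies within sampling error in frozen cohorts;
near-nominal empirical coverage of the analytic 95% interval; the
grace-window boundary behaviour on hand-computed dispensing sets;
recovery of a designed between-group gap as a significant difference;
and the monotone, direction-correct effect of surgery censoring.
Problem sizes in the tests (e.g. 20,000-person frozen cohorts, 500
replicate cohorts of 1,000) are the package's own choices, balancing
statistical resolution against desk-scale runtimes.

None of this validates the *epidemiology* on any real population:
passing tests show the machinery computes what it claims, not that
exposure groups in real data are comparable, that the grace windows
match real prescribing, or that synthetic hazard levels resemble any
jurisdiction's rates.

## Limitations

* **Exposure misclassification near death.** A person who dies never
  places their next refill, so the refill gap immediately before death
  is never bridged by a later dispensing: deaths occurring in such gaps
  are attributed to no-therapy even when the person was, in truth,
  still under treatment. This is inherent to claims-derived exposure
  (episodes end at supply exhaustion, no grace tail) and biases
  drug-group death rates downward and the no-therapy rate upward. The
  generator reproduces the phenomenon faithfully; the package's
  parameter-recovery tests therefore run on ground-truth state
  episodes, isolating estimator correctness from this reconstruction
  artifact.
* Exposure groups are self-selected; differences mix treatment effects
  with channeling (healthier patients receive mesalamine, the sickest
  receive steroids).
* Period life expectancy describes a synthetic cohort experiencing
  today's rates forever; it is not a forecast for any individual.
* The binomial variance of $q$ ignores the uncertainty in person-years
  and under-counts variance in zero-death bands.
* Combination therapy defined as day-level overlap will register brief
  accidental overlaps (e.g. a bridging course) as combination exposure.
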