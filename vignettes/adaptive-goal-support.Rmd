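---
title: "Adaptive step-down goal support: model, engine and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive step-down goal support: model, engine and simulation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(goalstep)
library(dplyr)
```

## The problem

Binge drinking — at least 4 drinks on one occasion for women, 5 for men —
is concentrated among young adults who rarely seek treatment. Text-message
just-in-time adaptive interventions (JITAIs) can reach them, but a fixed
"stay under the binge threshold" goal is unpalatable to heavier drinkers,
who decline to commit and then disengage. `goalstep` implements the
alternative: a *behavioral shaping* policy in which each weekend's
drinking-limit goal is tailored to the participant's own recent consumption
and stepped down gradually, together with the EMA (ecological momentary
assessment) scheduling machinery around it and the statistical battery used
to evaluate such trials.

## The goal policy

Let \(m_{t}\) be the maximum drinks the participant reported on any occasion
over weekend \(t\), and let \(\bar m\) be the mean of the two most recent
*responded* weekends before the current week. The prompted limit is

\[
L = \begin{cases}
10 & \bar m > 10 \quad (\text{cap})\\
\lfloor \bar m \rfloor - 1 & b < \bar m \le 10 \quad (\text{step-down})\\
b - 1 & \bar m \le b \quad (\text{floor})
\end{cases}
\]

where \(b\) is the sex-specific binge threshold (4 or 5). Limits are
integers in \([b - 1, 10]\) by construction. A goal is *met* when the
reported weekend maximum is at most \(L\).

Design choices where the contract was genuinely open:

* **Fractional averages.** The running average is kept as a real number and
  the step-down uses \(\lfloor \bar m \rfloor - 1\). This keeps limits
  integral and makes the limit a monotone function of the average, which in
  turn gives the monotone step-down property for non-increasing drinking.
* **Averages at or below the binge threshold.** The stated rule covers only
  \(\bar m > b\); below that we clamp at \(b-1\), the largest non-binge
  amount, recorded as `basis = "floor"`. Anything lower would prompt goals
  below any harm-reduction target the design contemplates.
* **Missing weekends.** The average is taken over the two most recent
  responded weekends however far back they lie; a single responded weekend
  is used alone; with none, no goal is prompted that week (the plan EMA is
  still sent). Week 1 uses the two run-in Sunday reports.
* **Inclusive limit vs "less than X" wording.** The stored limit is
  inclusive (`met` iff `reported <= limit`); the commitment message displays
  `limit + 1`, so "drink less than X" and the stored limit agree. The
  alternative reading (strict comparison against the displayed number) is
  observationally identical under this display rule.

Two consequences are verified exhaustively in the tests over all starting
maxima pairs in \([0,30]^2\): limits stay in \([b-1, 10]\), and a
participant who always drinks exactly the prompted limit reaches the floor
in finitely many weeks. Convergence is not monotone from every start (a
large weekend followed by a small one can briefly pull the average back
above the threshold) but the floor is always reached.

## The EMA engine

The engine is a deterministic state machine per participant. Weeks −2 and −1
are an assessment-only run-in (Thursday 5 pm drinking-plan prompt, Sunday
1 pm maximum-drinks prompt); answering at least 50% of those four prompts
makes the participant eligible to opt in (keyword "Go", case-insensitive).
Active weeks add the adaptive goal prompt after a "yes" plan reply, Friday
and Saturday 8 pm goal reminders and confidence queries (1–5) when a goal is
committed, low-confidence (\(<4\)) support vs high-confidence reinforcement,
and Sunday feedback (success, failure reframing, or consumption-only when no
goal was committed). Enrollment proceeds in 4-week blocks with voluntary
re-enrollment at each boundary, up to six blocks.

Times not fixed by the schedule description (the Friday/Saturday "evening")
are set to 20:00. Responses are expected within a 24-hour window; late
replies update state but are excluded from compliance counts. Tailored
support and feedback texts are site-configurable template IDs; only the five
assessment strings are fixed wording. Replaying an event log through the
engine is deterministic and reproduces the log exactly, which the test suite
asserts; this is the audit path for any recorded trial.

One participant in the motivating study is described as continuing up to 28
weeks, which exceeds six blocks plus run-in; the engine enforces the
six-block cap and does not model that discrepancy.

## The synthetic cohort

`simulate_cohort()` draws, per participant, an enrollment-length stratum
(weights 6/8/9/9 over 32), a latent intercept
\(b_0 \sim N(\mu_g, \sigma_g)\), and weekly desired consumption
\(D_t \sim \mathrm{Poisson}(e^{b_0 + \beta_g (t-1)})\), with the four
\((\mu_g, \beta_g)\) pairs (2.82, −0.34), (1.6, −0.17), (1.99, −0.13),
(0.61, −0.03) as defaults. Run-in weekends use the week-1 level, since no
intervention effect precedes enrollment. Behavioral draws use the observed
rates as defaults: plan-to-drink declining 0.78 → 0.46 over weeks 1–4,
commitment 0.96, high weekend confidence 0.6, adherence 0.98 (high) / 0.76
(low), response 0.82 on Thursday/Sunday and 0.58 on Friday/Saturday, and
block re-enrollment 29/38, 19/29, 9/19, 6/9, 2/6, 1/2. Adherent committed
weekends report \(\min(D_t, L)\) — truncation at the limit, the simplest
mechanism consistent with "met the goal"; non-adherent weekends report
\(D_t\) unchanged.

Values the study conditions do not pin down, chosen once: the random
intercept SD (0.5, a plausible between-person spread on the log scale); a
24% "low engager" mixture with response probability 0.2, which reproduces a
run-in failure rate near one quarter (a homogeneous 0.82 responder pool
would almost never fail the 50% gate); and independent Bernoulli
re-enrollment at each boundary, as no attrition mechanism beyond the
observed fractions is specified.

All draws for a participant come from a participant-indexed substream and
are pregenerated in a fixed order, so the event log is byte-identical across
runs and adding participants never reshuffles existing ones.

What the simulator does *not* emulate: day-level drinking microstructure,
assessment reactivity during the run-in, social or seasonal effects, and
any dependence of re-enrollment on drinking trajectory. Passing recovery
tests therefore show that the analysis correctly inverts this generative
model — not that real cohorts satisfy it.

## The analysis battery

* `response_rates()` — prompts issued vs in-window responses by block and
  slot type; absent cells are undefined, never zero.
* `goal_summary()` — commitment proportion over answered goal prompts,
  above-binge prompt share by week, and goal success over
  committed-and-evaluated weekends, stratified by the weekend's lowest
  reported confidence (<4 vs ≥4) and by goal level; every proportion keeps
  its numerator and denominator.
* `crosstab_chi2()` — Pearson chi-square without continuity correction
  (df = 1), Yates switchable; zero-margin tables return an explicit
  undefined signal.
* `wilcoxon_signed_rank()` — zero differences dropped, average ranks under
  ties, exact two-sided p by sign-assignment enumeration (computed by
  convolution) up to 25 non-zero pairs, tie-corrected normal approximation
  beyond. The exact path is needed because the standard no-tie exact
  distribution is unavailable under ties at these sample sizes.
* `two_sample_proportion_test()` — pooled-variance z.
* `fit_weekend_trend()` — per-stratum Poisson log-link panel model of the
  weekend maximum on week with a participant random intercept, fitted by
  Laplace approximation with the bobyqa optimizer (fixed settings, so
  repeated fits are identical). The week covariate is centred at week 1, so
  the intercept is the week-1 log-mean. An AR(1) within-participant
  residual option (`method = "ar1"`, via glmmTMB) is exposed, but the
  supported summary surface is the random-intercept model: the AR-within-
  Poisson estimation details are not pinned down by the design and the two
  agree closely on simulated cohorts. Strata with fewer than three
  participants are skipped with a warning.

Known numerical caveats: some published analyses of this design report
p-values (for example for the confidence contrast) that no standard variant
of these tests reproduces exactly; the implementations here follow the
stated test names and are verified against definitional brute-force oracles
instead of against those printed p-values.

## Problem sizes used in the checks

The slope-recovery study uses 200 participants over one 8-week enrollment
(two blocks), 20 replicates per (intercept, slope) pair, requiring the
fitted slope within ±0.05 of truth in at least 95% of replicates; with
full response and no truncation the slope standard error is well below
0.02 at every pair, so the band is several standard errors wide.
Calibration checks use at least 500 committed prompt-weeks and exact
binomial 99% acceptance regions around the generating probabilities; for
confidence-stratified goal success the generating value is
\(p_{\mathrm{adh}} + (1-p_{\mathrm{adh}})\,P(D_t \le L)\), since a
non-adherent weekend still meets the goal when desired consumption happens
to fall at or under the limit. Engine invariants (conservation of goal
evaluations, replay determinism, bounds, convergence to the floor) are
checked exhaustively where the state space allows and on seeded cohorts
otherwise.

## Worked example

```{r example, eval = FALSE}
sim <- simulate_cohort(sim_params(n_participants = 38, seed = 1))
response_rates(sim$events)
goal_summary(sim$events)

recs <- sim$events |>
  filter(type == "response", template_id == "max_prompt", week_index >= 1) |>
  transmute(participant_id, week_index, max_drinks = as.integer(value))
fit <- fit_weekend_trend(recs)
tidy(fit)
autoplot(fit)
```

## Limitations

The engine abstracts transport entirely (no delivery failures, no
time zones beyond a single study clock). The simulator's truncation
mechanism makes adherent weekends meet goals with certainty, so simulated
success rates run higher than observed ones unless adherence is lowered.
The pre/post table operates on complete cases only, matching the analysis
it mirrors; no multiple-testing adjustment is applied anywhere because none
is part of the analysis plan being implemented.
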