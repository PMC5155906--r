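---
title: "Methods: hierarchy, threshold cooperation, and the splitting game"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hierarchy, threshold cooperation, and the splitting game}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hiercoop)
```

## The game

`hiercoop` models a two-stage dyadic game played inside a ranked group of
ten. In each round two players are paired. In the **cooperation phase**
each holds an endowment of 20 experimental currency units (ECUs; 15 units
= 1 euro at payout) and simultaneously contributes any integer amount to
a common pot. If the joint contribution reaches the 20-unit threshold the
pot doubles to 40 units; otherwise contributions are lost and the round
ends. In the **splitting phase** the higher-ranked player proposes a
division of the 40 units; the lower-ranked player accepts or rejects. On
rejection a lottery assigns the whole pot to the lower-ranked player with
probability $k/10$, where $k \in \{1,\dots,5\}$ groups the rank
difference $d$ ($k = 1$ for $d$ of 8–9 down to $k = 5$ for $d = 1$).
Without a hierarchy the lottery is fair. Sessions are 9-round
round-robins, so each of the ten group members meets every other exactly
once. Five treatments are covered: no hierarchy (`control`), earned or
random hierarchy with the full game, and earned or random hierarchy with
the splitting phase only.

Responders state a full acceptance threshold each round
(strategy-method elicitation) rather than reacting to a single offer;
this makes the "minimum acceptable offer" analyses well-defined. In the
splitting-only treatments the phase operates on the same fixed 40-unit
pot as after successful cooperation, keeping the two families comparable.

## Equilibrium

With risk-neutral players, backward induction on the integer offer grid
gives the splitting-phase solution: rejection is worth $p_\text{low}
\cdot 40$ in expectation to the responder, so the smallest acceptable
integer offer is $\lceil 40\, p_\text{low} \rceil$ and the proposer
offers exactly that — the $4k$ schedule under the $k/10$ lottery, and a
20/20 split in the fair case. Acceptance at indifference is assumed;
without it no equilibrium exists on a discrete grid. The $k/10$ form
itself is a reconstruction: it is the unique grouping-respecting
probability assignment consistent with the $4k$ offer schedule on a
40-unit pot, and it is kept in one place (`lottery_probability()`) so
alternative rank-to-probability maps can be substituted.

The contribution stage is closed by brute force: `contribution_equilibria()`
enumerates the full $21 \times 21$ grid and keeps profiles where neither
player has a *strictly* profitable unilateral deviation (weak deviations do
not break equilibrium; this matters at indifference points such as $(0,0)$
under even continuation values). Because the set is generally large —
every successful profile with $c_i$ no larger than player $i$'s
continuation value, plus possibly $(0,0)$ — simulated rational play uses a
selection rule: the lower-ranked player contributes
$\min(\text{cont}_\text{low}, 10)$ and the higher-ranked player tops the
pot up to 20, i.e. minimal exposure for the disadvantaged side consistent
with certain success.

```{r spe}
spe_table()[c(1, 2, 10, 38), ]
```

## Agents

Three policy families share one interface (`decide_contribution()`,
`decide_offer()`, `decide_threshold()`):

* **nash** — the equilibrium quantities above; deterministic.
* **inequity_averse** — Fehr–Schmidt utility
  $U_i = x_i - \alpha \max(x_j - x_i, 0) - \beta \max(x_i - x_j, 0)$ with
  $\alpha \ge \beta \ge 0$, best responses on the integer grid. With
  $\alpha = \beta = 0$ it reproduces the rational agent exactly (a
  regression test enforces this). A consequence worth noting: rejection
  yields the maximally unequal 40/0 outcome, so a strongly
  inequity-averse responder can *lower* their acceptance threshold
  relative to the rational one.
* **empirical** — a stochastic calibration device (not a fit to any
  dataset) reproducing the qualitative patterns of interest: lower-ranked
  contributions rise with $k$ (fall with rank distance) and fall over
  rounds while higher-ranked contributions do the opposite; offers exceed
  the $4k$ anchor by more at large rank distances, flattening the
  offer-vs-$k$ slope below 4; stated thresholds exceed offers throughout.

The empirical defaults, in units: lower-ranked contribution
$10 + 1.0\,k - 0.5\,t_c$, higher-ranked $10 - 0.5\,k + 0.5\,t_c$ ($t_c$
the mean-centered round), no-hierarchy contribution mean 11 with no
slopes; offer shift above the anchor $\max(0,\, 8 - 1.5 k)$; threshold
shift 5 units above the offer shift; no-hierarchy mean offer 15 and mean
threshold 20, making offers 25% smaller than thresholds; Gaussian
decision noise with standard deviation 3, all outputs rounded and
clipped to the legal grids. Agents observe only success or failure,
never the partner's contribution, so policies condition on role, $k$ and
round alone. Under these defaults the hierarchy deficit in cooperative
success is deliberately mild — the contribution sums differ by well
under one noise standard deviation — so directional comparisons need
many sessions to resolve, and effect-recovery checks use an explicitly
injected calibration instead (see below).

## Synthetic studies

`study_design()` defaults to 6 sessions each of `control`, `earned` and
`random` plus 3 each of the splitting-only treatments: 24 groups, 240
simulated participants, 180 of them in cooperation treatments, matching
the study scale. Participants appear in exactly one session. Seeding is
hierarchical — master seed → per-session seeds → per-stage streams
(hierarchy, schedule order, decisions, lotteries) — so any stage is
independently reproducible and reruns are byte-identical. Earned ranks
sort independent standard-normal skill scores (an abstract stand-in for
the ranking tasks, which are out of scope) with random tie-breaks.

The generator emulates the design, not the population: decision noise is
independent across trials, so there are no persistent individual
differences, no learning beyond the built-in round slopes, and no
reputation dynamics. Passing calibration tests therefore demonstrates
that the pipeline recovers effects under the design's dependence
structure, not that human data would satisfy the same models.

## Statistical pipeline

Treatments with a cooperation phase are contrast-coded with the
orthogonal Helmert-style set $h_1 = (+2, -1, -1)$ (no hierarchy vs.
hierarchy) and $h_2 = (0, +1, -1)$ (earned vs. random); round is
mean-centered. Four model families are provided: cooperative success
(logistic; $h_1$, $h_2$, round and $h_1 \times$ round), contributions on
the binary rank code relative to the no-hierarchy mean, contributions on
the signed rank difference with the top- and bottom-ranked players
excluded, and the ultimatum family stacking offers (role $-1$) and
stated thresholds (role $+1$) with a cooperation-presence code and the
absolute rank difference.

Inference is a dyad-level bootstrap. In each replicate one member of
every dyad is selected at random as its representative; because
success, treatment and round are properties of the dyad, that selection
alone cannot produce replicate-to-replicate variation for the success
model, so the selected one-row-per-dyad data are additionally
cluster-resampled with replacement at the model's grouping unit (dyads,
or individuals carrying all their selected rows). Point estimates are
means over replicate coefficients and 95% intervals their 2.5/97.5
percentiles; 100 replicates by default. Within a replicate a
fixed-effects GLM/LM is fit: after selection each dyad contributes a
single row, leaving nothing for a dyad-level random effect to absorb,
and the generator has no persistent individual effects. Replicates whose
fit errors are dropped (the run aborts above a configurable 20% drop
fraction); fits that only warn — e.g. separation on all-success data —
are kept and counted as flagged. No multiplicity correction is applied;
intervals are reported per coefficient.

Calibration is checked by simulation at the default study size (18
cooperation sessions, 100 replicates per fit): with hierarchy treatments
generated identically to the control (a true null), the $h_1$ interval
covers zero at its nominal rate; with hierarchy contribution intercepts
depressed (sum mean 18 vs. 22), it excludes zero with a positive sign.
The test suite runs 10 repetitions of each pipeline, a size at which the
nominal 95% coverage is distinguishable from failure while keeping the
whole suite around two minutes.

## Worked example

```{r example}
trials <- generate_study(study_design(seed = 2026))
fit <- fit_success_model(trials, n_boot = 100, seed = 2026)
fit
summarize_figures(trials)$split_by_k |> head(6)
rank_earnings_correlation(trials)$rho
```

## Limitations

The empirical agent is a calibration device; none of its parameters are
estimates, and analyses of synthetic data cannot reproduce any
real-data coefficient. The $k/10$ lottery is a reconstruction
consistent with the $4k$ equilibrium, not an independently documented
formula. Mixed-model estimators are intentionally out of contract —
the pipeline's guarantees are the bootstrap coverage and recovery
properties above. Mixed-strategy or quantal-response refinements of the
contribution stage, demographic covariates, and reputation dynamics are
out of scope.
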