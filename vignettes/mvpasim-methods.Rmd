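---
title: "Modelling children's daily physical activity in an urban environment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling children's daily physical activity in an urban environment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mvpasim)
```

## The model

`mvpasim` simulates the weekday schedules of 9-11-year-old children in an
urban setting at 1-minute resolution and accumulates moderate-to-vigorous
physical activity (MVPA) minutes from every activity they perform. It is a
social-ecological agent-based model: each child's MVPA emerges from the
interplay of individual attributes, the social network, the neighbourhood and
the built environment.

Each agent carries a *tendency to be active* $A_i$ and an *outdoor-play
preference* $O_i$, both drawn from $N(1, 0.3^2)$ truncated to positive values
(negative tendencies are meaningless; the truncation removes about 0.04% of
the mass, so the sampled mean stays within Monte-Carlo error of 1). Agents
live in data zones carrying a deprivation quintile mapped to a multiplier
$s \in \{1, 0.9, 0.8, 0.7, 0.6\}$ (quintile 1, least deprived, maps to 1),
attend the catchment school of their zone, own household cars with
zone-dependent probabilities, and hold 3-8 reciprocal friendships inside
their school.

A weekday runs 09:00-20:00. School (09:00-15:00) comprises 320 lesson
minutes, 40 recess minutes and one 60-minute PE lesson per week; on the PE
day the PE minutes displace lesson minutes so the six-hour school day is
preserved. After school four behaviours compete for the evening:

* **Play on the way home.** Decided once at school exit with probability
  $F_{as} \cdot O_i \cdot s_i \cdot m$, where $m = 1/3$ if the child is
  driven home or has a sport session that day. The site is chosen among
  outdoor sites that extend the route home by at most 500 m.
* **Neighbourhood play.** While idle at home, a spontaneous-selection
  procedure fires on average 4 times per hour; outdoor play triggers with a
  per-attempt probability proportional to
  $F_{neigh} \cdot O_i \cdot s_i \cdot (1 + N_a \lambda')$, where $N_a$
  counts agents currently playing outdoors within 300 m of the home and
  $\lambda' = \lambda$ only when $N_a \ge 3$.
* **Friend meetings.** Each agent initiates a hosted meeting with daily
  probability $F_{friend}$; guests are friends without a sport session who
  are not already invited elsewhere. A meeting is held outdoors with
  probability $\gamma \bar{O} s_h$ ($\bar O$ the participants' mean
  preference, $s_h$ the host's zone multiplier), otherwise at the host's
  home.
* **Shopping.** Triggered by the same spontaneous procedure with frequency
  $F_{shop}$; the shop is drawn within 1000 m of home with weights that
  favour denser shopping clusters.

Outdoor sites are ranked by
$R_j = 0.6\,e^{-d_j \alpha} + 0.2\,e^{-\beta / v_j} + 0.2\,a_j$ with
$\alpha = 1/700$, $\beta = 0.7$, $v_j$ the current visitor count (the
presence term is defined as 0 at $v_j = 0$ so empty sites gain nothing) and
$a_j = 1$ for sites over 10,000 m². Selection is a *sequential roulette*:
candidates are examined in descending rank and candidate $j$ is accepted
with probability $R_j / \sum_k R_k$; when a full pass accepts nothing the
examination wraps around, so selection terminates almost surely.

Travel between activities is walk-or-car on the road network. The walk
probability is a logistic in distance, route walkability and (for non-school
trips) household cars; children without a household car always walk. Walking
accumulates MVPA at its own per-minute probability; car minutes accumulate
none.

Every minute of every activity is a Bernoulli MVPA trial with probability
$A^{\mathrm{eff}}_i \cdot P_k$, where $P_k$ is the per-minute MVPA
probability of the activity or land-use kind (by gender) and
$A^{\mathrm{eff}}_i = (1-\delta) A_i + \delta \bar{A}_f$ during joint
activities with friends (recess, PE and friend meetings), $\bar A_f$ being
the co-participating friends' mean tendency. For an event of known duration
the engine draws the binomial sum directly, which is distributionally
identical to the per-minute trials. Products above 1 are clamped to 1 and
clamping occurrences are counted on the run object (`run$clamp_count`).

## Key parameters

| symbol | meaning | default |
|---|---|---|
| $F_{as}, F_{friend}, F_{neigh}, F_{shop}$ | per-weekday activity frequencies | 2/5, 2/5, 1/5, 1/5 |
| durations | exponential means (play/meeting, shopping); fixed sport session | 70, 30, 60 min |
| $\gamma$ | share of meetings held outdoors | 0.5 |
| $\delta$ | peer adjustment of $A$ during joint activity | 0.3 (swept 0-1) |
| $\lambda$ | presence feedback per nearby outdoor player | 0.1 (swept 0-0.6) |
| $s$ | deprivation multipliers by quintile | 1 ... 0.6 |
| walk / car speed | network travel speeds | 33 / 500 m per min |

The walking speed follows the model's internal convention that a 500 m
detour is about 15 minutes of walking; it is deliberately conservative for
children and is configurable.

## Frequency-to-attempt calibration

The frequencies are weekday-scale probabilities, but neighbourhood play and
shopping are triggered by 15-minute attempts whose count depends on how busy
the evening is — which itself depends on the frequencies. Before each
experiment the engine therefore runs a short dry pass of the full dynamics
with $\lambda = 0$ and solves the fixed point
$q = F / \mathbb{E}[\text{attempts}]$ by multiplicative updates, averaging
the converged iterations to shrink Monte-Carlo error. Two properties matter:

* the presence feedback is **never absorbed** into the calibration (the dry
  pass forces $\lambda = 0$), so any $\lambda > 0$ acts on top of calibrated
  baseline rates — this is what lets the positive feedback between outdoor
  presence and play participation emerge;
* the friend-meeting initiation probability is calibrated the same way,
  compensating for scheduling conflicts (hosts and guests must be
  simultaneously free) that would otherwise deflate realised meetings below
  $F_{friend}$.

With the defaults, realised weekly episode counts of all four after-school
activities match their configured frequencies within binomial Monte-Carlo
error; the test suite checks this under the neutral conditions $O = s = 1$,
$\lambda = \delta = 0$, no cars, no sport sessions.

## The synthetic city

The generator emulates the study setting the model is designed for: a
contiguous urban area divided into equally sized data zones (default 6 x 5
zones of 400 m, 17 homes each, 510 children, a 4.8 km² area whose school
commutes span roughly 0.3-2 km as in a real urban catchment), a regular
street grid (200 m spacing) whose per-edge walkability is Beta-distributed
with a mean that declines with zone deprivation, two schools with zone-based
catchments, and counts of parks, sports fields, gardens, amenity spaces,
leisure centres and shops placed uniformly and snapped to the grid; garden
and amenity patches are the most numerous outdoor kinds (about two per
zone), mirroring how residential greenspace dominates urban land-use
inventories and ensuring that a play site within the 500 m after-school
detour bound exists for essentially every route. Deprivation layouts can be
random, a spatial gradient, or clustered. Real settings can be supplied as
three GeoJSON layers (zones, land use, roads) in a local planar-metre frame.

What the synthetic city does *not* emulate: irregular street topology,
heterogeneous building density, correlated land-use patterns (shops along
high streets), or realistic school sizes and catchment shapes. Passing tests
on the synthetic city therefore demonstrate the internal consistency of the
behavioural machinery and the directional effects of interventions, not
calibrated predictions for any real place.

## Placeholder tables

Two empirical inputs of the original study design are not publicly
available and ship as documented placeholders:

* the per-minute MVPA probabilities by land use and gender
  (`default_mvpa_table()`). The defaults respect the established qualitative
  ordering — outdoor play sites, schoolyard recess, PE and organised sport
  well above home, lessons and shopping; boys slightly above girls; car
  zero — but the levels are choices. Any quantitative claim requires a table
  estimated from accelerometer data (`read_mvpa_table()`).
* the travel-mode regression coefficients (`travel_model()`), chosen to
  satisfy the qualitative dependencies and two anchor points
  ($p_{walk}(500\,\mathrm{m}) \approx 0.9$ for school trips,
  $p_{walk}(3\,\mathrm{km}, 2 \text{ cars}) \approx 0.2$ otherwise).

A consequence of the slow walking convention plus the synthetic city's trip
distances is that walking contributes a larger share of total MVPA here
than the school day does; with empirically estimated tables the school share
dominates. Directional scenario comparisons are unaffected because every
scenario shares the same tables.

## Design choices on genuinely open points

* **Peer influence is transient by default.** The adjustment
  $A_i \leftarrow (1-\delta)A_i + \delta \bar A_f$ could be read as a
  persistent mutation, but iterating it daily over 30 days would collapse
  the population's tendencies towards school means. The default applies the
  adjusted value only during the joint activity; `peer_influence =
  "persistent"` switches to the cumulative reading.
* **School-day peer adjustment** applies during recess and PE (the social,
  active blocks), not during lessons, and uses all same-school friends.
* **The 500 m detour bound** is read as total added distance (out plus
  back minus the direct route), matching its "about 15 minutes of walking"
  gloss.
* **Eight scenarios**: extra daily PE displaces lesson minutes inside the
  fixed school day (configurable via `pe_extends_day`); "walk to all
  activities" removes car trips entirely, which also removes the car part
  of the after-school-play penalty.
* **Morning commute** necessarily precedes 09:00; it is logged with a start
  before 09:00 and its walking MVPA counts towards the day, while the
  minute-conservation invariant (660 minutes exactly) applies to events
  from 09:00 on.
* **SIMD orientation.** Correlations report the quintile with 1 = least
  deprived, so deprivation suppressing outdoor play yields a *negative*
  MVPA-SIMD correlation; under the official Scottish coding (1 = most
  deprived) the sign flips.
* **Meeting attendance.** A host may be a guest elsewhere the same day
  (meetings are sequenced); nobody is invited twice; invited agents hold
  their evening free until the meeting launches.

## Numerical and degenerate-input conventions

Probabilities are clamped to [0, 1] and clamping is counted, never silent.
Durations are integer minutes of at least 1, truncated so activity plus
return travel finishes by 20:00; an activity that cannot fit is skipped (and
the attempt-rate calibration absorbs the loss). Site-rank ties break by site
index. All randomness flows from one root seed through fixed derivation
offsets (environment, population, calibration, one per replicate), so runs
are bit-reproducible and replicates are independent.

## Problem sizes used by the test suite

The suite exercises the default 500-agent city with 10-weekday, 5-replicate
scenario experiments for the directional comparisons, 8-weekday,
2-3-replicate runs for the sensitivity sweeps, and a 180-agent city for the
27-point frequency-recovery grid; these sizes give comfortable Monte-Carlo
margins for every directional property while keeping a full run of the suite
in the tens of minutes.

## Known limitations

Weekends, holidays, siblings and parental constraints are outside the model.
Site quality is uniform within a land-use kind. The travel model is binary
walk-versus-car. Headline outputs (population mean MVPA, share below the
60-minute guideline) depend strongly on the placeholder MVPA table and
should be read as internally consistent model output, not as predictions.
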