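---
title: "Scheduled sleep deprivation: models, metrics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scheduled sleep deprivation: models, metrics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sleepssd)
library(data.table)
```

## The scientific question

The two-process view of sleep regulation holds that a circadian clock and a
wake-dependent homeostat jointly decide when and how much animals sleep.
Scheduled sleep deprivation (SSD) separates the two: a brief, fixed-dose
sleep deprivation is repeated on a 7 h ultradian cycle so that the recovery
opportunity ("rebound window") drifts around the 24 h day, one clock hour
per cycle. If the homeostat were clock-blind, equal sleep loss should
produce equal rebound at every hour; systematic morning/evening differences
in rebound instead reveal circadian programming of the homeostat itself.
This package implements the full behavioral arm of that design: DAM file
handling, sleep scoring, protocol construction, rebound metrics, circadian
profiles, the statistical layer, and a synthetic cohort generator that
makes every stage testable.

## Sleep scoring

Activity arrives as per-minute beam-crossing counts (Trikinetics DAM
format; 10 metadata columns, 32 count channels, one record per minute).
Sleep follows the standard fly convention: every minute inside a maximal
run of `>= 5` consecutive zero-count minutes is asleep, including the first
four; shorter zero runs are wake, and runs touching the recording edges
count if long enough. `score_sleep()` is deterministic and is checked in the
test suite against an independent sliding-window oracle on random traces.
Windows throughout the package are half-open `[start, end)` on a 0-based
minute grid; zeitgeber time (ZT) is hours since lights-on, and under
constant darkness the same mapping is kept as circadian time assuming a
24.0 h period (morning/evening comparisons in DD re-use the LD clock labels
without phase re-estimation).

Latency after deprivation is measured from the window start (the end of the
SD episode) to the first sleep-bout onset; a bout already in progress at
the window start counts as onset at the start, and windows with no onset
are reported censored at the window length rather than dropped. Whether the
original MATLAB tooling treated in-progress bouts and censoring this way is
not documented; we fix one convention and flag it.

## Protocols

`make_full_ssd()` builds 24 episodes of 150 min SD + 270 min rebound on a
420 min cycle; episode `k` has rebound onset `(first_onset_zt + 7k) mod 24`,
and because gcd(7, 24) = 1 the 24 onsets tile all 24 one-hour residue
classes (`validate_schedule()` verifies this computationally). The default
`first_onset_zt = 4.5` follows the protocol's worked example; the exact
phase of the very first episode is not stated in the source material, so it
is a configurable assumption. The abridged protocol places the stimulus at
ZT0, ZT8 and ZT23 of the first deprivation day, ZT7 of the next and ZT6 of
the third, i.e. rebound onsets {2.5, 10.5, 1.5, 9.5, 8.5}.

Baseline is the two full undisturbed days preceding the first deprivation
day. For any clock window `[zt_a, zt_b)` the baseline reference is the mean
over those two days of sleep in that window evaluated *circularly within
each 24 h day*. This matters for windows that wrap past midnight: the
wrapped portion is taken from the same baseline day rather than spilling
into the first deprivation day.

## Rebound metrics and the efficiency filter

Per fly and episode: sleep lost = baseline SD-window sleep − SD-window
sleep; sleep gain = rebound-window sleep − baseline rebound-window sleep;
efficiency = lost / baseline (undefined at zero baseline); plus latency.
The inclusion filter retains a fly only if efficiency exceeds 0.9 at every
episode with nonzero baseline SD-window sleep. Two readings of "at each SD
interval" are possible — excluding whole flies or individual fly × episode
records; both are implemented (`scope = "fly"` is the default, matching the
plainer reading). Zero-baseline episodes impose no constraint: one cannot
deprive sleep that would not have occurred; such records are logged.

## Circadian profiles and anticipation

`eduction()` folds activity onto a 24 h axis (mean counts per clock bin
over flies × days, default 30 min bins); `baseline_sleep_profile()` does
the same for sleep minutes and reports total daily sleep. The anticipation
index is

`AI = (A_near − A_far) / (A_near + A_far)`

with `A_near` the summed activity in the 3 h before a light transition and
`A_far` the 3 h before that (mirrored at ZT12 for lights-off). The exact
index behind published anticipation tables is cited to external software
and not reproducible from the text; we chose this normalized contrast
because published values are small, signed, and bounded well inside
[−1, 1], which a ratio-style index cannot produce. It is dimensionless,
invariant to uniform rescaling of counts, and its window lengths are
configurable. Published anticipation values are therefore *not* treated as
recomputable targets.

## Heatmaps, matching and statistics

The rebound heatmap has one row per rebound-onset ZT and nine 30-min
post-SD columns of cohort mean sleep. Abridged protocols observe only five
rows; missing rows are filled by column-wise linear interpolation along the
onset-ZT axis, treated circularly by default because ZT is periodic (the
original figures state only "linear interpolation"; a clamped mode is
provided). Observed rows are never modified, and on a complete 24-row
protocol interpolation is the identity.

Morning/evening comparisons must control two confounds: baseline sleep in
the rebound window and the amount of sleep deprived.
`match_morning_evening()` minimizes
`w1·|Δbaseline|/s_b + w2·|Δlost|/s_l` over morning ([0, 6) ZT) × evening
([6, 12) ZT) candidate pairs, with each delta standardized by the spread of
that quantity across candidates, equal weights by default (the original
criterion is described only qualitatively), absolute tolerances as a hard
gate, and deterministic tie-breaks (smaller baseline delta, then earlier
morning, then earlier evening). An inadmissible instance returns an
explicit no-match result rather than an error.

The statistical layer mirrors the study's tests and nothing more: paired
two-sided t (flies paired with themselves across time points), one-way
ANOVA with Tukey HSD as the only multiplicity correction, and OLS
regression of per-episode mean gain on episode index for protocol-long
trends. Degenerate inputs (zero-variance differences, n < 2, exact fits)
are flagged, not raised.

## The synthetic cohort generator

`simulate_cohort()` is a bout-based alternating-renewal model, not a
per-minute Bernoulli process, for one decisive reason: sleep bouts have a
hard 5-min floor and wake minutes always emit `>= 1` count, so the 5-min
scoring rule recovers the simulated state *exactly*. Injected quantities
are therefore not distorted by scoring, which makes parameter-recovery
tests clean.

Mechanics per fly: wake/sleep bouts alternate with means
`mu_w = wake_mean0 · C(zt) / (1 + w·P)` and
`mu_s = 5 + sleep_mean0 · (1 + w·P) / C(zt)` (geometric tails), where
`C(zt)` is a circadian wake gate with circular Gaussian peaks at ZT0 and
ZT12 over a positive floor, and `P` is sleep pressure (`+alpha` per wake
minute, `×(1−beta)` per sleep minute). During deprivation windows each
minute is independently forced awake with probability `sd_efficacy`
(default 0.99), abstracting the ~20 s vibration train that
`stimulus_times()` generates explicitly. Each fly runs on an RNG substream
derived from `(seed, fly)`, so enlarging a cohort never perturbs existing
flies.

Defaults were fixed once from the qualitative features of wild-type female
behavior the protocol assumes: bimodal activity with low sleep after
lights-on and before lights-off, consolidated night sleep, total daily
sleep a substantial fraction of the day, and comparable morning/evening
baseline sleep in the probed rebound windows. The shipped defaults (gate
floor 0.25, morning peak 1.8 with sigma 2.6 h, evening peak 1.3 with sigma
1.5 h, `wake_mean0` 60 min, `sleep_mean0` 18 min, `alpha` 1, `beta` 0.03,
`weight` 0.005, activity rate 2 counts/min) give roughly 710 min of daily
sleep with expected baseline sleep of ~94 min in the ZT1.5–6 window and
~106 min in ZT9.5–14 — both leaving the default injected gains feasible.
These are plausibility targets, not fits; the gate shape is not an
empirical claim about any real cohort.

**Gain injection.** In `gain_injection` mode, rebound windows whose onset
appears in `gain_profile` draw a total window sleep `S` with expectation
exactly `B(zt) + g(zt)`: `S = 5 + Binomial(265, (T−5)/265)` for targets
`T >= 5` (a 0/5 mixture below), partitioned into bouts of `>= 5` min at
random positions. `B(zt)`, the mechanistic model's expected baseline sleep
in that clock window, is estimated by a fixed-seed simulation
(`expected_baseline_sleep()`, default 256 flies × 2 days, seed 8191,
cached); using a constant seed makes `B` a deterministic function of the
model and keeps the estimate independent of any particular cohort. The
pipeline's expected measured gain at an injected onset then equals `g(zt)`
by construction. Episodes not listed in the profile stay on the mechanistic
process, which keeps every injection feasible (`B + g <= 270`). The default
profile injects 133 min at ZT1.5 and 51 min at ZT9.5 — a greater-than-
twofold morning/evening asymmetry for the pipeline to detect. Infeasible
profiles are a configuration error, not a silent clamp.

## What passing tests do and do not show

The generator emulates minute-resolution counts, circadian bimodality,
consolidated bouts, near-complete forced wakefulness under stimulation, and
a controllable time-of-day rebound gain. It does **not** emulate
inter-individual parameter heterogeneity, stress effects of prolonged
stimulation, arousal-threshold dynamics, position-dependent beam-crossing
biases, or death/escape artifacts in real monitors. Recovery of injected
gains therefore validates the *pipeline arithmetic and statistics*, not any
biological claim about real flies.

## Numerical and design choices, briefly

- Time is 0-based minutes; all windows half-open; ZT in decimal hours on a
  minute grid.
- DAM records with a non-valid status are dropped and counted; the
  resulting holes are surfaced by `validate_dam()` and are an integrity
  error for scoring — never silently filled. How the original study handled
  acquisition gaps is undocumented; dropping is the conservative choice.
- Monitor files are written with locale-independent month names and LF
  endings; writing is byte-stable and round-trips exactly.
- Heatmap interpolation wraps circularly by default (ZT is periodic);
  clamped interpolation is available for comparison.
- Test problem sizes: module tests use 4–24-fly cohorts on the abridged
  protocol; acceptance-style recovery runs use 32-fly cohorts on the full
  protocol with a 256-fly baseline-expectation estimate, sizes at which the
  Monte-Carlo error of the recovered gains is a few minutes.
- Known limitations: no mixed-effects or survival treatment of latency
  (censoring is flagged only), no DD phase re-estimation, single-beam
  monitors only, and per-fly (not per-record) exclusion as the default
  filter reading.
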