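---
title: "The somnus intervention engine: models, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The somnus intervention engine: models, calibration and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somnus)
```

somnus re-creates, at desk scale, the decision logic of a smartphone app in
which a virtual agent screens users for insomnia complaints and guides a
two-step behavioral intervention. This vignette is the package's account of
the underlying models, the calibration of the synthetic cohort, and the
choices made where the design was genuinely open.

## Screening instrument and protocol thresholds

The Insomnia Severity Index (ISI) is a 7-item questionnaire, each item on a
0--4 Likert scale, so the total spans 0--28. The engine uses the standard
clinical bands — 0--7 none, 8--14 subthreshold, 15--21 moderate, 22--28
severe — and two protocol thresholds derived from them: a total **above 14**
makes the user eligible for the intervention program, and a total **above
21** after the final interview indicates referral to a sleep specialist.
The two rules are deliberately expressed as strict inequalities on the
integer total (`> 14`, `> 21`), which makes the referral rule exactly
equivalent to membership of the severe band (22--28); `classify_isi()`
checks all 29 totals exhaustively in the test suite.

The acceptance (usability, satisfaction) and trust (credibility,
benevolence) instruments are scored as **per-item means**, so the
positivity thresholds live on the item scale: satisfaction is positive
strictly above 3 of 5, credibility strictly above 1 of 3, and benevolence
when the mean reaches the top two agreement categories of a 5-point scale.
The exact item counts and scales of these instruments are not fixed by the
engine; `aes_config()`/`etq_config()` default to 6 items (3 per subscale)
and are fully overridable, because only the subscore thresholds — not the
item lists — are contractual.

## The sleep diary and its identities

One diary entry records the evening's calendar date, three clock times
(intention to sleep, final awakening, arising) and three reports (sleep
onset latency SOL, number of awakenings NWAK, wake after sleep onset WASO).
From these, `derive_night()` computes

* TIB = arise − try-to-sleep (time in bed),
* TWAK = arise − final awakening (terminal wakefulness),
* TST = TIB − SOL − WASO − TWAK (total sleep time), and
* SE = 100 × TST / TIB (sleep efficiency, %).

TST and SE are *always derived, never entered*, and the identity is kept
exact by **rejecting** (not clamping) any entry whose reported wakefulness
exceeds the in-bed interval; rejection reasons are surfaced row-by-row by
the CSV reader.

Clock times carry no date, so the engine anchors them with a **noon rule**:
a clock time at or after 12:00 belongs to the evening of the entry's date,
one before 12:00 to the next morning. This resolves both early-evening and
post-midnight bedtimes without extra flags, and restricts a night to the
noon-to-noon window around its date — an in-bed interval must be shorter
than 24 h, which is also the simulator's constraint when it draws nights.
A metamorphic test shifts all clocks by one hour across midnight and
verifies that every derived duration is unchanged.

Durations are handled internally as real minutes; hh:mm formatting (minutes
rounded half-up) and the one-decimal SE string exist only in the
presentation layer (`make_feedback()`).

## Protocol state machine

The interaction flow is an explicit state machine (`advance()`,
`transition_table()`): screening interview → either a fixed three-item
sleep-hygiene bundle (total ≤ 14; the session then terminates) or the
Step-1 diary week; the follow-up interview request is emitted exactly when
the 7th validated night arrives; after Interview 2 the user enters Step 2,
10 elapsed days of personalized recommendations (diary entries remain legal
and are accepted throughout, but do not gate progress); after Interview 3 a
total above 21 routes to referral, anything else to autonomous use.

Open points the machine resolves explicitly:

* Interviews 2 and 3 are modeled as *due* states that wait for an
  `isi_completed` event — users may delay, and no timeout is imposed.
* Interview 3 requires all 10 Step-2 days to have elapsed.
* Dropout is an explicit event, legal from every non-terminal stage;
  terminal stages (hygiene-advised, autonomous use, referred, dropout)
  absorb.

Sessions serialize to JSON and are *reconstructed by replaying their event
log through the machine itself*, so a stored session is accepted only if
its history is legal; replay determinism is tested. The safety properties —
no path to Step 2 with fewer than 7 diary nights, at most three ISI
occasions in strict order, absorbing terminals — are model-checked with
10^4 randomized event sequences (length 60, dropout down-weighted so the
walk reaches the deep stages including referral).

## Recommendation rules

The exact condition table of the original app's personalized
recommendations is not publicly available, so the shipped defaults are an
explicit reconstruction from standard behavioral sleep-medicine heuristics:
time-in-bed restriction when SE < 85% with TIB > 9 h, stimulus control when
mean SOL > 30 min, a fixed rise time when TWAK > 30 min, a wind-down
routine when NWAK > 2 or WASO > 30 min, stimulant limits when efficiency is
low with elevated SOL, and a specialist note when the ISI remains severe.
They live entirely in `inst/extdata/default_rules.yaml` so a different rule
table replaces them without any code change, and they should not be read as
the original app's rules.

Conditions are written in a deliberately small expression grammar —
indicator names, numeric literals, comparisons, `and`/`or`/`not`,
arithmetic — validated by an AST whitelist before evaluation in a bare
environment; no function calls ever execute from config. Advice ordering is
by (priority, rule id), never file order, so rule files can be reorganized
freely; when no rule fires the generic hygiene items are returned as the
personalized bundle's fallback, since an eligible user must never leave
empty-handed.

## Statistics layer

The study-statistics module is implemented from the defining formulas:
Pearson chi-square with expected counts from the margins and **no
continuity correction** (the uncorrected statistic reproduces the published
2×2 anchors 10.71 and 0.343 exactly, so uncorrected is the dialect of
record), pooled-variance two-sample t with df = n₁ + n₂ − 2, paired t on
difference scores, and Pearson correlation with its t-based test. Base R's
`chisq.test`, `t.test` and `cor.test` appear in the test suite only as
independent cross-checks of these implementations. p-values are computed
exactly; "<.001"-style formatting is a report-layer concern.

One family of published subgroup statistics (the severity-stratified
comparisons) does not recompute from its own printed cell counts — e.g. the
gender 2×2 yields 32.17 against a printed 31.91, plausibly a missing-data
denominator issue — so those values are documented as non-anchors: the
engine asserts self-consistency with a brute-force oracle instead of
chasing the printed numbers.

## The synthetic cohort: what it emulates

`default_config()` encodes the study conditions: 2069 downloaders; a 76%
screening completion probability; eligibility (ISI > 14) with probability
0.491 *conditional on screening* (the published 49.1% uses screened users
as denominator); Step-1 completion at 21.5% of eligible and Step-2 at 28.3%
of Step-1 completers, each drawn stage-wise Bernoulli so the funnel is
monotone by construction.

**Baseline ISI** is a two-component truncated normal tied to the
eligibility draw: subclinical users on 0--14 (mean 10.02, SD 3.42),
clinical users on 15--28 (mean 18.2, SD 2.74), rounded to integers within
the stratum so eligibility is exact. Note a deliberate property: Step-1
completers are a random subset of the clinical stratum, and the *truncated*
clinical distribution has mean ≈ 18.8, close to the published baseline mean
of Step-1 completers (18.56) without any extra selection mechanism.

**Outcome trajectories.** The Step-1 ISI change is normal with mean −2.57
(the published 18.56 → 15.99 drop) and SD 4.20, obtained by inverting the
paired-t formula from the published t of 7.88 on 165 df; the Step-2 change
has mean −0.96 and SD 4.63 (from t = 1.42, 46 df). These SDs are inferences
— the change-score SDs are not printed — and are flagged as such. Follow-up
totals are clamped to [0, 28] and rounded to integers (an ISI total is a
sum of integer items; the clamping bias is negligible at these effect
sizes). In the noiseless limit (`sd_delta = 0`) the generator returns the
exact `baseline + mean_delta` without rounding, so the closed-form limit
holds exactly and is tested.

**Diaries.** For Step-1 completers, each indicator's nightly mean drifts
linearly so that nights 1--2 and 6--7 average exactly to the published
first-2-night and last-2-night calibration values (TIB 8:56:45 → 8:40:27,
SOL 1:31:38 → 0:58:37, WASO 0:48:57 → 0:42:01, TWAK 0:58:11 → 0:39:43,
NWAK 1.89 → 1.67); the 10 Step-2 nights sit at the published post-Step-2
means, held constant for lack of a printed per-night trajectory. Components
are drawn and TST/SE are always derived, so the diary identity holds by
construction and every simulated night passes the validator.

Distributional choices worth stating:

* **Wake components (SOL, WASO, TWAK) are gamma-distributed**, matched to
  the calibration mean and SD. At the published dispersions (SOL SD ≈ 159
  min around a 92-min mean) a normal truncated at zero would inflate the
  mean by roughly 80% and destroy parameter recovery; the gamma has the
  right support and preserves the mean exactly.
* **NWAK is Poisson** with the drifting mean — integer counts by
  construction, variance close to the published SD.
* **TIB is normal**, with the night constrained to (1 h, 22 h) and to the
  noon-to-noon window; jointly invalid nights (wakefulness ≥ TIB, or the
  interval leaving the window) are redrawn. This validity censoring clips
  the heavy SOL tail, so the simulated SOL means sit below their configured
  values; sleep efficiency — the quantity the calibration is held to —
  is essentially unaffected (the published first-2-night columns are
  themselves not identity-consistent, differing by ~27 min between printed
  TST and TIB − SOL − WASO − TWAK, so the wake-component means cannot all
  be matched simultaneously under an exact identity).
* **Demographics** are drawn conditionally on the responder flag from the
  two published marginal distributions (age, gender, education,
  confinement, health-care-professional status), which reproduces both
  columns and the direction of the responder/non-responder differences
  directly. Addiction covariates are gamma draws per severity stratum.
  Technology familiarity uses a configurable categorical distribution
  (default 10/30/60%), a value the study does not print.

## What passing tests do and do not show

The simulator emulates marginal distributions, stage-wise adherence and
mean trajectories. It does not model within-user night-to-night
autocorrelation, weekday effects, informative dropout (dropout is
independent of severity given the stage), item-level ISI psychometrics
(items are a random decomposition of the total), or seasonal/campaign
effects on recruitment. Calibration-recovery tests therefore validate the
engine's arithmetic and the generator's faithfulness to its configuration —
they are not evidence about real users.

## Numerical and testing choices

Monte-Carlo checks run 20 replicate cohorts of 2069 users (the study's
cohort size), a scale at which every configured probability and mean is
recovered well within its tolerance band while the full suite stays fast;
the binomial standard error on the screening fraction at this scale is
under 0.1 percentage points. All randomness flows through R's default RNG
from a single seed per cohort; identical (config, seed) pairs reproduce
byte-identical cohorts, which the round-trip and manifest tests verify via
MD5 hashes. Degenerate inputs are rejected loudly (zero-variance paired t,
zero expected cells, over-reported wakefulness, illegal protocol events)
rather than patched, with one report-layer exception: `emit_study_tables()`
prints a zero statistic for a constant-difference paired comparison, so an
effect-free cohort tabulates as "no change" instead of erroring.

## Known limitations

* The default recommendation rules are reconstructions; conclusions about
  the original app's advice logic cannot be drawn from them.
* The change-score SDs are inverted from printed t statistics, not
  observed; any real-data reuse should re-estimate them.
* Diary SOL/WASO/TWAK means are reproduced only up to validity censoring
  (see above); SE and TIB are the calibrated quantities.
* The engine is single-user-at-a-time for protocol purposes; there is no
  scheduling, notification or concurrency layer.
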