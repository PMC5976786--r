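---
title: "Engagement-related behavior in dementia dyads: coding, reliability, and the EMODEB path model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Engagement-related behavior in dementia dyads: coding, reliability, and the EMODEB path model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(emodeb)
library(dplyr)
```

## The problem and the data model

People with moderate dementia often cannot report their own engagement in an
activity, so engagement has to be read off the body. The ELICSE coding scheme
operationalizes this through Laban Movement Analysis: observable behavior is
split into three mutually exclusive **body-part groups** — head, torso,
arms/hands — and within each group, *directional shape* behaviors are labeled
by the **focus** they address: the partner, the facilitator/experimenter, the
activity artifact ("game": board games during cognitive stimulation, the robot
during free play), or none of these. Affect appears in two ways: as
positive/negative/neutral **modifiers** superimposed on directional behaviors,
and as non-directional signs-of-affection gestures of the arms/hands
(`SOApos`/`SOAneg`) that carry their valence intrinsically.

An annotation session is therefore a set of **behavior streams**, one per
`(session, participant, coder, group)`, each a list of timed states. Two
invariants define a valid stream: states within a group never overlap
(mutual exclusivity), and the states jointly cover the observation from start
to end (exhaustiveness, via each group's "none" behavior). `validate_streams()`
enforces both; nothing is silently repaired, because coding errors in this
kind of data should surface, not vanish. Intervals are half-open
`[start, stop)`, which makes mutual exclusivity decidable at shared
boundaries: the boundary instant belongs to the following event. The default
gap tolerance is 0.04 s — a single video frame at 25 fps, the natural
granularity of frame-accurate annotation tools — and is configurable.

Two conventions were genuinely open and are fixed here as package decisions:

* The textual scheme distinguishes facilitator and experimenter, but every
  scored behavior merges them (`GFE`, `RoFE`), so the package uses four
  operational foci.
* Modifiers on "none" behaviors are forced to neutral: affect is only defined
  as a coloring of a directional behavior.

## Inter-rater reliability with a temporal tolerance window

Agreement between two coders is computed on time-discretized streams (bins
labeled by the state at the bin midpoint; default resolution 0.5 s). Because
human coders disagree about *when* a behavior starts more often than about
*what* it is, agreement uses a tolerance window, default 3 s: at bin `t`,
coder B is credited with coder A's state if B shows that state anywhere in
`t ± 3 s`, otherwise B's own state stands. The commercial annotation tools
that popularized this comparison do not document their alignment algorithm,
so the package defines its own — deterministic, bin-based, and symmetrized by
averaging the A-versus-B tally with the transpose of the B-versus-A tally, so
neither coder is privileged. Two properties anchor the definition and are
tested: at zero tolerance it reduces *exactly* to the textbook Cohen's kappa
on the raw bin pairs, and it is invariant under swapping the coders.

Reporting follows the field's frequency rules: per-behavior kappas are
suppressed for behaviors with mean duration below 1% of the session (kappa is
unstable for very rare states) and flagged for caution below 5%. The global
kappa pools the three groups' confusion matrices block-diagonally, which
keeps each group's marginals intact while yielding a single chance-corrected
figure for the whole scheme. An undefined kappa (chance agreement 1, e.g.
both coders coding a single identical state throughout) is reported as a
flag, never coerced to 0 or 1.

One caveat: for bins where the *other* coder's state never appears in the
reference coder's window, the symmetrized matrix retains half of that
disagreement, so windowed agreement is not always exactly 1 even when each
directional comparison is; this is the cost of symmetry and is documented
rather than hidden.

## From streams to the six engagement scores

`duration_table()` turns validated streams into percentages of observation
duration per behavior and per modifier valence; within each group these sum
to 100. `reduce_scores()` applies the fixed reduction: behaviors directed
toward the game or the partner are engagement-related, those toward the
facilitator/experimenter or toward none are disengagement-related, giving one
score per body part in `[-100, 100]`:

* `GAct  = (GP + GG) − (GFE + NoneH)`
* `LTAct = (LIP + NRLTG) − NoneT`
* `RoAct = (RoP + MG) − (RoFE + NoneAH)`

and three affect scores subtracting negatively from positively modified time
(`GAct_gsup`, `LTAct_postsup`, `RoAct_qogest`, the last also adding the
whole-behavior percentages of `SOApos`/`SOAneg`). Two details are followed
literally because the reduction table states them: the SOA gestures enter
`RoAct_qogest` but not `RoAct` (while still counting in the arms/hands 100%),
and neutral time never enters an affect score. The `[-100, 100]` range is a
theorem given group sums of 100; the test suite checks it on randomized valid
tables.

Applied to the published mean duration percentages shipped with the package,
the reduction gives `GAct` = 81.30 for game-based cognitive stimulation and
74.00 for robot-based free play — the package's own recomputation of those
summary figures.

## Engagement levels, affect intensity, and body-part organization

The central empirical observation behind the model is that the head leads:
movements toward the game or the partner are initiated by the head and
sequenced into the torso and arms/hands. `classify_instant()` therefore
treats a focus as *engaged* only when the head addresses it; an instant where
only torso and arms address a focus is level 0 (such configurations are rare
and visible in the diagnostics of the per-bin timeline). Given an engaged
head focus, the level counts recruited parts: 1 head only (passive attention
/ social acknowledgement), 2 head+torso (attentional/social readiness), 3
head+arms (reduced active participation/engagement), 4 all three (full
active). Reduced-active ranks above readiness, following the ordering of the
four intensity levels rather than the narrative aside that calls readiness
merely "a step forward" from passive. Mixed foci follow the head: other
parts count only toward the head's focus, so ties cannot occur.

Affect intensity is the signed count of engaged parts with positive minus
negative modifiers, an integer in `[-3, +3]`; the weighted engagement score
sums part weights (defaults 0.50/0.10/0.40 for head/torso/arms, reflecting
the parts' importance in the model) over parts at the engaged focus, so the
default levels map to 0.50 < 0.60 < 0.90 < 1.00.

`detect_patterns()` recovers the Laban body-part organizations: *successive*
(head, then torso within a lag, then arms within a further lag), *sequential*
(head then arms with no torso onset between), *simultaneous* (all onsets
within a small window), and *space hold* (every recruited part keeps the
focus for a minimum duration after the organization completes, the arms
typically continuing to gesture — an ongoing manipulation counts as
gesturing, so a statically held full engagement still registers the hold).
The thresholds (simultaneity 0.5 s, lag 3 s, hold 5 s) are engineering
defaults exposed in the interface; no published values exist for them. The
planted-pattern tests only assert recovery when generated lags respect these
thresholds.

## The EMODEB path model and its estimation

The model is a fixed recursive system on the six scores: 9 directed edges,
`GAct` exogenous, uncorrelated errors. With `p = 6` variables there are 21
covariance moments and `9 + 6 = 15` free parameters (one coefficient per
edge, one variance per variable), so `df = 6`.

`fit_path_model()` minimizes the maximum-likelihood discrepancy

$$F_{ML}(\theta) = \ln|\Sigma(\theta)| + \mathrm{tr}(S\,\Sigma(\theta)^{-1}) - \ln|S| - p$$

with `S` the sample covariance on the `n − 1` denominator and
`Σ(θ) = (I−B)^{-1} Ψ (I−B)^{-T}` the implied covariance of the recursive
system; means are unstructured and ignored. Numerics: variances are
log-parameterized (positivity for free), optimization is BFGS started from
per-node least-squares coefficients and marginal variances, and convergence
requires a gradient norm below 1e−6. The model chi-square is `(n−1) F_ML` at
the optimum; standard errors come from the inverse observed information
`(n−1)/2 · H(F_ML)` (delta method for the variances); standardized estimates
use the model-implied standard deviations.

For a recursive DAG with uncorrelated errors the ML coefficients coincide
with per-equation OLS — the likelihood factorizes over nodes. That
equivalence is *the* correctness oracle for the optimizer: the suite checks
agreement to 1e−6 on 100 random datasets, and calibration of the chi-square
(mean near the df, 5% rejection near nominal) on data simulated from the
model's own structure at n = 77.

Incremental fit indices compare against the independence null (all
covariances zero, variances free, `df_null = p(p−1)/2 = 15`): RMSEA, NFI,
CFI, RFI, and PNFI with the standard James–Mulaik–Brent parsimony ratio
`df/df_null`. Published figures for this model appear to use a different
parsimony ratio for PNFI; the package implements the standard formula and
notes the convention in the fit object rather than reverse-engineering a
proprietary implementation. Similarly, published estimate/SE/CR columns for
this model are mutually inconsistent (suggesting mixed
standardized/unstandardized conventions), so both unstandardized and
standardized estimates are always reported side by side.

Before fitting, `mahalanobis_filter()` screens multivariate outliers —
path analysis by ML is sensitive to non-normality — removing either a fixed
number of farthest rows (the design used k = 7 of 84, leaving n = 77) or
rows beyond a chi-square quantile. Whole rows are excluded (listwise), and
ties break deterministically by row order. Follow-up simple regressions are
available via `follow_up_regression()`, which reports the standardized slope
with `df = n − 2` (at β = 0.246 and n = 77 the closed form gives t = 2.198).

## The synthetic-data generator

No annotation data for this population is publicly deposited, so the package
generates its own at two levels.

**Score level** (`simulate_scores()`): draws `GAct` from its marginal and
propagates through the linear system in topological order. Defaults encode
the study conditions: n = 84 participant-sessions, the published path
coefficients as generating values, an exogenous mean of 77.65 (midway
between the two activities' recomputed `GAct` means) with SD 15, and error
SDs of 30/25 for the torso and arms scores and 6 for the affect scores —
chosen once to mirror the wide spread of postural scores versus the rarity
of affect, and not revisited. Clipping to `[-100, 100]` is off by default
because truncation bends the linear structure the estimator tests rely on.

**Stream level** (`simulate_session_streams()`): a 22-minute session (within
the study's 20–25 min range) where the head focus follows a semi-Markov
chain with gamma dwell times (shape 2); on engaged episodes the torso
follows with probability 0.8 and the arms with probability 0.9 after
uniform 0.5–2.5 s lags — the head-led successive organization. Dwell means
are calibrated so time budgets match the published duration percentages
(head at game ≈ 88% in cognitive games, ≈ 73% in robot play; with a uniform
jump chain, occupancies are proportional to mean dwells, which makes the
calibration one-line). Affect bouts are rare in cognitive games (0.2/min)
and frequent in robot play (2/min), mostly positive (0.9), matching the
qualitative description of the two activities; short signs-of-affection
gestures are carved into the arms stream at ≈ 0.05/min. A per-participant
engagement propensity (log-normal, SD 0.35) creates between-subject
variance. Generated streams satisfy the validator's invariants by
construction — a property fuzz-tested rather than assumed.

**Two-coder noise** (`corrupt_streams()`): boundary jitter (truncated,
order-preserving), whole-event label substitution, and absorption of events
below a miss threshold, followed by repair to exclusivity/coverage. Zero
noise reproduces the input exactly; kappa is then 1 by construction, and
expected kappa falls monotonically with jitter — both tested.

What the generator does *not* emulate: verbal and vocal behavior,
within-couple dependence (an optional shared propensity is deliberately not
the default, since no dependence structure was reported), coder drift over
sessions, and the long-tailed idiosyncrasies of real dementia behavior.
Passing tests therefore demonstrate that the pipeline's arithmetic,
reliability machinery and estimator behave correctly under the stated
statistical structure — not that the scheme itself is valid for new
populations, which requires real double-coded video.

## Problem sizes and reproducibility

The test suite and the acceptance script size their simulations to what the
statistics require rather than to realism: reliability properties use 2–5
minute sessions (a few hundred bins are ample for kappa), estimator checks
use 100–500 replicates at the study's n = 77, and the full-cohort pipeline
runs once per seed at the paper-sized 42 × 2 design. All randomness flows
from explicit seeds; `scripts/acceptance.R --seed N --out results.json`
reproduces every reported number from a fresh cohort.

## A worked example

```{r example, eval = FALSE}
cohort <- simulate_cohort(paper_sized = TRUE, seed = 42)
scores <- score_table(cohort$events,
  durations = cohort$sessions, activities = cohort$sessions
)
fit <- scores |>
  mahalanobis_filter(k = 7) |>
  getElement("scores") |>
  fit_path_model()
glance(fit)
tidy(fit)
```

## Known limitations

* The tolerant-agreement definition is one defensible reading of a tool
  behavior that was never published; kappas computed here are comparable
  within the package, not guaranteed to match proprietary implementations.
* Only recursive path models on observed variables are supported — no latent
  variables, correlated errors, mean structures, or multi-group fitting.
* Exactly two coders; Fleiss/Krippendorff generalizations are out of scope.
* The scheme ships with the dementia-dyad inventory; other activity settings
  should extend it via `as_elicse_scheme()` / `read_scheme()`, and the
  reliability rules will follow the declared inventory.
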