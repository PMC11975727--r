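---
title: "Methods: simulation design, outcome rules, and the ensemble model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulation design, outcome rules, and the ensemble model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the scientific choices behind `htnrec`: what the
synthetic cohort emulates, how the treatment-success label is defined, how
the ensemble and its confidence tier work, and where the design was
genuinely open.

## The estimand and its assumptions

The unit of analysis is a patient's *initial antihypertensive regimen*: the
set of ingredient–daily-dose pairs started within a 14-day grace window of
the first antihypertensive prescription. The outcome is binary treatment
success — blood-pressure control per age-dependent JNC 8 goals for at least
a year on that regimen, with no moderate or severe adverse effect.

The model estimates `P(success | x, t)` for all candidate regimens `t`, not
only the prescribed one, which is a causal quantity under three conditions:

* **Consistency** — treatments are unambiguous because everything is
  normalized to ingredient + total daily dose before modelling; a
  combination pill and the equivalent separate pills produce identical
  regimens (this is tested as an invariant).
* **Exchangeability** — all covariates plausibly driving both prescription
  and outcome are model inputs, and completeness is enforced: a missing
  feature is a hard error, never an imputation.
* **Positivity** — the confidence tier demotes candidate regimens with
  little or no training support among feature-similar patients, so
  recommendations are never served from regions where a comparison was
  never observed.

## Synthetic cohort: what it emulates

The generator (`generate_cohort()`) draws covariates from published-style
primary-care marginals: a six-band age mixture (mean near 60.8 years), 49.3%
female, race mix 92.5/3.3/4.2% White/Black/Other, seven comorbidity
prevalences (tachyarrhythmia 29.4% … gout 3.3%), pretreatment SBP
137.8 ± 18.9 mm Hg, DBP 81.0 ± 11.5 mm Hg, and log-normal creatinine with
mean 1.0 mg/dL. The initial regimen is drawn from per-class prescription
likelihoods (ACE inhibitor 26.5%, β-blocker 13.9%, thiazide 12.6%, CCB
11.2%, ARB 8.6%, ACEi–thiazide combination 5.4%), with the residual 21.8%
split across an `other` class and four further two-agent regimens so that
78% of patients start on a single agent.

The planted response surface is logistic:

```
logit P(success | x, t) = b[class(t)]
    + a[class] * (age - 60)/10
    + r_black[class] * 1{Black} + r_other[class] * 1{Other}
    + sum_m c[m, class] * comorbidity_m
    - 0.30 * (SBP - 140)/10
    + d[class] * 1{high dose}
```

Age slopes favour ACE inhibitors below 60 and thiazides above; race shifts
favour thiazide/CCB and disfavour ACEi/ARB for Black patients; comorbidity
shifts favour ACEi/ARB in chronic kidney disease, β-blockade in heart
failure (and against it in asthma), and against thiazides in gout. The
global systolic slope (−0.30 per 10 mm Hg above 140) encodes that severe
hypertension is harder to control and gives the surface individual-level
spread. Dose terms default to zero but are plumbed through. Creatinine, sex
and three comorbidities carry zero coefficients on purpose: they are the
probes for the exchangeability check (shuffling them must not move
cell-level predictions beyond estimation noise).

Per-class intercepts `b` are not free: they were solved once by Monte-Carlo
root finding (2 × 10⁶ covariate draws per class) so that the expected
success rate per class equals the configured targets (39.1% ACEi, 30.9%
β-blocker, 38.5% thiazide, 29.6% CCB, 35.4% ARB, 44.5% ACEi–thiazide, and
residual-class targets whose likelihood-weighted overall mean is 33.8%) and
then frozen into the default configuration. The residual classes must
average about 25% success for the marginal to close — an arithmetic
consequence of the published per-class rates, not a tunable.

Each patient's realized success is one Bernoulli draw per candidate regimen
from a dedicated random substream (an avalanche-hashed seed per patient,
L'Ecuyer-CMRG streams). Linearly spaced substream seeds were measurably
biased in their first draws (column means off by up to 0.012 at
n = 20,000), which propagated into class success rates; the hashed CMRG
scheme removes this. Record-level noise runs on a separate seeded stream, so
a fixed seed reproduces the bundle byte for byte.

Trajectories are then written so the rule-based labeler recovers the
realized state: successes get maintained prescriptions and window readings
whose sample mean is drawn strictly inside the control limits (deviations
are centered and rescaled to a bounded range, so rounding can never cross a
threshold); failures draw a mechanism (high average 40%, threshold spike
12%, early discontinuation with high readings 10%, documented adverse
effect 12%, laboratory criteria 20%, hypotension/bradycardia 6%) and their
records violate exactly that rule. Moderate documented adverse effects end
the prescription within 30 days with probability 0.75, severe with 0.851.
Mild events are sprinkled independently of outcome and never end a
prescription. Configured fractions of patients are planted to violate each
inclusion rule (missing diagnosis, no prior care, late treatment, short
follow-up, missing baselines, incident diabetes) or to discontinue with
controlled pressures, so every cohort filter and the outcome-rule exclusion
are exercised at scale.

What the generator does **not** emulate: correlated comorbidity structure
(flags are independent, so the share with no comorbidity is lower than a
real cohort's), visit-process informativeness (readings are missing
completely at random within windows), secular trends, pharmacokinetics, and
any confounding by indication — treatment assignment is independent of
covariates. Passing tests therefore demonstrate that the machinery recovers
a known surface under clean conditions, not that it would overcome
real-world confounding.

## Outcome label

Blood-pressure control uses readings that survive the measurement filter
(non-invasive, sitting, arm, ambulatory context). The primary outcome window
is 6–12 months after the start of treatment (days 183–365); if it is empty
and the regimen is maintained, the earliest non-empty of 12–14, 14–18 and
18–24 months is used (days 366–426, 427–547, 548–730 — month windows are
mapped to fixed day counts; "9 months" is 270 days and "a year" 365
throughout, because calendar-month arithmetic is not reproducible). Control
means the window's mean SBP and DBP are strictly below the age-dependent
goals and no single reading exceeds the maxima. Age exactly 60 takes the
older branch (the guideline's own cutoff is ≥ 60), with age measured at
treatment start.

Adverse-effect failure is evaluated chronologically over the whole episode:
hypotension (< 90/< 60), bradycardia (HR < 50), creatinine rise > 30% over
the latest pre-treatment value, sodium outside (130, 150), potassium
outside (3.6, 5.1), fasting glucose > 120, or a documented moderate/severe
allergy-table event. Boundaries are exclusive exactly as written — potassium
5.1 and a creatinine ratio of exactly 1.30 are not failures. Episodes
discontinued before one year are failures when pre-discontinuation readings
(at least 14 days after start and 6 months before the end) were high, and
excluded when controlled, since year-long success is unobservable. Two
precedence conventions were needed where the rules are silent: a reading
past the maximum threshold is reported as the failure reason even when the
window average is also high, and same-day adverse events resolve in a fixed
criterion order (hypotension, bradycardia, creatinine, sodium, potassium,
glucose, documented event). The vectorized cohort labeler and the
per-episode labeler implement the same rules and are tested against each
other and against an independently coded brute-force rule walker.

## Ensemble and confidence tier

Members are single-hidden-layer feed-forward networks (`nnet`), each trained
on an independent 80% subsample with its own seed. Defaults — width 5,
weight decay 0.02, 250 iterations — were selected for recovery of the
planted surface at the default study size; the surface is a smooth logistic,
so small, well-regularized members generalize better here than wide ones.
The width, decay, iteration budget, member count and subsample fraction are
all configuration knobs, since the reference architecture is not public.
The median of member scores is the reported probability; bands use
linear-interpolation percentiles (R quantile type 7) at 10/25/75/90.

The confidence tier exists to filter positivity violations, and its
composition was a genuinely open design. Raw probability-scale dispersion
(p90 − p10) fails at this: its scale shrinks mechanically as predictions
approach 0 or 1, so "confident" collapses onto the near-zero predictions and
recall *falls* in the confident strata. The tier therefore ranks on
training support — the number of training episodes with the candidate
regimen inside the patient's race × 20-year-age-band neighborhood — with
cutoffs calibrated on training predictions to target tier fractions (41.8%
medium-or-high, 17.3% high), plus a veto demoting the most discordant 10%
of predictions by *normalized* dispersion, `(p90 − p10) / sqrt(p(1−p))`,
which approximates inverse effective support independently of the
probability level. Zero support is always low. Floors of 5 (medium) and
20 (high) supporting episodes apply regardless of calibration.

Classification uses a 0.5 threshold on the median (configurable). Class
scores aggregate regimen medians with within-class prescription weights;
weights must sum to one per class or the aggregation errors. Ranking ties
break by higher support, then lexicographic regimen id, so recommendations
are deterministic.

## Guideline engine

Chronic kidney disease (any race) permits ACEi/ARB; Black patients without
CKD thiazide/CCB; everyone else any of the four first-line classes. CKD
precedence over the race rule is a declared decision. For combinations, the
general and race rules require every component class to be permitted, while
under CKD it suffices that the combination contains an ACEi or ARB — also a
declared decision, since the source rules only say combinations are
"allowed". The full race × CKD × class-label behaviour is pinned by a
hand-written truth table shipped with the package.

## Problem sizes and numerical conventions

The reference study conditions are n = 20,000 simulated patients, a
1,000-patient validation split, and a 20-member ensemble; the full pipeline
runs in a few minutes on one CPU, and unit tests use cohorts of 500–2,000.
Percentages report to one decimal with half-even rounding. Undefined metrics
(zero denominators, classes with only excluded episodes) report `NA`, never
zero. Probability-vector validity is checked to 10⁻⁹; class-weight sums to
10⁻⁶. Degenerate inputs are first-class: empty-but-headered tables load,
single-reading windows and single-point curve grids work, all-one-class
training labels raise an error, and an all-filtered candidate list returns
an explicit no-confident-recommendation signal.

## Known limitations

The generator's clean separability means reported precision/recall levels
are specific to the planted world and should not be read as clinical
performance. Support counting uses coarse demographic neighborhoods; a
distance-based overlap measure would be finer-grained. The sig-text grammar
is closed by design — free-text prescriptions outside it are flagged, not
guessed. Long-term cardiovascular outcomes are out of scope; success is
one-year blood-pressure control.
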