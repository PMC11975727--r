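# htnrec

Individualized first-line hypertension management from longitudinal
EHR-style tables, within a causal (potential-outcomes) framing.

Roughly a third of newly diagnosed hypertensive patients achieve blood-pressure
control on their first antihypertensive regimen without a moderate or severe
adverse effect. Which regimen works best differs by age, race, baseline blood
pressure and comorbidity, yet guidelines (JNC 8) only narrow the choice to a
class set. `htnrec` is for biostatisticians and clinical-informatics
researchers who want a complete, testable pipeline for this problem:

* a **synthetic EHR generator** with a *known* (planted) treatment-response
  surface, calibrated so the labelled cohort reproduces realistic marginals
  (33.8% overall success; class likelihoods and per-class success rates of a
  primary-care training population), so every downstream stage can be scored
  against ground truth;
* **cohort construction**: new primary-hypertension diagnosis, established
  prior care, treatment within 270 days of diagnosis, ≥ 1 year follow-up,
  baseline blood pressure and creatinine, a measurable outcome; exclusions
  for incident diabetes/prediabetes and ingredient–dose pairs seen fewer than
  twice (iterated to a fixed point);
* **medication normalization** to ingredient + total daily dose (the
  consistency condition): RxNorm-style code mapping, combination-product
  decomposition, sig-text parsing (`"take 2 pills 3 times a day"`), and
  merged per-ingredient-dose timelines;
* **rule-based outcome labelling**: JNC 8 blood-pressure goals
  (mean < 140/90 and no reading > 160/90 under age 60; mean < 150/90 and no
  reading > 170/90 at 60+) over the 6–12-month window with 12–24-month
  fallbacks, plus adverse-effect failure criteria (hypotension, bradycardia,
  > 30% creatinine rise, dysnatremia, dyskalemia, elevated fasting glucose,
  documented moderate/severe adverse effects);
* an **ensemble success model**: 20 feed-forward members, each trained on an
  independent 80% subsample; the member-score median is the success
  probability and the 10/25/75/90 percentiles are its uncertainty bands;
* a **confidence tier** (low/medium/high) that implements the positivity
  filter: training-support cutoffs calibrated to target tier fractions, with
  a veto on ensemble dispersion normalized by `sqrt(p(1-p))`;
* the **JNC 8 first-line engine** and evaluation reports
  (precision/recall/F1, confidence-stratified metrics, class success tables,
  guideline agreement).

## Model

For patient covariates `x` (age, sex, race, pretreatment SBP/DBP, creatinine,
seven comorbidity flags) and a candidate regimen `t` (a set of
ingredient–daily-dose pairs), each ensemble member `m` estimates
`p_m(x, t) = P(success | x, t)`, where *success* means one year of
blood-pressure control on the initial regimen with no moderate or severe
adverse effect. The reported probability is the member median,

    p̂(x, t) = median{ p_1(x,t), …, p_20(x,t) },

with percentile bands from the same member scores. The recommendation is
`argmax_t p̂(x, t)` over candidates at or above a requested confidence tier;
class-level scores are prescription-probability-weighted means over the
regimens in a class. Causal interpretation rests on consistency (ingredient +
dose resolution), exchangeability (all treatment-correlated covariates are
model inputs; completeness is enforced — missing features are an error, never
imputed), and positivity (the confidence tier demotes candidates with little
or no support among feature-similar training patients).

## Worked example

```r
library(htnrec)

cfg <- generator_config(n_patients = 5000, seed = 1)
pl  <- run_pipeline(cfg, out_dir = tempfile("htnrec_"), n_validation = 500)
#> simulate: 5000 patients, 74292 vitals rows
#> build-cohort: 4804 of 5000 included
#> label: 1593 success / 3122 failure / 89 excluded
#> train: 20 members on 4221 episodes

glance(pl$report)
#> # A tibble: 1 × 6
#>   n_cases precision recall    f1 model_agreement physician_agreement
#>     <int>     <dbl>  <dbl> <dbl>           <dbl>               <dbl>
#> 1     494      54.3   22.9  32.2              91                  71
```

1593 / (1593 + 3122) = 33.8% of determinate episodes succeed — the marginal
the generator is calibrated to. On the 500 held-out patients the ensemble
predicts success of the actually prescribed regimen with 54.3% precision and
22.9% recall, and its top suggested class falls inside the JNC 8-permitted
set for 91% of patients (versus 71% for the simulated prescriptions).

Ranking candidate regimens for one patient:

```r
pt <- tibble::tibble(patient_id = 1L, age = 52, sex = "F", race = "White",
  pre_sbp = 150, pre_dbp = 92, creatinine = 0.9,
  tachyarrhythmia = FALSE, diabetes = FALSE, ihd = FALSE, asthma = FALSE,
  ckd = FALSE, chf = FALSE, gout = FALSE)
head(recommend(pl$ensemble, pt, min_tier = "medium"), 3)
#> # A tibble: 3 × 11
#>   patient_id treatment_id  median   p10   p25   p75   p90 …
#> 1          1 enalapril:10   0.378 0.250 0.305 0.459 0.528
#> 2          1 losartan:50    0.343 0.231 0.273 0.397 0.479
#> 3          1 enalapril:5    0.319 0.218 0.261 0.476 0.512
```

Each row is an ingredient–daily-dose candidate with its median predicted
success probability, percentile bands, training support, and confidence
tier. `success_curves()` + `autoplot()` draw the banded class-level curves
across age or baseline systolic pressure.

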