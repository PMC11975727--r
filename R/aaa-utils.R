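# Shared constants and small helpers.

# Day-count constants used throughout cohort construction and outcome
# labelling. Month-denominated windows are mapped to fixed day counts so the
# rules are calendar-free and reproducible.
DAYS_9_MONTHS <- 270L
DAYS_1_YEAR <- 365L
DAYS_6_MONTHS <- 183L
DAYS_14_MONTHS <- 426L
DAYS_18_MONTHS <- 547L
DAYS_24_MONTHS <- 730L
MIN_POST_TREATMENT_DAYS <- 14L

DRUG_CLASSES <- c("ACEi", "ARB", "CCB", "beta_blocker", "other", "thiazide")

RACE_LEVELS <- c("White", "Black", "Other")
SEX_LEVELS <- c("F", "M")

COMORBIDITIES <- c(
  "tachyarrhythmia", "diabetes", "ihd", "asthma", "ckd", "chf", "gout"
)

# ICD-10 style condition codes used by the generator and the cohort filters.
CONDITION_CODES <- c(
  hypertension = "I10",
  diabetes = "E11.9",
  prediabetes = "R73.03",
  ckd = "N18.3",
  ihd = "I25.10",
  tachyarrhythmia = "I48.91",
  chf = "I50.9",
  gout = "M10.9",
  asthma = "J45.909",
  general_exam = "Z00.00"
)

VITAL_KINDS <- c("SBP", "DBP", "HR")
VITAL_CONTEXTS <- c(
  "ambulatory", "hospital", "exercise", "operation", "anesthesia", "dialysis"
)
LAB_ANALYTES <- c("creatinine", "sodium", "potassium", "glucose_fasting")
AE_SEVERITIES <- c("mild", "moderate", "severe")

FAILURE_REASONS <- c(
  "hypotension", "bradycardia", "creatinine_rise", "natremia", "kalemia",
  "glucose", "documented_ae", "bp_average", "bp_threshold"
)

BP_WINDOWS <- c("6-12m", "12-14m", "14-18m", "18-24m", "discontinuation")

INCLUSION_CRITERIA <- c(
  "primary_htn_dx", "prior_care", "treatment_within_9_months",
  "followup_1yr", "baseline_bp", "baseline_creatinine", "outcome_measurable"
)
EXCLUSION_CRITERIA <- c("new_diabetes", "rare_pair")

inv_logit <- function(x) stats::plogis(x)

#' Combination class label from component classes
#'
#' Deterministic reporting key for a regimen: the distinct component classes,
#' sorted, joined with `-` (e.g. `"ACEi-thiazide"`).
#'
#' @param classes Character vector of component drug classes.
#' @return A single class label string.
#' @export
class_label <- function(classes) {
  paste(sort(unique(classes), method = "radix"), collapse = "-")
}

# Canonical treatment id for a set of (ingredient, dose) components:
# "ingredient:dose" sorted by ingredient, joined with "+".
make_treatment_id <- function(ingredient, dose_mg) {
  parts <- paste0(ingredient, ":", format(dose_mg, trim = TRUE, scientific = FALSE))
  paste(sort(parts, method = "radix"), collapse = "+")
}

# Percentage rounded to one decimal (R's round() is half-even).
as_pct <- function(x) round(100 * x, 1)

stop_config <- function(field, msg) {
  abort(sprintf("Invalid generator configuration: field `%s` %s", field, msg),
        class = "htnrec_config_error")
}
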