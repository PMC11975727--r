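# Shared fixtures. Large objects are built once per session and cached in the
# global environment so every test file reuses the same cohort and ensemble.

ref_patient <- function(age = 50, sex = "F", race = "White", pre_sbp = 160,
                        pre_dbp = 90, creatinine = 0.8, ...) {
  base <- tibble::tibble(
    patient_id = 0L, age = age, sex = sex, race = race, pre_sbp = pre_sbp,
    pre_dbp = pre_dbp, creatinine = creatinine,
    tachyarrhythmia = FALSE, diabetes = FALSE, ihd = FALSE, asthma = FALSE,
    ckd = FALSE, chf = FALSE, gout = FALSE
  )
  mods <- list(...)
  for (nm in names(mods)) base[[nm]] <- mods[[nm]]
  base
}

# One-patient bundle builder for labelling edge cases. All dates are offsets
# (days) from the treatment start, which is fixed at day 1000 of the record.
ORIGIN <- as.Date("2015-01-01")
TSTART <- ORIGIN + 1000

mk_vital <- function(day, kind, value, position = "sitting",
                     body_site = "arm", invasive = FALSE,
                     context = "ambulatory", patient_id = 1L) {
  tibble::tibble(
    patient_id = patient_id, kind = kind, value = value,
    date = TSTART + day, position = position, body_site = body_site,
    invasive_flag = invasive, context = context
  )
}

mk_bp <- function(day, sbp, dbp, ...) {
  dplyr::bind_rows(mk_vital(day, "SBP", sbp, ...), mk_vital(day, "DBP", dbp, ...))
}

mk_lab <- function(day, analyte, value, patient_id = 1L) {
  units <- c(creatinine = "mg/dL", sodium = "mEq/L", potassium = "mEq/L",
             glucose_fasting = "mg/dL")[[analyte]]
  tibble::tibble(patient_id = patient_id, analyte = analyte, value = value,
                 units = units, date = TSTART + day)
}

# A minimal valid single-patient bundle around one lisinopril 10 mg episode.
# `end_day` NA keeps the prescription open-ended.
mk_case <- function(vitals = NULL, labs = NULL, allergies = NULL,
                    end_day = NA, age = 50, baseline_creatinine = 1.0,
                    race = "White") {
  patients <- tibble::tibble(
    patient_id = 1L, birth_date = TSTART - round(age * 365.25),
    sex = "F", race = race
  )
  diagnoses <- tibble::tibble(
    patient_id = 1L, code = c("Z00.00", "I10"),
    date = c(ORIGIN, ORIGIN + 900), setting = "ambulatory"
  )
  meds <- tibble::tibble(
    patient_id = 1L, code = "104375", name = "lisinopril 10 mg tablet",
    per_unit_dose_mg = 10, sig_text = "1 tablet daily",
    start_date = TSTART,
    end_date = if (is.na(end_day)) as.Date(NA) else TSTART + end_day
  )
  base_rows <- dplyr::bind_rows(
    mk_bp(-30, 138, 84),
    mk_vital(-700, "HR", 72)
  )
  base_labs <- mk_lab(-40, "creatinine", baseline_creatinine)
  ehr_bundle(
    patients = patients, diagnoses = diagnoses,
    vitals = dplyr::bind_rows(base_rows, vitals),
    labs = dplyr::bind_rows(base_labs, labs),
    medications = meds, allergies = allergies
  )
}

mk_episode <- function(bundle) {
  initial_treatment(build_timeline(normalize_medications(bundle$medications)))
}

label_case <- function(bundle) {
  ep <- mk_episode(bundle)
  label_treatment(1L, ep[1, ], bundle)
}

# ---- cached large runs ----------------------------------------------------

acceptance_fixture <- function() {
  if (!exists(".htnrec_acceptance_run", envir = globalenv())) {
    cfg <- generator_config(n_patients = 20000, seed = 1)
    sim <- generate_cohort(cfg)
    cohort <- build_cohort(sim$bundle)
    included <- cohort$eligibility$patient_id[cohort$eligibility$included]
    split <- split_train_validation(included, 1000, seed = 1)
    feats <- extract_features(sim$bundle, cohort$included_episodes)
    feats <- featurize(
      feats,
      cohort$included_episodes$treatment_id[
        match(feats$patient_id, cohort$included_episodes$patient_id)
      ]
    )
    ens <- train_ensemble(
      dplyr::filter(feats, .data$patient_id %in% split$train),
      dplyr::filter(cohort$labels, .data$patient_id %in% split$train),
      ensemble_config(), seed = 1
    )
    run <- list(config = cfg, sim = sim, cohort = cohort, split = split,
                features = feats, ensemble = ens)
    assign(".htnrec_acceptance_run", run, envir = globalenv())
  }
  get(".htnrec_acceptance_run", envir = globalenv())
}

small_model_fixture <- function() {
  if (!exists(".htnrec_small_model", envir = globalenv())) {
    sim <- small_sim()
    cohort <- build_cohort(sim$bundle)
    feats <- extract_features(sim$bundle, cohort$included_episodes)
    feats <- featurize(
      feats,
      cohort$included_episodes$treatment_id[
        match(feats$patient_id, cohort$included_episodes$patient_id)
      ]
    )
    cfg <- ensemble_config(members = 6, hidden = 3, maxit = 40)
    ens <- train_ensemble(feats, cohort$labels, cfg, seed = 101)
    assign(".htnrec_small_model",
           list(features = feats, labels = cohort$labels, config = cfg,
                ensemble = ens),
           envir = globalenv())
  }
  get(".htnrec_small_model", envir = globalenv())
}

small_sim <- function() {
  if (!exists(".htnrec_small_sim", envir = globalenv())) {
    assign(".htnrec_small_sim",
           generate_cohort(generator_config(n_patients = 2000, seed = 7)),
           envir = globalenv())
  }
  get(".htnrec_small_sim", envir = globalenv())
}
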