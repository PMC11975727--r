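# Cohort construction: measurement filters, inclusion/exclusion criteria,
# planted-violation recovery, and the train/validation split.

test_that("measurement filter keeps only valid ambulatory rows", {
  rows <- dplyr::bind_rows(
    mk_vital(10, "SBP", 130),                             # valid
    mk_vital(10, "SBP", 130, invasive = TRUE),            # invasive
    mk_vital(10, "SBP", 130, context = "hospital"),       # hospitalized
    mk_vital(10, "SBP", 130, context = "exercise"),
    mk_vital(10, "SBP", 130, position = "standing"),
    mk_vital(10, "SBP", 130, body_site = "wrist")
  )
  kept <- filter_bp_measurements(rows)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$context, "ambulatory")
})

test_that("each planted violation is excluded for its own criterion", {
  sim <- small_sim()
  elig <- apply_exclusions(apply_inclusion(sim$bundle), sim$bundle)
  merged <- dplyr::left_join(sim$scenarios, elig, by = "patient_id")

  expect_crit <- function(viol, criterion) {
    sub <- dplyr::filter(merged, .data$viol == !!viol)
    expect_true(all(!sub$included), label = paste(viol, "excluded"))
    expect_true(all(purrr::map_lgl(sub$failed_criteria, ~ criterion %in% .x)),
                label = paste(viol, "carries", criterion))
  }
  expect_crit("no_htn_dx", "primary_htn_dx")
  expect_crit("no_prior_care", "prior_care")
  expect_crit("late_treatment", "treatment_within_9_months")
  expect_crit("short_followup", "followup_1yr")
  expect_crit("no_baseline_bp", "baseline_bp")
  expect_crit("no_baseline_creatinine", "baseline_creatinine")
  expect_crit("new_diabetes", "new_diabetes")

  # excluded patients always carry at least one named criterion; included
  # patients carry none
  expect_true(all(lengths(merged$failed_criteria[!merged$included]) >= 1))
  expect_true(all(lengths(merged$failed_criteria[merged$included]) == 0))

  # non-planted patients are not excluded by cohort filters
  clean <- dplyr::filter(merged, .data$viol %in% c("none",
                                                   "discontinued_controlled"))
  expect_true(all(clean$included))
})

test_that("the 270-day treatment window boundary is inclusive", {
  mk <- function(delay) {
    start <- ORIGIN + 900 + delay
    patients <- tibble::tibble(patient_id = 1L,
                               birth_date = start - round(50 * 365.25),
                               sex = "F", race = "White")
    diagnoses <- tibble::tibble(patient_id = 1L, code = c("Z00.00", "I10"),
                                date = c(ORIGIN, ORIGIN + 900),
                                setting = "ambulatory")
    meds <- tibble::tibble(patient_id = 1L, code = "104375", name = "x",
                           per_unit_dose_mg = 10, sig_text = "1 tablet daily",
                           start_date = start, end_date = as.Date(NA))
    vit <- dplyr::bind_rows(
      tibble::tibble(patient_id = 1L, kind = c("SBP", "DBP"),
                     value = c(138, 84), date = start - 30,
                     position = "sitting", body_site = "arm",
                     invasive_flag = FALSE, context = "ambulatory"),
      tibble::tibble(patient_id = 1L, kind = c("SBP", "DBP"),
                     value = c(128, 78), date = start + 220,
                     position = "sitting", body_site = "arm",
                     invasive_flag = FALSE, context = "ambulatory"),
      tibble::tibble(patient_id = 1L, kind = "HR", value = 70,
                     date = start + 400, position = "sitting",
                     body_site = "arm", invasive_flag = FALSE,
                     context = "ambulatory")
    )
    labs <- tibble::tibble(patient_id = 1L, analyte = "creatinine", value = 1,
                           units = "mg/dL", date = start - 40)
    ehr_bundle(patients = patients, diagnoses = diagnoses, vitals = vit,
               labs = labs, medications = meds)
  }
  elig_270 <- apply_inclusion(mk(270))
  expect_true(elig_270$included)
  elig_271 <- apply_inclusion(mk(271))
  expect_false(elig_271$included)
  expect_true("treatment_within_9_months" %in% elig_271$failed_criteria[[1]])
})

test_that("rare ingredient-dose pairs are excluded at a fixed point", {
  # 5 patients: three share lisinopril:10; one unique pair (valsartan:160);
  # one patient whose HCTZ:25 is shared only with the valsartan patient, so
  # removing that patient makes the pair rare in a second pass.
  start <- ORIGIN + 900
  mk_pt <- function(id, codes, units) {
    list(
      patients = tibble::tibble(patient_id = id,
                                birth_date = start - round(55 * 365.25),
                                sex = "F", race = "White"),
      diagnoses = tibble::tibble(patient_id = id, code = c("Z00.00", "I10"),
                                 date = c(ORIGIN, ORIGIN + 800),
                                 setting = "ambulatory"),
      medications = tibble::tibble(patient_id = id, code = codes, name = "x",
                                   per_unit_dose_mg = units,
                                   sig_text = "1 tablet daily",
                                   start_date = start, end_date = as.Date(NA)),
      vitals = dplyr::bind_rows(
        tibble::tibble(patient_id = id, kind = c("SBP", "DBP"),
                       value = c(138, 84), date = start - 30,
                       position = "sitting", body_site = "arm",
                       invasive_flag = FALSE, context = "ambulatory"),
        tibble::tibble(patient_id = id, kind = c("SBP", "DBP"),
                       value = c(128, 78), date = start + 220,
                       position = "sitting", body_site = "arm",
                       invasive_flag = FALSE, context = "ambulatory"),
        tibble::tibble(patient_id = id, kind = "HR", value = 70,
                       date = start + 400, position = "sitting",
                       body_site = "arm", invasive_flag = FALSE,
                       context = "ambulatory")
      ),
      labs = tibble::tibble(patient_id = id, analyte = "creatinine",
                            value = 1, units = "mg/dL", date = start - 40)
    )
  }
  pts <- list(
    mk_pt(1L, "104375", 10), mk_pt(2L, "104375", 10), mk_pt(3L, "104375", 10),
    mk_pt(4L, c("203321", "310799"), c(160, 25)),  # unique valsartan pair
    mk_pt(5L, "310799", 25)                         # shared only with #4
  )
  bundle <- ehr_bundle(
    patients = dplyr::bind_rows(purrr::map(pts, "patients")),
    diagnoses = dplyr::bind_rows(purrr::map(pts, "diagnoses")),
    vitals = dplyr::bind_rows(purrr::map(pts, "vitals")),
    labs = dplyr::bind_rows(purrr::map(pts, "labs")),
    medications = dplyr::bind_rows(purrr::map(pts, "medications"))
  )
  elig <- apply_exclusions(apply_inclusion(bundle), bundle)
  expect_equal(elig$included, c(TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_true("rare_pair" %in% elig$failed_criteria[[4]])
  expect_true("rare_pair" %in% elig$failed_criteria[[5]])

  # a pair occurring exactly twice is retained ("less than twice" fails)
  pts2 <- list(mk_pt(1L, "104375", 10), mk_pt(2L, "104375", 10),
               mk_pt(3L, "203321", 160), mk_pt(4L, "203321", 160))
  bundle2 <- ehr_bundle(
    patients = dplyr::bind_rows(purrr::map(pts2, "patients")),
    diagnoses = dplyr::bind_rows(purrr::map(pts2, "diagnoses")),
    vitals = dplyr::bind_rows(purrr::map(pts2, "vitals")),
    labs = dplyr::bind_rows(purrr::map(pts2, "labs")),
    medications = dplyr::bind_rows(purrr::map(pts2, "medications"))
  )
  elig2 <- apply_exclusions(apply_inclusion(bundle2), bundle2)
  expect_true(all(elig2$included))
})

test_that("a prediabetes code 200 days post-treatment excludes the patient", {
  sim <- small_sim()
  bundle <- sim$bundle
  elig <- apply_inclusion(bundle)
  target <- dplyr::filter(
    dplyr::left_join(sim$scenarios, elig, by = "patient_id"),
    .data$viol == "none", .data$included
  )$patient_id[1]
  start <- sim$scenarios$start[sim$scenarios$patient_id == target]
  bundle$diagnoses <- dplyr::bind_rows(
    bundle$diagnoses,
    tibble::tibble(patient_id = target, code = "R73.03", date = start + 200,
                   setting = "ambulatory")
  )
  elig2 <- apply_exclusions(apply_inclusion(bundle), bundle)
  row <- dplyr::filter(elig2, .data$patient_id == target)
  expect_false(row$included)
  expect_true("new_diabetes" %in% row$failed_criteria[[1]])
})

test_that("cohort filters are idempotent", {
  sim <- small_sim()
  elig1 <- apply_exclusions(apply_inclusion(sim$bundle), sim$bundle)
  included <- elig1$patient_id[elig1$included]
  # keep only the included patients' records and re-apply
  sub <- sim$bundle
  for (nm in names(sub)) {
    sub[[nm]] <- dplyr::filter(sub[[nm]], .data$patient_id %in% included)
  }
  elig2 <- apply_exclusions(apply_inclusion(sub), sub)
  expect_true(all(elig2$included))
})

test_that("train/validation split is disjoint, exhaustive and reproducible", {
  ids <- seq_len(17917)
  sp <- split_train_validation(ids, 1000, seed = 42)
  expect_equal(length(sp$train), 16917)
  expect_equal(length(sp$validation), 1000)
  expect_length(intersect(sp$train, sp$validation), 0)
  expect_setequal(c(sp$train, sp$validation), ids)
  sp2 <- split_train_validation(ids, 1000, seed = 42)
  expect_identical(sp, sp2)
  sp3 <- split_train_validation(ids, 1000, seed = 43)
  expect_false(identical(sp$validation, sp3$validation))
  expect_error(split_train_validation(1:10, 10, seed = 1),
               class = "htnrec_argument_error")
})
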