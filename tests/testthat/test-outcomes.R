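# Outcome labelling: thresholds, windows, control decisions, adverse-effect
# criteria, and full-episode labels on constructed cases.

test_that("blood-pressure limits switch at age 60 (60 takes the older branch)", {
  thr <- bp_thresholds(c(45, 75, 60))
  expect_equal(thr$avg_sbp_limit, c(140, 150, 150))
  expect_equal(thr$max_sbp_limit, c(160, 170, 170))
  expect_equal(thr$avg_dbp_limit, rep(90, 3))
  expect_equal(thr$max_dbp_limit, rep(90, 3))
})

test_that("window selection follows the primary-then-fallback order", {
  rd <- function(days) tibble::tibble(day = days, sbp = 130, dbp = 80)
  # readings at months 7 and 9 -> primary window
  sel <- select_bp_window(rd(c(213, 274)), NA)
  expect_equal(sel$window, "6-12m")
  expect_equal(nrow(sel$readings), 2)
  # nothing before month 13, reading at month 13 -> 12-14m
  sel <- select_bp_window(rd(396), NA)
  expect_equal(sel$window, "12-14m")
  # fallback order is earliest non-empty
  sel <- select_bp_window(rd(c(500, 600)), NA)
  expect_equal(sel$window, "14-18m")
  sel <- select_bp_window(rd(600), NA)
  expect_equal(sel$window, "18-24m")
  # discontinued at month 8: readings must be >= day 14 and >= 6 months
  # before the end
  sel <- select_bp_window(rd(c(10, 40)), 243)
  expect_equal(sel$window, "discontinuation")
  expect_equal(sel$readings$day, 40)
  # fallback readings only count while the regimen is maintained
  sel <- select_bp_window(rd(400), 380)
  expect_true(is.na(sel$window))
})

test_that("control requires strict average and non-exceeded maxima", {
  thr <- bp_thresholds(45)
  # mean SBP exactly at the limit fails (strict inequality)
  r <- tibble::tibble(sbp = c(138, 142), dbp = c(85, 80))
  out <- bp_control_outcome(r, thr)
  expect_false(out)
  expect_equal(attr(out, "reason"), "bp_average")
  # single spike above the max limit fails even with a controlled mean
  r <- tibble::tibble(sbp = c(120, 165), dbp = c(75, 80))
  out <- bp_control_outcome(r, thr)
  expect_false(out)
  expect_equal(attr(out, "reason"), "bp_threshold")
  # a reading exactly at the max limit is allowed ("never surpassed >160")
  r <- tibble::tibble(sbp = c(115, 160), dbp = c(75, 80))
  expect_true(bp_control_outcome(r, thr))
  # older patient: 145/85 x3 is controlled
  thr60 <- bp_thresholds(75)
  r <- tibble::tibble(sbp = rep(145, 3), dbp = rep(85, 3))
  expect_true(bp_control_outcome(r, thr60))
  # no readings is indeterminate, never success
  expect_true(is.na(bp_control_outcome(r[0, ], thr)))
})

test_that("adverse-effect criteria honour their exact boundaries", {
  controlled <- mk_bp(220, 128, 78)

  # creatinine +35% fails, exactly +30% does not (rule is > 30%)
  lab <- label_case(mk_case(vitals = controlled,
                            labs = mk_lab(100, "creatinine", 1.35)))
  expect_equal(lab$status, "failure")
  expect_equal(lab$failure_reason, "creatinine_rise")
  lab <- label_case(mk_case(vitals = controlled,
                            labs = mk_lab(100, "creatinine", 1.30)))
  expect_equal(lab$status, "success")

  # potassium exactly 5.1 is allowed; 5.2 is hyperkalemia
  lab <- label_case(mk_case(vitals = controlled,
                            labs = mk_lab(90, "potassium", 5.1)))
  expect_equal(lab$status, "success")
  lab <- label_case(mk_case(vitals = controlled,
                            labs = mk_lab(90, "potassium", 5.2)))
  expect_equal(lab$failure_reason, "kalemia")
  lab <- label_case(mk_case(vitals = controlled,
                            labs = mk_lab(90, "potassium", 3.5)))
  expect_equal(lab$failure_reason, "kalemia")

  # sodium boundaries 130/150 exclusive
  lab <- label_case(mk_case(vitals = controlled,
                            labs = mk_lab(90, "sodium", 130)))
  expect_equal(lab$status, "success")
  lab <- label_case(mk_case(vitals = controlled,
                            labs = mk_lab(90, "sodium", 129)))
  expect_equal(lab$failure_reason, "natremia")

  # fasting glucose > 120
  lab <- label_case(mk_case(vitals = controlled,
                            labs = mk_lab(90, "glucose_fasting", 121)))
  expect_equal(lab$failure_reason, "glucose")

  # hypotension and bradycardia on valid ambulatory vitals
  lab <- label_case(mk_case(vitals = dplyr::bind_rows(controlled,
                                                      mk_bp(60, 86, 55))))
  expect_equal(lab$failure_reason, "hypotension")
  lab <- label_case(mk_case(vitals = dplyr::bind_rows(controlled,
                                                      mk_vital(60, "HR", 48))))
  expect_equal(lab$failure_reason, "bradycardia")
  # an invasive hypotensive reading is filtered, not an event
  lab <- label_case(mk_case(vitals = dplyr::bind_rows(
    controlled, mk_bp(60, 86, 55, invasive = TRUE))))
  expect_equal(lab$status, "success")
})

test_that("documented allergy events count only at moderate/severe", {
  controlled <- mk_bp(220, 128, 78)
  alg <- function(sev) tibble::tibble(
    patient_id = 1L, medication_code = "104375", severity = sev,
    date = TSTART + 90
  )
  expect_equal(label_case(mk_case(vitals = controlled,
                                  allergies = alg("mild")))$status, "success")
  lab <- label_case(mk_case(vitals = controlled, allergies = alg("severe")))
  expect_equal(lab$status, "failure")
  expect_equal(lab$failure_reason, "documented_ae")
  lab <- label_case(mk_case(vitals = controlled, allergies = alg("moderate")))
  expect_equal(lab$failure_reason, "documented_ae")
})

test_that("full-episode labels cover success, failure, and exclusions", {
  # year-long maintained episode, controlled window, no AEs -> success
  lab <- label_case(mk_case(vitals = mk_bp(220, 128, 78)))
  expect_equal(lab$status, "success")
  expect_equal(lab$bp_window_used, "6-12m")
  expect_gte(lab$n_bp_readings, 1)

  # discontinued at month 8 with controlled prior pressures -> excluded
  lab <- label_case(mk_case(vitals = mk_bp(40, 128, 78), end_day = 240))
  expect_equal(lab$status, "excluded")
  expect_equal(lab$bp_window_used, "discontinuation")

  # discontinued with high prior pressures -> failure
  lab <- label_case(mk_case(vitals = mk_bp(40, 152, 80), end_day = 240))
  expect_equal(lab$status, "failure")
  expect_equal(lab$failure_reason, "bp_average")

  # controlled window but a severe cough-type allergy event -> failure
  lab <- label_case(mk_case(
    vitals = mk_bp(220, 128, 78),
    allergies = tibble::tibble(patient_id = 1L, medication_code = "104375",
                               severity = "severe", date = TSTART + 50)
  ))
  expect_equal(lab$status, "failure")
  expect_equal(lab$failure_reason, "documented_ae")

  # no readings anywhere -> excluded (indeterminate)
  lab <- label_case(mk_case(vitals = NULL))
  expect_equal(lab$status, "excluded")
  expect_equal(lab$n_bp_readings, 0)
})

test_that("lowering controlled readings never flips success to failure", {
  base <- mk_case(vitals = mk_bp(220, 139, 89))
  expect_equal(label_case(base)$status, "success")
  for (s in c(135, 125, 115, 105)) {
    lowered <- mk_case(vitals = mk_bp(220, s, min(s - 40, 85)))
    expect_equal(label_case(lowered)$status, "success")
  }
})

test_that("labels are a pure function of the bundle", {
  b <- mk_case(vitals = mk_bp(220, 128, 78))
  expect_identical(label_case(b), label_case(b))
})

test_that("vectorized cohort labelling agrees with per-episode labelling", {
  sim <- small_sim()
  episodes <- initial_treatment(
    build_timeline(normalize_medications(sim$bundle$medications))
  )
  idx <- withr::with_seed(11, sample(nrow(episodes), 250))
  sample_ep <- episodes[idx, ]
  vec <- label_cohort(sim$bundle, sample_ep)
  for (i in seq_len(nrow(sample_ep))) {
    single <- label_treatment(sample_ep$patient_id[i], sample_ep[i, ],
                              sim$bundle)
    expect_equal(vec$status[i], single$status)
    expect_equal(vec$failure_reason[i], single$failure_reason)
    expect_equal(vec$n_bp_readings[i], single$n_bp_readings)
  }
})
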