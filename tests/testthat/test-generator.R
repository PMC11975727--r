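# Synthetic-data generator: planted surface, determinism, adverse-effect
# behaviour, and generator/labeler consistency.

test_that("planted success probability is the inverse-logit linear predictor", {
  co <- zero_effect_coefficients()
  co$intercept[] <- -0.5
  p <- ground_truth_success(ref_patient(pre_sbp = 140, age = 60),
                            "lisinopril:10", co)
  expect_equal(p, 1 / (1 + exp(0.5)), tolerance = 1e-6)
  expect_equal(round(p, 4), 0.3775)

  # zero coefficients: 0.5 for every patient-treatment
  z <- zero_effect_coefficients()
  pts <- dplyr::bind_rows(ref_patient(age = 30, race = "Black", pre_sbp = 180),
                          ref_patient(age = 80, ckd = TRUE))
  expect_equal(ground_truth_success(pts, "amlodipine:5", z), c(0.5, 0.5))

  # a positive thiazide-by-Black coefficient raises thiazide success for
  # Black patients, all else equal
  co2 <- zero_effect_coefficients()
  co2$black[["thiazide"]] <- 0.4
  p_black <- ground_truth_success(ref_patient(race = "Black"),
                                  "hydrochlorothiazide:12.5", co2)
  p_white <- ground_truth_success(ref_patient(race = "White"),
                                  "hydrochlorothiazide:12.5", co2)
  expect_gt(p_black, p_white)

  expect_error(
    ground_truth_success(ref_patient(), "ibuprofen:200",
                         default_effect_coefficients()),
    class = "htnrec_domain_error"
  )
})

test_that("invalid configurations error naming the offending field", {
  expect_error(generator_config(n_patients = 0), regexp = "n_patients",
               class = "htnrec_config_error")
  expect_error(generator_config(race_probs = c(White = 0.5, Black = 0.2,
                                               Other = 0.2)),
               regexp = "race_probs", class = "htnrec_config_error")
  bad_cl <- c(ACEi = 0.5, beta_blocker = 0.6)
  expect_error(generator_config(class_likelihoods = bad_cl),
               regexp = "class_likelihoods", class = "htnrec_config_error")
  expect_error(generator_config(bp_noise_sd = -1), regexp = "bp_noise_sd",
               class = "htnrec_config_error")
})

test_that("the same seed reproduces the bundle exactly", {
  cfg <- generator_config(n_patients = 150, seed = 99)
  s1 <- generate_cohort(cfg)
  s2 <- generate_cohort(cfg)
  expect_identical(s1$bundle, s2$bundle)
  expect_identical(s1$ground_truth, s2$ground_truth)
  s3 <- generate_cohort(generator_config(n_patients = 150, seed = 100))
  expect_false(identical(s1$bundle$vitals, s3$bundle$vitals))
})

test_that("severe adverse events discontinue within a month 85.1% of the time", {
  rates <- list(ACEi = c(mild = 0, moderate = 0, severe = 1))
  ev <- simulate_adverse_events(seq_len(10000), rep("ACEi", 10000), rates,
                                seed = 5)
  expect_equal(nrow(ev), 10000)
  expect_true(all(ev$severity == "severe"))
  expect_equal(mean(ev$discontinued), 0.851, tolerance = 0.01)
  gap <- ev$disc_day[ev$discontinued] - ev$day[ev$discontinued]
  expect_true(all(gap >= 1 & gap <= 30))

  rates_mod <- list(ACEi = c(mild = 0, moderate = 1, severe = 0))
  ev_mod <- simulate_adverse_events(seq_len(10000), rep("ACEi", 10000),
                                    rates_mod, seed = 5)
  expect_equal(mean(ev_mod$discontinued), 0.75, tolerance = 0.015)
})

test_that("zero rates emit nothing; mild events never discontinue", {
  none <- simulate_adverse_events(1:500, rep("ACEi", 500),
                                  list(ACEi = c(mild = 0, moderate = 0,
                                                severe = 0)), seed = 1)
  expect_equal(nrow(none), 0)
  mild <- simulate_adverse_events(1:2000, rep("ACEi", 2000),
                                  list(ACEi = c(mild = 1, moderate = 0,
                                                severe = 0)), seed = 1)
  expect_true(all(mild$severity == "mild"))
  expect_false(any(mild$discontinued))
})

test_that("generated cohorts have no mild-AE-driven discontinuations", {
  sim <- small_sim()
  mild_only <- sim$bundle$allergies |>
    dplyr::filter(.data$severity == "mild") |>
    dplyr::anti_join(
      dplyr::filter(sim$bundle$allergies,
                    .data$severity %in% c("moderate", "severe")),
      by = "patient_id"
    )
  sc <- dplyr::semi_join(sim$scenarios, mild_only, by = "patient_id")
  # mild-event patients' episodes end early only for planted discontinuation
  # scenarios, never because of the mild event
  early <- dplyr::filter(sc, !is.na(.data$end_day), .data$end_day < 365)
  expect_true(all(early$mech %in% c("discontinued_high", "disc_controlled")))
})

test_that("labelling recovers the realized state for nearly all episodes", {
  sim <- small_sim()
  co <- build_cohort(sim$bundle)
  m <- dplyr::inner_join(co$labels, sim$scenarios, by = "patient_id")
  ne <- dplyr::filter(m, .data$status != "excluded")
  agreement <- mean((ne$status == "success") == ne$realized)
  expect_gte(agreement, 0.99)
})

test_that("changing the seed moves realizations but not the marginals", {
  cfg_a <- generator_config(n_patients = 4000, seed = 21)
  cfg_b <- generator_config(n_patients = 4000, seed = 22)
  a <- generate_cohort(cfg_a)
  b <- generate_cohort(cfg_b)
  expect_false(identical(a$ground_truth$realized, b$ground_truth$realized))
  # marginal success within sampling error of each other
  expect_equal(mean(a$ground_truth$realized), mean(b$ground_truth$realized),
               tolerance = 0.04)
  # class likelihoods stable across seeds
  fa <- table(a$scenarios$class_label) / 4000
  fb <- table(b$scenarios$class_label) / 4000
  expect_true(all(abs(fa - fb[names(fa)]) < 0.04))
})

test_that("counterfactual ground truth covers every candidate regimen", {
  sim <- generate_cohort(generator_config(n_patients = 40, seed = 3),
                         counterfactuals = TRUE)
  menu <- treatment_menu()$menu
  gt <- sim$ground_truth
  expect_equal(nrow(gt), 40 * nrow(menu))
  expect_equal(sum(gt$observed), 40)
  # observed rows agree with the observed-only table
  obs <- dplyr::filter(gt, .data$observed)
  sim2 <- generate_cohort(generator_config(n_patients = 40, seed = 3))
  expect_equal(
    dplyr::arrange(dplyr::select(obs, "patient_id", "treatment_id",
                                 "success_probability", "realized"),
                   .data$patient_id),
    dplyr::arrange(dplyr::select(sim2$ground_truth, "patient_id",
                                 "treatment_id", "success_probability",
                                 "realized"), .data$patient_id)
  )
})
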