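# Cohort realization: demographics, planted outcomes, and the record-level
# trajectories that make the outcome labeler recover each planted state.

# Reading-value construction keeps hard margins around every labelling
# threshold so that rounding can never flip a planted outcome:
# window means are drawn strictly inside (or outside) the average limits and
# per-reading deviations are centered and rescaled to a bounded range.
center_scale <- function(x, bound) {
  x <- x - mean(x)
  mx <- max(abs(x))
  if (mx > bound) x <- x * (bound / mx)
  x
}

# Stratified distinct day sampling: n distinct integer days in [lo, hi].
stratified_days <- function(i, n, lo, hi, u) {
  lo + floor((hi - lo + 1) * (i - 1 + u) / n)
}

#' Generate a synthetic EHR cohort with known ground truth
#'
#' Draws patient covariates from the configured marginals, assigns an initial
#' regimen from the class likelihoods, realizes treatment success from the
#' planted logistic surface (one seeded substream per patient), and writes
#' record-level trajectories consistent with the realized state: controlled
#' blood-pressure series for successes; threshold- or average-violating
#' series, adverse-effect records, abnormal labs, or early discontinuation
#' for failures. Configured fractions of patients are planted to violate each
#' inclusion rule so cohort filters are exercised.
#'
#' @param config A [generator_config()].
#' @param counterfactuals If `TRUE`, the ground-truth table carries the
#'   planted probability and realized state for every candidate regimen per
#'   patient (only one is observed); otherwise observed regimens only.
#' @return A list of class `htn_sim`: `bundle` (an [ehr_bundle()]),
#'   `ground_truth`, `scenarios` (per-patient planted scenario), `config`.
#' @export
generate_cohort <- function(config = generator_config(),
                            counterfactuals = FALSE) {
  validate_generator_config(config)
  n <- as.integer(config$n_patients)
  menu <- treatment_menu()
  menu_tbl <- dplyr::filter(menu$menu,
                            .data$class_label %in% names(config$class_likelihoods))
  vs <- config$visit_schedule

  withr::with_seed(config$seed, {
    # ---- covariates (global stream) -----------------------------------
    bands <- config$age_distribution
    band_idx <- sample.int(nrow(bands), n, replace = TRUE, prob = bands$prob)
    age <- runif(n, bands$lower[band_idx], bands$upper[band_idx])
    # quantize to whole birth-date days so the age recovered from the written
    # birth_date is exactly the age the planted surface used
    age <- round(age * 365.25) / 365.25
    sex <- ifelse(runif(n) < config$sex_fraction, "F", "M")
    race <- sample(names(config$race_probs), n, replace = TRUE,
                   prob = config$race_probs)
    flags <- purrr::map(config$comorbidity_prevalences,
                        ~ runif(n) < .x)
    pre_sbp <- round(pmin(pmax(rnorm(n, 137.8, 18.9), 100), 195), 1)
    pre_dbp <- round(pmin(pmax(rnorm(n, 81, 11.5), 55), 105), 1)
    pre_dbp <- pmin(pre_dbp, pre_sbp - 15)
    creatinine <- round(pmin(pmax(rlnorm(n, log(0.95), 0.3), 0.4), 4), 2)

    dx_date <- as.Date("2005-01-01") + sample.int(5478L, n, replace = TRUE) - 1L

    obs_class <- sample(names(config$class_likelihoods), n, replace = TRUE,
                        prob = config$class_likelihoods)
    treatment_id <- character(n)
    for (cl in unique(obs_class)) {
      sub <- dplyr::filter(menu_tbl, .data$class_label == cl)
      idx <- which(obs_class == cl)
      treatment_id[idx] <- sample(sub$treatment_id, length(idx),
                                  replace = TRUE,
                                  prob = sub$weight_within_class)
    }

    viol_names <- names(config$exclusion_fractions)
    viol <- sample(c(viol_names, "none"), n, replace = TRUE,
                   prob = c(config$exclusion_fractions,
                            1 - sum(config$exclusion_fractions)))

    # new-diabetes violators must not have pre-existing diabetes
    flags$diabetes[viol == "new_diabetes"] <- FALSE

    delay <- round(runif(n, 10, 180))
    delay[viol == "late_treatment"] <- round(runif(sum(viol == "late_treatment"),
                                                   285, 350))
    start <- dx_date + delay

    sc <- tibble::tibble(
      patient_id = seq_len(n), age = age, sex = sex, race = race,
      pre_sbp = pre_sbp, pre_dbp = pre_dbp, creatinine = creatinine,
      dx_date = dx_date, delay = delay, start = start,
      class_label = obs_class, treatment_id = treatment_id, viol = viol
    )
    for (m in names(flags)) sc[[m]] <- flags[[m]]

    # ---- planted surface and per-patient realization ------------------
    sc$p_obs <- ground_truth_success(sc, sc$treatment_id,
                                     config$effect_coefficients)
    all_ids <- menu_tbl$treatment_id
    u <- matrix(NA_real_, n, length(all_ids))
    old_kind <- RNGkind("L'Ecuyer-CMRG")[1]
    for (i in seq_len(n)) {
      set.seed(patient_substream_seed(config$seed, i))
      u[i, ] <- runif(length(all_ids))
    }
    RNGkind(old_kind)
    obs_col <- match(sc$treatment_id, all_ids)
    sc$realized <- u[cbind(seq_len(n), obs_col)] < sc$p_obs

    # ---- scenario mechanics (record stream) ---------------------------
    set.seed(patient_substream_seed(config$seed, 0L) + 1L)

    sc$mech <- ifelse(sc$realized, "success", NA_character_)
    fail_idx <- which(!sc$realized)
    sc$mech[fail_idx] <- sample(names(config$failure_mix), length(fail_idx),
                                replace = TRUE, prob = config$failure_mix)
    sc$mech[sc$viol == "short_followup"] <- "short"
    sc$mech[sc$viol == "discontinued_controlled"] <- "disc_controlled"

    maintained_mechs <- c("success", "bp_average", "bp_threshold",
                          "documented_ae", "creatinine_rise", "kalemia",
                          "natremia", "glucose", "hypotension", "bradycardia")
    late_ok <- sc$viol == "none" & sc$mech %in% maintained_mechs
    late_kind <- rep(NA_character_, n)
    pick <- late_ok & runif(n) < config$fallback_window_fraction
    late_kind[pick] <- sample(c("12-14m", "14-18m", "18-24m"), sum(pick),
                              replace = TRUE)
    sc$late_kind <- late_kind

    # documented adverse effects: severity and discontinuation behaviour
    sc$ae_severity <- NA_character_
    sc$ae_day <- NA_real_
    ae_idx <- which(sc$mech == "documented_ae")
    if (length(ae_idx) > 0) {
      rates <- do.call(rbind, config$ae_rates[sc$class_label[ae_idx]])
      p_sev <- rates[, "severe"] / pmax(rates[, "moderate"] + rates[, "severe"],
                                        1e-12)
      sev <- ifelse(runif(length(ae_idx)) < p_sev, "severe", "moderate")
      sc$ae_severity[ae_idx] <- sev
      sc$ae_day[ae_idx] <- round(runif(length(ae_idx), 30, 300))
    }

    # episode end (days from start); NA = open-ended
    sc$end_day <- NA_real_
    maintained <- sc$mech %in% maintained_mechs
    open_ended <- runif(n) < 0.5 | !is.na(sc$late_kind)
    sc$end_day[maintained & !open_ended] <-
      365 + round(rexp(sum(maintained & !open_ended), 1 / 150))
    disc <- sc$mech %in% c("discontinued_high", "disc_controlled")
    sc$end_day[disc] <- round(runif(sum(disc), 240, 330))
    ae_disc <- !is.na(sc$ae_severity) &
      runif(n) < ifelse(sc$ae_severity == "severe", 0.851, 0.75)
    sc$end_day[which(ae_disc)] <- sc$ae_day[which(ae_disc)] +
      round(runif(sum(ae_disc, na.rm = TRUE), 3, 28))
    sc$end_day[sc$mech == "short"] <- NA_real_

    thr <- bp_thresholds(sc$age)
    sc$avg_s <- thr$avg_sbp_limit
    sc$max_s <- thr$max_sbp_limit

    # ---- medications ---------------------------------------------------
    meds <- build_medication_rows(sc, menu)

    # ---- diagnoses -----------------------------------------------------
    dgn <- build_diagnosis_rows(sc)

    # ---- vitals --------------------------------------------------------
    vit <- build_vital_rows(sc, config)

    # ---- labs ----------------------------------------------------------
    lab <- build_lab_rows(sc)

    # ---- allergies -----------------------------------------------------
    first_code <- meds |>
      dplyr::group_by(.data$patient_id) |>
      dplyr::slice_min(.data$start_date, n = 1, with_ties = FALSE) |>
      dplyr::ungroup() |>
      dplyr::select("patient_id", "code")
    alg_doc <- sc |>
      dplyr::filter(!is.na(.data$ae_severity)) |>
      dplyr::left_join(first_code, by = "patient_id") |>
      dplyr::transmute(
        .data$patient_id, medication_code = .data$code,
        severity = .data$ae_severity, date = .data$start + .data$ae_day
      )
    mild_rate <- purrr::map_dbl(config$ae_rates, "mild")[sc$class_label]
    mild_pick <- which(runif(n) < mild_rate & sc$mech != "short")
    alg_mild <- sc[mild_pick, ] |>
      dplyr::left_join(first_code, by = "patient_id") |>
      dplyr::transmute(
        .data$patient_id, medication_code = .data$code, severity = "mild",
        date = .data$start + round(runif(length(mild_pick), 20, 300))
      )
    alg <- dplyr::bind_rows(alg_doc, alg_mild)

    patients <- tibble::tibble(
      patient_id = sc$patient_id,
      birth_date = sc$start - round(sc$age * 365.25),
      sex = sc$sex, race = sc$race
    )

    bundle <- ehr_bundle(
      patients = patients, diagnoses = dgn, vitals = vit, labs = lab,
      medications = meds, allergies = alg
    )

    ground_truth <- tibble::tibble(
      patient_id = sc$patient_id, treatment_id = sc$treatment_id,
      class_label = sc$class_label, success_probability = sc$p_obs,
      realized = sc$realized, observed = TRUE,
      ae_severity = sc$ae_severity, ae_day = sc$ae_day
    )
    if (counterfactuals) {
      p_all <- purrr::map(all_ids, function(tid) {
        ground_truth_success(sc, tid, config$effect_coefficients)
      })
      cf <- tibble::tibble(
        patient_id = rep(sc$patient_id, length(all_ids)),
        treatment_id = rep(all_ids, each = n),
        class_label = rep(menu_tbl$class_label, each = n),
        success_probability = unlist(p_all),
        realized = as.vector(u) < unlist(p_all),
        observed = rep(all_ids, each = n) == rep(sc$treatment_id, length(all_ids)),
        ae_severity = NA_character_, ae_day = NA_real_
      )
      ground_truth <- dplyr::arrange(cf, .data$patient_id, .data$treatment_id)
    }

    scenarios <- dplyr::select(
      sc, "patient_id", "viol", "mech", "late_kind", "end_day", "realized",
      "treatment_id", "class_label", "start"
    )

    structure(
      list(bundle = bundle, ground_truth = ground_truth,
           scenarios = scenarios, config = config),
      class = "htn_sim"
    )
  })
}

# ---------------------------------------------------------------------------
# record builders (called inside the seeded generator body)

build_medication_rows <- function(sc, menu) {
  map <- rx_class_map()
  combo_codes <- map |>
    dplyr::group_by(.data$code, .data$product_name) |>
    dplyr::filter(dplyr::n() > 1) |>
    dplyr::summarise(
      treatment_id = make_treatment_id(.data$ingredient, .data$unit_mg),
      per_unit = sum(.data$unit_mg), .groups = "drop"
    )
  single_map <- map |>
    dplyr::group_by(.data$code) |>
    dplyr::filter(dplyr::n() == 1) |>
    dplyr::ungroup()

  ep <- sc |>
    dplyr::select("patient_id", "treatment_id", "class_label", "start",
                  "end_day") |>
    dplyr::mutate(end_date = .data$start + .data$end_day)

  use_product <- ep$treatment_id %in% combo_codes$treatment_id &
    runif(nrow(ep)) < 0.6
  prod_rows <- ep[use_product, ] |>
    dplyr::left_join(combo_codes, by = "treatment_id") |>
    dplyr::mutate(sig_text = sample(c("1 tablet daily", "1 tablet every 24 hours"),
                                    sum(use_product), replace = TRUE)) |>
    dplyr::transmute(
      .data$patient_id, .data$code, name = .data$product_name,
      per_unit_dose_mg = .data$per_unit, .data$sig_text,
      start_date = .data$start, .data$end_date
    )

  comp <- ep[!use_product, ] |>
    dplyr::left_join(treatment_menu()$components, by = "treatment_id",
                     relationship = "many-to-many") |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::mutate(comp_idx = dplyr::row_number()) |>
    dplyr::ungroup()
  # stagger the second component of separate-pill combinations a few days
  comp$start_date <- comp$start +
    ifelse(comp$comp_idx > 1, sample(0:5, nrow(comp), replace = TRUE), 0)

  own <- dplyr::select(single_map, "code", "product_name", "ingredient",
                       own_mg = "unit_mg")
  comp <- dplyr::left_join(comp, own,
                           by = c("ingredient", "dose_mg" = "own_mg"))
  half <- dplyr::select(single_map, half_code = "code",
                        half_name = "product_name", "ingredient",
                        half_mg = "unit_mg")
  comp <- comp |>
    dplyr::mutate(half_target = .data$dose_mg / 2) |>
    dplyr::left_join(half, by = c("ingredient", "half_target" = "half_mg"))

  use_half <- !is.na(comp$half_code) & runif(nrow(comp)) < 0.4
  k1_sigs <- c("1 tablet daily", "1 tablet every 24 hours")
  k2_sigs <- c("take 1 pill 2 times a day", "1 tablet every 12 hours",
               "1 tablet twice a day")
  comp$sig_text <- ifelse(
    use_half,
    sample(k2_sigs, nrow(comp), replace = TRUE),
    sample(k1_sigs, nrow(comp), replace = TRUE)
  )
  comp$out_code <- ifelse(use_half, comp$half_code, comp$code)
  comp$out_name <- ifelse(use_half, comp$half_name, comp$product_name)
  comp$out_unit <- ifelse(use_half, comp$half_target, comp$dose_mg)

  comp_rows <- dplyr::transmute(
    comp, .data$patient_id, code = .data$out_code, name = .data$out_name,
    per_unit_dose_mg = .data$out_unit, .data$sig_text, .data$start_date,
    .data$end_date
  )

  rows <- dplyr::bind_rows(prod_rows, comp_rows)

  # split ~30% of single-agent prescriptions into two abutting renewals
  single_agent <- rows |>
    dplyr::add_count(.data$patient_id, name = "n_rows") |>
    dplyr::mutate(
      split = .data$n_rows == 1 & runif(dplyr::n()) < 0.3 &
        (is.na(.data$end_date) |
           .data$end_date >= .data$start_date + 240)
    )
  keep <- dplyr::filter(single_agent, !.data$split)
  sp <- dplyr::filter(single_agent, .data$split)
  sp1 <- dplyr::mutate(sp, end_date = .data$start_date + 89)
  sp2 <- dplyr::mutate(sp, start_date = .data$start_date + 90)
  dplyr::bind_rows(keep, sp1, sp2) |>
    dplyr::select("patient_id", "code", "name", "per_unit_dose_mg",
                  "sig_text", "start_date", "end_date") |>
    dplyr::arrange(.data$patient_id, .data$start_date, .data$code)
}

build_diagnosis_rows <- function(sc) {
  n <- nrow(sc)
  htn <- sc |>
    dplyr::filter(.data$viol != "no_htn_dx") |>
    dplyr::transmute(.data$patient_id,
                     code = CONDITION_CODES[["hypertension"]],
                     date = .data$dx_date, setting = "ambulatory")
  exam <- sc |>
    dplyr::filter(.data$viol != "no_prior_care") |>
    (\(d) dplyr::transmute(
      d, .data$patient_id, code = CONDITION_CODES[["general_exam"]],
      date = .data$dx_date - round(runif(nrow(d), 60, 700)),
      setting = "ambulatory"
    ))()
  com <- purrr::map(COMORBIDITIES, function(m) {
    d <- sc[sc[[m]], ]
    if (nrow(d) == 0) return(NULL)
    offset <- round(runif(nrow(d), 30, 1000))
    offset[d$viol == "no_prior_care"] <- 0
    tibble::tibble(
      patient_id = d$patient_id, code = CONDITION_CODES[[m]],
      date = d$dx_date - offset, setting = "ambulatory"
    )
  })
  new_dm <- sc |>
    dplyr::filter(.data$viol == "new_diabetes") |>
    (\(d) tibble::tibble(
      patient_id = d$patient_id, code = CONDITION_CODES[["diabetes"]],
      date = d$start + round(runif(nrow(d), 30, 300)),
      setting = "ambulatory"
    ))()
  dplyr::bind_rows(htn, exam, dplyr::bind_rows(com), new_dm)
}

build_vital_rows <- function(sc, config) {
  n <- nrow(sc)
  vs <- config$visit_schedule
  noise_sd <- config$bp_noise_sd

  pair_rows <- function(d, sbp, dbp, date, position = "sitting",
                        body_site = "arm", invasive = FALSE,
                        context = "ambulatory") {
    m <- length(sbp)
    tibble::tibble(
      patient_id = rep(d$patient_id, 2L),
      kind = rep(c("SBP", "DBP"), each = m),
      value = c(sbp, dbp),
      date = rep(date, 2L),
      position = rep(rep_len(position, m), 2L),
      body_site = rep(rep_len(body_site, m), 2L),
      invasive_flag = rep(rep_len(invasive, m), 2L),
      context = rep(rep_len(context, m), 2L)
    )
  }

  # baseline pair: exact latent values between diagnosis and treatment start
  base <- dplyr::filter(sc, .data$viol != "no_baseline_bp")
  base_date <- base$dx_date + ceiling(base$delay * runif(nrow(base), 0.6, 0.9))
  out <- list(pair_rows(base, base$pre_sbp, base$pre_dbp, base_date))

  older <- base[runif(nrow(base)) < 0.5, ]
  if (nrow(older) > 0) {
    s2 <- round(older$pre_sbp + rnorm(nrow(older), 0, 3), 1)
    d2 <- round(older$pre_dbp + rnorm(nrow(older), 0, 3), 1)
    d2 <- pmin(d2, s2 - 15)
    out[[length(out) + 1L]] <- pair_rows(
      older, s2, d2,
      older$dx_date + ceiling(older$delay * runif(nrow(older), 0.1, 0.5))
    )
  }

  # ---- outcome-window readings --------------------------------------
  rd <- sc |>
    dplyr::filter(.data$mech != "short") |>
    dplyr::mutate(
      is_disc = .data$mech %in% c("discontinued_high", "disc_controlled"),
      lo = dplyr::case_when(
        is_disc ~ 14,
        late_kind == "12-14m" ~ 370, late_kind == "14-18m" ~ 430,
        late_kind == "18-24m" ~ 550, TRUE ~ vs$window_lo
      ),
      hi = dplyr::case_when(
        is_disc ~ .data$end_day - 183,
        late_kind == "12-14m" ~ 420, late_kind == "14-18m" ~ 540,
        late_kind == "18-24m" ~ 720, TRUE ~ vs$window_hi
      ),
      n_rd = 1L + rpois(dplyr::n(),
                        ifelse(.data$is_disc, 2,
                               vs$mean_outcome_readings - 1)),
      n_rd = pmin(.data$n_rd, floor(.data$hi - .data$lo)),
      n_rd = pmax(.data$n_rd, 1L),
      high_bp = .data$mech %in% c("bp_average", "discontinued_high"),
      m_sbp = dplyr::if_else(
        .data$high_bp,
        .data$avg_s + runif(dplyr::n(), 3, 14),
        dplyr::if_else(.data$mech == "bp_threshold",
                       .data$avg_s - runif(dplyr::n(), 8, 16),
                       .data$avg_s - runif(dplyr::n(), 6, 18))
      ),
      m_dbp = runif(dplyr::n(), 70, 82),
      bound_s = dplyr::if_else(.data$mech == "bp_threshold", 7, 12)
    )

  rd_long <- rd |>
    dplyr::select("patient_id", "start", "lo", "hi", "n_rd", "m_sbp", "m_dbp",
                  "bound_s", "mech", "max_s") |>
    tidyr::uncount(.data$n_rd, .remove = FALSE, .id = "i") |>
    dplyr::mutate(
      day = stratified_days(.data$i, .data$n_rd, .data$lo, .data$hi,
                            runif(dplyr::n())),
      dev_s = rnorm(dplyr::n(), 0, noise_sd),
      dev_d = rnorm(dplyr::n(), 0, noise_sd * 0.6)
    ) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::mutate(
      dev_s = center_scale(.data$dev_s, .data$bound_s[1]),
      dev_d = center_scale(.data$dev_d, 7)
    ) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      sbp = round(.data$m_sbp + .data$dev_s, 1),
      dbp = round(.data$m_dbp + .data$dev_d, 1),
      sbp = dplyr::if_else(.data$mech == "bp_threshold" & .data$i == 1,
                           .data$max_s + round(runif(dplyr::n(), 4, 12), 1),
                           .data$sbp),
      date = .data$start + .data$day
    )
  out[[length(out) + 1L]] <- pair_rows(rd_long, rd_long$sbp, rd_long$dbp,
                                       rd_long$date)

  # short-followup patients: early readings only
  sh <- dplyr::filter(sc, .data$mech == "short")
  if (nrow(sh) > 0) {
    for (k in 1:2) {
      out[[length(out) + 1L]] <- pair_rows(
        sh,
        round(sh$avg_s - runif(nrow(sh), 6, 18), 1),
        round(runif(nrow(sh), 70, 82), 1),
        sh$start + round(runif(nrow(sh), 30, 170))
      )
    }
  }

  # extra pre-window pair for half of the maintained, on-time patients
  extra_ok <- sc$viol == "none" & is.na(sc$late_kind) &
    sc$mech %in% c("success", "bp_average", "bp_threshold", "documented_ae",
                   "creatinine_rise", "kalemia", "natremia", "glucose",
                   "bradycardia")
  ex <- sc[extra_ok & runif(n) < 0.5, ]
  if (nrow(ex) > 0) {
    out[[length(out) + 1L]] <- pair_rows(
      ex,
      round(ex$avg_s - runif(nrow(ex), 6, 18), 1),
      round(runif(nrow(ex), 70, 82), 1),
      ex$start + round(runif(nrow(ex), 20, 170))
    )
  }

  # hypotension events
  hy <- dplyr::filter(sc, .data$mech == "hypotension")
  if (nrow(hy) > 0) {
    out[[length(out) + 1L]] <- pair_rows(
      hy,
      round(runif(nrow(hy), 80, 88), 1),
      round(runif(nrow(hy), 48, 58), 1),
      hy$start + round(runif(nrow(hy), 30, 170))
    )
  }

  # heart-rate rows: two normal per non-short patient, a bradycardic value
  # for the bradycardia mechanism, and a late follow-up marker row
  hr_rows <- function(d, value, date) {
    tibble::tibble(
      patient_id = d$patient_id, kind = "HR", value = value, date = date,
      position = "sitting", body_site = "arm", invasive_flag = FALSE,
      context = "ambulatory"
    )
  }
  nh <- dplyr::filter(sc, .data$mech != "short")
  for (k in 1:2) {
    out[[length(out) + 1L]] <- hr_rows(
      nh, pmin(pmax(round(rnorm(nrow(nh), 74, 8)), 55), 95),
      nh$start + round(runif(nrow(nh), 60, 300))
    )
  }
  br <- dplyr::filter(sc, .data$mech == "bradycardia")
  if (nrow(br) > 0) {
    out[[length(out) + 1L]] <- hr_rows(
      br, round(runif(nrow(br), 40, 48)),
      br$start + round(runif(nrow(br), 30, 300))
    )
  }
  out[[length(out) + 1L]] <- hr_rows(
    nh, pmin(pmax(round(rnorm(nrow(nh), 74, 8)), 55), 95),
    nh$start + round(runif(nrow(nh), 370, 450))
  )
  sh2 <- dplyr::filter(sc, .data$mech == "short")
  if (nrow(sh2) > 0) {
    out[[length(out) + 1L]] <- hr_rows(
      sh2, pmin(pmax(round(rnorm(nrow(sh2), 74, 8)), 55), 95),
      sh2$start + round(runif(nrow(sh2), 120, 190))
    )
  }

  # rows that must be removed by the measurement filter
  nz <- sc[runif(n) < 0.05, ]
  if (nrow(nz) > 0) {
    kindv <- sample(c("hospital", "exercise", "standing", "invasive", "wrist"),
                    nrow(nz), replace = TRUE)
    out[[length(out) + 1L]] <- pair_rows(
      nz,
      round(runif(nrow(nz), 150, 200), 1),
      round(runif(nrow(nz), 60, 100), 1),
      nz$start + round(runif(nrow(nz), 20, 300)),
      position = ifelse(kindv == "standing", "standing", "sitting"),
      body_site = ifelse(kindv == "wrist", "wrist", "arm"),
      invasive = kindv == "invasive",
      context = dplyr::case_when(
        kindv == "hospital" ~ "hospital",
        kindv == "exercise" ~ "exercise",
        TRUE ~ "ambulatory"
      )
    )
  }

  dplyr::bind_rows(out)
}

build_lab_rows <- function(sc) {
  n <- nrow(sc)
  lab_row <- function(d, analyte, value, units, date) {
    tibble::tibble(patient_id = d$patient_id, analyte = analyte,
                   value = value, units = units, date = date)
  }
  out <- list()
  base <- dplyr::filter(sc, .data$viol != "no_baseline_creatinine")
  out[[1]] <- lab_row(
    base, "creatinine", base$creatinine, "mg/dL",
    base$dx_date + ceiling(base$delay * runif(nrow(base), 0.2, 0.8))
  )

  post_day <- function(d) d$start + round(runif(nrow(d), 40, 330))
  keep <- sc[runif(n) < 0.8, ]
  out[[length(out) + 1L]] <- lab_row(
    keep, "creatinine", round(keep$creatinine * runif(nrow(keep), 0.85, 1.25), 2),
    "mg/dL", post_day(keep)
  )
  keep <- sc[runif(n) < 0.7, ]
  out[[length(out) + 1L]] <- lab_row(
    keep, "sodium", round(runif(nrow(keep), 134, 148), 1), "mEq/L",
    post_day(keep)
  )
  keep <- sc[runif(n) < 0.7, ]
  out[[length(out) + 1L]] <- lab_row(
    keep, "potassium", round(runif(nrow(keep), 3.7, 5.05), 2), "mEq/L",
    post_day(keep)
  )
  keep <- sc[runif(n) < 0.7, ]
  out[[length(out) + 1L]] <- lab_row(
    keep, "glucose_fasting", round(runif(nrow(keep), 82, 118)), "mg/dL",
    post_day(keep)
  )

  cr <- dplyr::filter(sc, .data$mech == "creatinine_rise")
  if (nrow(cr) > 0) {
    out[[length(out) + 1L]] <- lab_row(
      cr, "creatinine", round(cr$creatinine * runif(nrow(cr), 1.35, 1.8), 2),
      "mg/dL", post_day(cr)
    )
  }
  ka <- dplyr::filter(sc, .data$mech == "kalemia")
  if (nrow(ka) > 0) {
    low <- runif(nrow(ka)) < 0.5
    out[[length(out) + 1L]] <- lab_row(
      ka, "potassium",
      round(ifelse(low, runif(nrow(ka), 3.0, 3.45), runif(nrow(ka), 5.2, 5.9)), 2),
      "mEq/L", post_day(ka)
    )
  }
  na_ <- dplyr::filter(sc, .data$mech == "natremia")
  if (nrow(na_) > 0) {
    low <- runif(nrow(na_)) < 0.5
    out[[length(out) + 1L]] <- lab_row(
      na_, "sodium",
      round(ifelse(low, runif(nrow(na_), 124, 128.5),
                   runif(nrow(na_), 151.5, 156)), 1),
      "mEq/L", post_day(na_)
    )
  }
  gl <- dplyr::filter(sc, .data$mech == "glucose")
  if (nrow(gl) > 0) {
    out[[length(out) + 1L]] <- lab_row(
      gl, "glucose_fasting", round(runif(nrow(gl), 125, 180)), "mg/dL",
      post_day(gl)
    )
  }
  dplyr::bind_rows(out)
}
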