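# Cohort construction: measurement filters, inclusion/exclusion criteria,
# train/validation split.

#' Filter blood-pressure (and heart-rate) measurements to valid ambulatory rows
#'
#' Retains only non-invasive, sitting, arm, ambulatory-context measurements;
#' rows recorded during hospitalization, exercise, operation, anesthesia or
#' dialysis, in another position, on another body site, or invasively are
#' removed.
#'
#' @param vitals The `vitals` table of an [ehr_bundle()].
#' @return The retained rows.
#' @export
filter_bp_measurements <- function(vitals) {
  dplyr::filter(
    vitals,
    !.data$invasive_flag,
    .data$position == "sitting",
    .data$body_site == "arm",
    .data$context == "ambulatory"
  )
}

first_htn_dx <- function(diagnoses) {
  diagnoses |>
    dplyr::filter(.data$code == CONDITION_CODES[["hypertension"]],
                  .data$setting == "ambulatory") |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(dx_date = min(.data$date), .groups = "drop")
}

last_record_date <- function(bundle) {
  dates <- dplyr::bind_rows(
    dplyr::select(bundle$diagnoses, "patient_id", "date"),
    dplyr::select(bundle$vitals, "patient_id", "date"),
    dplyr::select(bundle$labs, "patient_id", "date"),
    dplyr::transmute(bundle$medications, .data$patient_id,
                     date = dplyr::coalesce(.data$end_date, .data$start_date)),
    dplyr::select(bundle$allergies, "patient_id", "date")
  )
  dplyr::summarise(dplyr::group_by(dates, .data$patient_id),
                   last_date = max(.data$date), .groups = "drop")
}

first_record_date <- function(bundle) {
  dates <- dplyr::bind_rows(
    dplyr::select(bundle$diagnoses, "patient_id", "date"),
    dplyr::select(bundle$vitals, "patient_id", "date"),
    dplyr::select(bundle$labs, "patient_id", "date"),
    dplyr::select(dplyr::rename(bundle$medications, date = "start_date"),
                  "patient_id", "date"),
    dplyr::select(bundle$allergies, "patient_id", "date")
  )
  dplyr::summarise(dplyr::group_by(dates, .data$patient_id),
                   first_date = min(.data$date), .groups = "drop")
}

#' Apply the inclusion criteria
#'
#' Checks every criterion for every patient and records all failures (not
#' just the first): a primary-hypertension diagnosis; established care before
#' the diagnosis (at least one earlier record of any type); first
#' antihypertensive start within 270 days of diagnosis; at least 365 days of
#' data after treatment start; at least one valid blood-pressure reading and
#' one creatinine within 365 days before treatment start; and a measurable
#' outcome (at least one usable reading in the outcome windows).
#'
#' @param bundle An `ehr_bundle`.
#' @param episodes Optional precomputed [initial_treatment()] table; computed
#'   from the bundle when omitted.
#' @return An eligibility tibble: `patient_id`, `included`, `failed_criteria`
#'   (list-column), `dx_date`, `treatment_start`.
#' @export
apply_inclusion <- function(bundle, episodes = NULL) {
  if (is.null(episodes)) {
    episodes <- initial_treatment(
      build_timeline(normalize_medications(bundle$medications))
    )
  }
  pts <- dplyr::select(bundle$patients, "patient_id")
  dx <- first_htn_dx(bundle$diagnoses)
  firsts <- first_record_date(bundle)
  lasts <- last_record_date(bundle)
  valid_bp <- bp_reading_pairs(filter_bp_measurements(bundle$vitals))

  eg <- pts |>
    dplyr::left_join(dx, by = "patient_id") |>
    dplyr::left_join(dplyr::select(episodes, "patient_id", "start", "end"),
                     by = "patient_id") |>
    dplyr::left_join(firsts, by = "patient_id") |>
    dplyr::left_join(lasts, by = "patient_id")

  # Baseline measurements within a year before treatment start.
  base_bp <- valid_bp |>
    dplyr::inner_join(dplyr::select(eg, "patient_id", "start"),
                      by = "patient_id") |>
    dplyr::filter(!is.na(.data$start), .data$date < .data$start,
                  .data$date >= .data$start - DAYS_1_YEAR) |>
    dplyr::distinct(.data$patient_id) |>
    dplyr::mutate(has_base_bp = TRUE)
  base_cr <- bundle$labs |>
    dplyr::filter(.data$analyte == "creatinine") |>
    dplyr::inner_join(dplyr::select(eg, "patient_id", "start"),
                      by = "patient_id") |>
    dplyr::filter(!is.na(.data$start), .data$date < .data$start,
                  .data$date >= .data$start - DAYS_1_YEAR) |>
    dplyr::distinct(.data$patient_id) |>
    dplyr::mutate(has_base_cr = TRUE)

  labels <- label_cohort(bundle, dplyr::semi_join(episodes, eg, by = "patient_id"))
  # Outcome is documented when the label is determinate (success/failure,
  # e.g. via an adverse-effect criterion) or when the exclusion itself is an
  # outcome-rule decision backed by readings (discontinued-controlled).
  measurable <- dplyr::transmute(
    labels, .data$patient_id,
    measurable = .data$status != "excluded" | .data$n_bp_readings > 0
  )

  eg <- eg |>
    dplyr::left_join(base_bp, by = "patient_id") |>
    dplyr::left_join(base_cr, by = "patient_id") |>
    dplyr::left_join(measurable, by = "patient_id") |>
    dplyr::mutate(
      has_base_bp = dplyr::coalesce(.data$has_base_bp, FALSE),
      has_base_cr = dplyr::coalesce(.data$has_base_cr, FALSE),
      measurable = dplyr::coalesce(.data$measurable, FALSE),
      fail_dx = is.na(.data$dx_date),
      fail_care = is.na(.data$first_date) | is.na(.data$dx_date) |
        .data$first_date >= .data$dx_date,
      fail_window = is.na(.data$start) | is.na(.data$dx_date) |
        as.integer(.data$start - .data$dx_date) > DAYS_9_MONTHS |
        .data$start < .data$dx_date,
      fail_followup = is.na(.data$start) | is.na(.data$last_date) |
        as.integer(.data$last_date - .data$start) < DAYS_1_YEAR,
      fail_base_bp = !.data$has_base_bp,
      fail_base_cr = !.data$has_base_cr,
      fail_outcome = !.data$measurable
    )

  fails <- cbind(
    primary_htn_dx = eg$fail_dx,
    prior_care = eg$fail_care,
    treatment_within_9_months = eg$fail_window,
    followup_1yr = eg$fail_followup,
    baseline_bp = eg$fail_base_bp,
    baseline_creatinine = eg$fail_base_cr,
    outcome_measurable = eg$fail_outcome
  )
  failed <- apply(fails, 1L, function(row) INCLUSION_CRITERIA[row],
                  simplify = FALSE)
  tibble::tibble(
    patient_id = eg$patient_id,
    included = lengths(failed) == 0,
    failed_criteria = failed,
    dx_date = eg$dx_date,
    treatment_start = eg$start
  )
}

#' Apply the exclusion criteria
#'
#' Excludes patients with a first diabetes or prediabetes diagnosis within
#' 365 days after treatment start, and episodes containing an (ingredient,
#' daily-dose) pair prescribed fewer than twice cohort-wide. The rare-pair
#' rule is iterated to a fixed point, since removing an episode can make
#' another pair rare.
#'
#' @param records Eligibility tibble from [apply_inclusion()].
#' @param bundle An `ehr_bundle`.
#' @param episodes Optional precomputed episode table.
#' @return The updated eligibility tibble.
#' @export
apply_exclusions <- function(records, bundle, episodes = NULL) {
  if (is.null(episodes)) {
    episodes <- initial_treatment(
      build_timeline(normalize_medications(bundle$medications))
    )
  }
  dm_codes <- CONDITION_CODES[c("diabetes", "prediabetes")]
  dm_rows <- dplyr::filter(bundle$diagnoses, .data$code %in% dm_codes)
  first_dm <- if (nrow(dm_rows) == 0) {
    tibble::tibble(patient_id = integer(), first_dm = as.Date(character()))
  } else {
    dm_rows |>
      dplyr::group_by(.data$patient_id) |>
      dplyr::summarise(first_dm = min(.data$date), .groups = "drop")
  }

  rec <- dplyr::left_join(records, first_dm, by = "patient_id")
  new_dm <- !is.na(rec$first_dm) & !is.na(rec$treatment_start) &
    rec$first_dm > rec$treatment_start &
    as.integer(rec$first_dm - rec$treatment_start) <= DAYS_1_YEAR

  add_failure <- function(failed, idx, criterion) {
    failed[idx] <- purrr::map(failed[idx], ~ unique(c(.x, criterion)))
    failed
  }
  failed <- rec$failed_criteria
  failed <- add_failure(failed, which(new_dm), "new_diabetes")

  # Rare ingredient-dose pairs, iterated to a fixed point over the currently
  # retained cohort.
  comp <- episodes |>
    dplyr::select("patient_id", "components") |>
    tidyr::unnest("components") |>
    dplyr::mutate(pair = paste0(.data$ingredient, ":", .data$daily_dose_mg))
  active <- rec$patient_id[lengths(failed) == 0]
  repeat {
    pair_counts <- comp |>
      dplyr::filter(.data$patient_id %in% active) |>
      dplyr::count(.data$pair)
    rare <- pair_counts$pair[pair_counts$n < 2]
    drop <- unique(comp$patient_id[comp$pair %in% rare &
                                     comp$patient_id %in% active])
    if (length(drop) == 0) break
    failed <- add_failure(failed, match(drop, rec$patient_id), "rare_pair")
    active <- setdiff(active, drop)
  }

  tibble::tibble(
    patient_id = rec$patient_id,
    included = lengths(failed) == 0,
    failed_criteria = failed,
    dx_date = rec$dx_date,
    treatment_start = rec$treatment_start
  )
}

#' Split included patients into training and validation sets
#'
#' Disjoint, exhaustive over the included ids, reproducible under `seed`.
#'
#' @param included_ids Vector of included patient ids.
#' @param n_validation Number of validation patients (must be smaller than the
#'   cohort).
#' @param seed Integer seed.
#' @return A list with `train` and `validation` id vectors.
#' @export
split_train_validation <- function(included_ids, n_validation, seed) {
  if (n_validation >= length(included_ids)) {
    abort("n_validation must be smaller than the included cohort",
          class = "htnrec_argument_error")
  }
  validation <- withr::with_seed(
    seed, sort(sample(included_ids, n_validation))
  )
  list(train = sort(setdiff(included_ids, validation)), validation = validation)
}

#' Build the analyzable cohort from a bundle
#'
#' Convenience wrapper: medication normalization, initial episodes, inclusion
#' then exclusion criteria, outcome labels for the included patients.
#'
#' @param bundle An `ehr_bundle`.
#' @param grace_days Grace window for grouping staggered starts (days).
#' @return A list of class `htn_cohort`: `eligibility`, `episodes` (all
#'   patients), `included_episodes`, `labels` (included patients only).
#' @export
build_cohort <- function(bundle, grace_days = 14) {
  episodes <- initial_treatment(
    build_timeline(normalize_medications(bundle$medications)),
    grace_days = grace_days
  )
  eligibility <- apply_inclusion(bundle, episodes)
  eligibility <- apply_exclusions(eligibility, bundle, episodes)
  included <- dplyr::semi_join(
    episodes,
    dplyr::filter(eligibility, .data$included),
    by = "patient_id"
  )
  labels <- label_cohort(bundle, included)
  structure(
    list(eligibility = eligibility, episodes = episodes,
         included_episodes = included, labels = labels),
    class = "htn_cohort"
  )
}
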