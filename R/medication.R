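# Medication normalization: code -> ingredient/class, sig -> daily dose,
# prescription rows -> merged ingredient-dose timelines -> initial episode.

#' Normalize prescription rows to ingredient + daily-dose resolution
#'
#' Decomposes combination products into their ingredients (one row each),
#' parses sig text into administrations per day, and computes
#' `daily_dose_mg = unit strength x units per day` per ingredient. This is the
#' consistency step: a combination pill and the equivalent separate pills
#' normalize to identical (ingredient, daily dose) rows.
#'
#' @param medications The `medications` table of an [ehr_bundle()].
#' @return A tibble with one row per (prescription, ingredient):
#'   `patient_id`, `code`, `ingredient`, `drug_class`, `daily_dose_mg`,
#'   `start_date`, `end_date`, `unmapped`.
#' @export
normalize_medications <- function(medications) {
  if (nrow(medications) == 0) {
    return(tibble::tibble(
      patient_id = integer(), code = character(), ingredient = character(),
      drug_class = character(), daily_dose_mg = double(),
      start_date = as.Date(character()), end_date = as.Date(character()),
      unmapped = logical()
    ))
  }
  per_row <- dplyr::mutate(medications, .row = dplyr::row_number())
  # A combination code contributes one normalized row per ingredient.
  joined <- dplyr::left_join(
    per_row,
    dplyr::select(rx_class_map(), "code", "ingredient", "drug_class", "unit_mg"),
    by = "code", relationship = "many-to-many"
  )
  unmapped <- is.na(joined$ingredient)
  parsed <- parse_sig(joined$sig_text[!unmapped], joined$unit_mg[!unmapped])
  joined$daily_dose_mg <- NA_real_
  joined$daily_dose_mg[!unmapped] <- parsed$daily_dose_mg
  if (any(unmapped)) {
    warn(sprintf("%d prescription row(s) flagged unmapped", sum(unmapped)))
  }
  tibble::tibble(
    patient_id = joined$patient_id,
    code = joined$code,
    ingredient = joined$ingredient,
    drug_class = joined$drug_class,
    daily_dose_mg = joined$daily_dose_mg,
    start_date = joined$start_date,
    end_date = joined$end_date,
    unmapped = unmapped
  )
}

#' Build merged ingredient-dose timelines
#'
#' Per (patient, ingredient, daily dose), merges overlapping or abutting
#' prescription intervals (gap of one day counts as abutting) into maximal
#' intervals; an interval is open-ended when any contributing prescription has
#' no end date. Merging is order-independent.
#'
#' @param normalized Output of [normalize_medications()] (unmapped rows are
#'   dropped with a warning).
#' @return A tibble of `IngredientDoseInterval` rows: `patient_id`,
#'   `ingredient`, `drug_class`, `daily_dose_mg`, `start`, `end` (`NA` = open).
#' @export
build_timeline <- function(normalized) {
  if (any(normalized$unmapped)) {
    warn(sprintf("Dropping %d unmapped prescription row(s) from the timeline",
                 sum(normalized$unmapped)))
    normalized <- dplyr::filter(normalized, !.data$unmapped)
  }
  if (any(!is.na(normalized$end_date) &
            normalized$end_date < normalized$start_date)) {
    abort("Prescription end_date before start_date",
          class = "htnrec_validation_error")
  }
  if (nrow(normalized) == 0) {
    return(tibble::tibble(
      patient_id = integer(), ingredient = character(),
      drug_class = character(), daily_dose_mg = double(),
      start = as.Date(character()), end = as.Date(character())
    ))
  }
  out <- normalized |>
    dplyr::mutate(
      end_eff = dplyr::if_else(is.na(.data$end_date),
                               as.Date("9999-12-31"), .data$end_date)
    ) |>
    dplyr::group_by(.data$patient_id, .data$ingredient, .data$drug_class,
                    .data$daily_dose_mg) |>
    dplyr::arrange(.data$start_date, .by_group = TRUE) |>
    dplyr::mutate(
      # New run whenever a prescription starts more than one day after the
      # running maximum end of its predecessors.
      new_run = .data$start_date >
        dplyr::lag(cummax(as.integer(.data$end_eff)) + 1L,
                   default = -.Machine$integer.max),
      run = cumsum(.data$new_run)
    ) |>
    dplyr::group_by(.data$run, .add = TRUE) |>
    dplyr::summarise(
      start = min(.data$start_date),
      end = dplyr::if_else(any(is.na(.data$end_date)),
                           as.Date(NA), max(.data$end_date)),
      .groups = "drop"
    ) |>
    dplyr::select(-"run") |>
    dplyr::arrange(.data$patient_id, .data$ingredient, .data$daily_dose_mg,
                   .data$start)
  out
}

#' Extract the initial treatment episode per patient
#'
#' The analysis unit is the first regimen: every ingredient-dose interval
#' whose start falls within `grace_days` of the patient's earliest
#' antihypertensive start is one episode; near-simultaneous starts form a
#' combination. The episode ends at the earliest component end (open if all
#' components are open-ended).
#'
#' @param timeline Output of [build_timeline()].
#' @param grace_days Window (days) for grouping staggered starts into one
#'   initial regimen; default 14.
#' @return A tibble with one row per patient: `patient_id`, `treatment_id`,
#'   `class_label`, `start`, `end`, and a `components` list-column of
#'   (ingredient, drug_class, daily_dose_mg).
#' @export
initial_treatment <- function(timeline, grace_days = 14) {
  if (nrow(timeline) == 0) {
    return(tibble::tibble(
      patient_id = integer(), treatment_id = character(),
      class_label = character(), start = as.Date(character()),
      end = as.Date(character()), components = list()
    ))
  }
  first_start <- timeline |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(first_start = min(.data$start), .groups = "drop")
  comp <- timeline |>
    dplyr::inner_join(first_start, by = "patient_id") |>
    dplyr::filter(as.integer(.data$start - .data$first_start) <= grace_days) |>
    # One interval per (ingredient, dose): keep the earliest if duplicated.
    dplyr::group_by(.data$patient_id, .data$ingredient, .data$drug_class,
                    .data$daily_dose_mg) |>
    dplyr::slice_min(.data$start, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()

  episodes <- comp |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(
      treatment_id = make_treatment_id(.data$ingredient, .data$daily_dose_mg),
      class_label = class_label(.data$drug_class),
      start = min(.data$start),
      # Earliest discontinuation of any component; open only if every
      # component is open-ended.
      end = dplyr::if_else(all(is.na(.data$end)), as.Date(NA),
                           suppressWarnings(min(.data$end, na.rm = TRUE))),
      components = list(tibble::tibble(
        ingredient = ingredient,
        drug_class = drug_class,
        daily_dose_mg = daily_dose_mg
      )),
      .groups = "drop"
    )
  episodes
}
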