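# Rule-based treatment-success labelling: JNC 8 blood-pressure control plus
# adverse-effect failure criteria over the initial treatment episode.

#' Age-dependent JNC 8 blood-pressure limits
#'
#' Patients under 60 must average below 140/90 mm Hg and never exceed
#' 160 systolic or 90 diastolic in the outcome window; patients 60 and over
#' must average below 150/90 and never exceed 170/90. Age exactly 60 takes
#' the older branch (the guideline's own cutoff is >= 60).
#'
#' @param age_years Age at treatment start (vectorized).
#' @return A tibble with `avg_sbp_limit`, `avg_dbp_limit`, `max_sbp_limit`,
#'   `max_dbp_limit`.
#' @export
#' @examples
#' bp_thresholds(c(45, 75))
bp_thresholds <- function(age_years) {
  stopifnot(all(age_years > 0))
  older <- age_years >= 60
  tibble::tibble(
    avg_sbp_limit = ifelse(older, 150, 140),
    avg_dbp_limit = 90,
    max_sbp_limit = ifelse(older, 170, 160),
    max_dbp_limit = 90
  )
}

# Window day ranges relative to treatment start. The primary outcome window is
# 6-12 months; if it is empty and the regimen is maintained, the earliest
# non-empty of 12-14, 14-18, 18-24 months is used.
window_defs <- function() {
  tibble::tibble(
    window = c("6-12m", "12-14m", "14-18m", "18-24m"),
    lo = c(DAYS_6_MONTHS, DAYS_1_YEAR + 1L, DAYS_14_MONTHS + 1L,
           DAYS_18_MONTHS + 1L),
    hi = c(DAYS_1_YEAR, DAYS_14_MONTHS, DAYS_18_MONTHS, DAYS_24_MONTHS)
  )
}

#' Select the blood-pressure outcome window for an episode
#'
#' For a maintained episode the primary window is 6-12 months after treatment
#' start; if it holds no readings, the earliest non-empty of 12-14, 14-18 and
#' 18-24 months is used (readings only count while the regimen is maintained).
#' If the episode ended before one year, the window is readings at least 14
#' days after start and at least 6 months before the episode end.
#'
#' @param readings Tibble of valid ambulatory readings for one patient, with
#'   columns `day` (days since treatment start), `sbp`, `dbp` (either may be
#'   `NA` when unpaired).
#' @param episode_end_day Days from start to episode end, or `NA` if open.
#' @return A list with `window` (id, or `NA` when no window holds a reading)
#'   and `readings` (the rows used).
#' @export
select_bp_window <- function(readings, episode_end_day = NA) {
  ended_early <- !is.na(episode_end_day) && episode_end_day < DAYS_1_YEAR
  if (ended_early) {
    used <- dplyr::filter(
      readings,
      .data$day >= MIN_POST_TREATMENT_DAYS,
      .data$day <= episode_end_day - DAYS_6_MONTHS
    )
    return(list(
      window = if (nrow(used) > 0) "discontinuation" else NA_character_,
      readings = used
    ))
  }
  defs <- window_defs()
  for (i in seq_len(nrow(defs))) {
    used <- dplyr::filter(
      readings, .data$day >= defs$lo[i], .data$day <= defs$hi[i],
      is.na(episode_end_day) | .data$day <= episode_end_day
    )
    if (nrow(used) > 0) {
      return(list(window = defs$window[i], readings = used))
    }
  }
  list(window = NA_character_, readings = readings[0, , drop = FALSE])
}

#' Blood-pressure control decision for a set of readings
#'
#' Controlled means the mean systolic and mean diastolic are strictly below
#' the average limits and no single reading exceeds the maximum limits
#' (strictly above fails). Zero readings is indeterminate, never success.
#'
#' @param readings Tibble with `sbp`, `dbp` columns (NA allowed when unpaired).
#' @param thresholds One row of [bp_thresholds()].
#' @return `TRUE`, `FALSE`, or `NA` (indeterminate); when `FALSE`, the
#'   attribute `"reason"` is `"bp_average"` or `"bp_threshold"`.
#' @export
bp_control_outcome <- function(readings, thresholds) {
  sbp <- readings$sbp[!is.na(readings$sbp)]
  dbp <- readings$dbp[!is.na(readings$dbp)]
  if (length(sbp) + length(dbp) == 0) return(NA)
  # a reading past the high threshold is the reported reason even when the
  # average criterion is also violated
  max_ok <- all(sbp <= thresholds$max_sbp_limit) &&
    all(dbp <= thresholds$max_dbp_limit)
  if (!max_ok) return(structure(FALSE, reason = "bp_threshold"))
  avg_ok <- (length(sbp) == 0 || mean(sbp) < thresholds$avg_sbp_limit) &&
    (length(dbp) == 0 || mean(dbp) < thresholds$avg_dbp_limit)
  if (!avg_ok) return(structure(FALSE, reason = "bp_average"))
  TRUE
}

# Chronological adverse-event scan shared by the per-episode and vectorized
# labelers. Events are searched from the day after treatment start through the
# episode end; ties on the same day resolve in fixed criterion order.
ae_priority <- c(
  hypotension = 1, bradycardia = 2, creatinine_rise = 3, natremia = 4,
  kalemia = 5, glucose = 6, documented_ae = 7
)

#' Adverse-effect failure criteria for one episode
#'
#' Scans filtered ambulatory vitals, labs and documented allergy-table events
#' within the episode for the failure criteria: hypotension (SBP < 90 or
#' DBP < 60), bradycardia (HR < 50), creatinine rise (> 30% over baseline),
#' dysnatremia (< 130 or > 150 mEq/L), dyskalemia (< 3.6 or > 5.1 mEq/L),
#' elevated fasting glucose (> 120 mg/dL), or a documented moderate/severe
#' adverse effect (mild events never count). The chronologically first
#' criterion is returned.
#'
#' @param labs,vitals,allergies Patient-level tables (vitals already passed
#'   through [filter_bp_measurements()] for BP/HR validity).
#' @param baseline_creatinine Latest pre-treatment creatinine (mg/dL).
#' @param start Episode start date.
#' @param end Episode end date or `NA`.
#' @return `NA_character_` or one of the failure reasons.
#' @export
adverse_effect_failure <- function(labs, vitals, allergies,
                                   baseline_creatinine, start, end = NA) {
  end_day <- if (is.na(end)) Inf else as.integer(end - start)
  events <- list()
  addev <- function(day, reason) {
    events[[length(events) + 1L]] <<- tibble::tibble(day = day, reason = reason)
  }

  if (nrow(vitals) > 0) {
    v <- dplyr::mutate(vitals, day = as.integer(.data$date - start))
    v <- dplyr::filter(v, .data$day >= 1, .data$day <= end_day)
    hypo <- dplyr::filter(v, (.data$kind == "SBP" & .data$value < 90) |
                            (.data$kind == "DBP" & .data$value < 60))
    if (nrow(hypo) > 0) addev(min(hypo$day), "hypotension")
    brady <- dplyr::filter(v, .data$kind == "HR", .data$value < 50)
    if (nrow(brady) > 0) addev(min(brady$day), "bradycardia")
  }
  if (nrow(labs) > 0) {
    l <- dplyr::mutate(labs, day = as.integer(.data$date - start))
    l <- dplyr::filter(l, .data$day >= 1, .data$day <= end_day)
    creat <- dplyr::filter(l, .data$analyte == "creatinine",
                           .data$value > 1.3 * baseline_creatinine)
    if (nrow(creat) > 0) addev(min(creat$day), "creatinine_rise")
    na_ev <- dplyr::filter(l, .data$analyte == "sodium",
                           .data$value < 130 | .data$value > 150)
    if (nrow(na_ev) > 0) addev(min(na_ev$day), "natremia")
    k_ev <- dplyr::filter(l, .data$analyte == "potassium",
                          .data$value < 3.6 | .data$value > 5.1)
    if (nrow(k_ev) > 0) addev(min(k_ev$day), "kalemia")
    g_ev <- dplyr::filter(l, .data$analyte == "glucose_fasting",
                          .data$value > 120)
    if (nrow(g_ev) > 0) addev(min(g_ev$day), "glucose")
  }
  if (nrow(allergies) > 0) {
    a <- dplyr::mutate(allergies, day = as.integer(.data$date - start))
    a <- dplyr::filter(a, .data$day >= 0, .data$day <= end_day,
                       .data$severity %in% c("moderate", "severe"))
    if (nrow(a) > 0) addev(min(a$day), "documented_ae")
  }
  if (length(events) == 0) return(NA_character_)
  ev <- dplyr::bind_rows(events)
  ev <- dplyr::arrange(ev, .data$day, ae_priority[.data$reason])
  ev$reason[1]
}

#' Label one treatment episode
#'
#' Applies the full treatment-success rule: failure if any adverse-effect
#' criterion fires or the selected blood-pressure window is uncontrolled;
#' episodes discontinued before one year are failures when pre-discontinuation
#' pressures were high and excluded when controlled (year-long success is
#' unobservable); success requires a maintained episode, a controlled window,
#' and no moderate/severe adverse effect. Episodes with no usable reading are
#' excluded (indeterminate).
#'
#' @param patient_id Patient identifier.
#' @param episode One row of [initial_treatment()] output (needs `start`,
#'   `end`).
#' @param bundle An `ehr_bundle`.
#' @return A one-row tibble: `patient_id`, `status`, `failure_reason`,
#'   `bp_window_used`, `n_bp_readings`.
#' @export
label_treatment <- function(patient_id, episode, bundle) {
  pid <- patient_id
  start <- episode$start
  end <- episode$end
  vit <- filter_bp_measurements(
    dplyr::filter(bundle$vitals, .data$patient_id == pid)
  )
  labs <- dplyr::filter(bundle$labs, .data$patient_id == pid)
  alg <- dplyr::filter(bundle$allergies, .data$patient_id == pid)

  base_cr <- labs |>
    dplyr::filter(.data$analyte == "creatinine", .data$date < start) |>
    dplyr::slice_max(.data$date, n = 1, with_ties = FALSE)
  baseline_creatinine <- if (nrow(base_cr) > 0) base_cr$value else NA_real_

  reason <- adverse_effect_failure(labs, vit, alg, baseline_creatinine,
                                   start, end)

  readings <- bp_reading_pairs(vit) |>
    dplyr::mutate(day = as.integer(.data$date - start)) |>
    dplyr::filter(.data$day >= 1)
  end_day <- if (is.na(end)) NA_integer_ else as.integer(end - start)
  sel <- select_bp_window(readings, end_day)

  age <- patient_age(bundle$patients, pid, start)
  controlled <- if (nrow(sel$readings) > 0) {
    bp_control_outcome(sel$readings, bp_thresholds(age))
  } else NA

  lab_row <- function(status, failure_reason = NA_character_) {
    tibble::tibble(
      patient_id = pid, status = status, failure_reason = failure_reason,
      bp_window_used = sel$window %||% NA_character_,
      n_bp_readings = nrow(sel$readings)
    )
  }

  if (!is.na(reason)) return(lab_row("failure", reason))
  if (is.na(controlled)) return(lab_row("excluded"))
  ended_early <- !is.na(end_day) && end_day < DAYS_1_YEAR
  if (!controlled) return(lab_row("failure", attr(controlled, "reason")))
  if (ended_early) return(lab_row("excluded"))  # controlled, then discontinued
  lab_row("success")
}

# Pair SBP/DBP rows recorded at the same timestamp into readings.
bp_reading_pairs <- function(vitals) {
  bp <- dplyr::filter(vitals, .data$kind %in% c("SBP", "DBP"))
  if (nrow(bp) == 0) {
    return(tibble::tibble(patient_id = integer(), date = as.Date(character()),
                          sbp = double(), dbp = double()))
  }
  tidyr::pivot_wider(
    bp, id_cols = c("patient_id", "date"),
    names_from = "kind", values_from = "value", values_fn = mean
  ) |>
    dplyr::rename_with(tolower, dplyr::any_of(c("SBP", "DBP"))) |>
    (\(d) {
      if (!"sbp" %in% names(d)) d$sbp <- NA_real_
      if (!"dbp" %in% names(d)) d$dbp <- NA_real_
      d
    })()
}

patient_age <- function(patients, pid, at_date) {
  row <- dplyr::filter(patients, .data$patient_id == pid)
  as.numeric(at_date - row$birth_date) / 365.25
}

#' Label every episode in a cohort (vectorized)
#'
#' Equivalent to mapping [label_treatment()] over episodes, implemented with
#' grouped table operations so cohorts of tens of thousands label in seconds.
#'
#' @param bundle An `ehr_bundle`.
#' @param episodes Episode table from [initial_treatment()].
#' @return A tibble: `patient_id`, `status`, `failure_reason`,
#'   `bp_window_used`, `n_bp_readings`.
#' @export
label_cohort <- function(bundle, episodes) {
  if (nrow(episodes) == 0) {
    return(tibble::tibble(
      patient_id = integer(), status = character(),
      failure_reason = character(), bp_window_used = character(),
      n_bp_readings = integer()
    ))
  }
  ep <- episodes |>
    dplyr::left_join(dplyr::select(bundle$patients, "patient_id", "birth_date"),
                     by = "patient_id") |>
    dplyr::mutate(
      age = as.numeric(.data$start - .data$birth_date) / 365.25,
      end_day = as.integer(.data$end - .data$start)
    )
  thr <- bp_thresholds(ep$age)
  ep <- dplyr::bind_cols(dplyr::select(
    ep, "patient_id", "start", "end_day"), thr)

  vit <- filter_bp_measurements(bundle$vitals) |>
    dplyr::inner_join(dplyr::select(ep, "patient_id", "start", "end_day"),
                      by = "patient_id") |>
    dplyr::mutate(day = as.integer(.data$date - .data$start))

  # --- adverse events ---------------------------------------------------
  in_episode <- function(d, day_col = "day", from = 1) {
    dplyr::filter(d, .data[[day_col]] >= from,
                  is.na(.data$end_day) | .data[[day_col]] <= .data$end_day)
  }
  ev_hypo <- vit |>
    dplyr::filter((.data$kind == "SBP" & .data$value < 90) |
                    (.data$kind == "DBP" & .data$value < 60)) |>
    in_episode() |>
    dplyr::transmute(.data$patient_id, .data$day, reason = "hypotension")
  ev_brady <- vit |>
    dplyr::filter(.data$kind == "HR", .data$value < 50) |>
    in_episode() |>
    dplyr::transmute(.data$patient_id, .data$day, reason = "bradycardia")

  labs <- bundle$labs |>
    dplyr::inner_join(dplyr::select(ep, "patient_id", "start", "end_day"),
                      by = "patient_id") |>
    dplyr::mutate(day = as.integer(.data$date - .data$start))
  base_cr <- labs |>
    dplyr::filter(.data$analyte == "creatinine", .data$day < 0) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::slice_max(.data$day, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::select("patient_id", baseline_creatinine = "value")
  post_labs <- in_episode(labs) |>
    dplyr::left_join(base_cr, by = "patient_id")
  ev_lab <- post_labs |>
    dplyr::mutate(reason = dplyr::case_when(
      analyte == "creatinine" & !is.na(baseline_creatinine) &
        value > 1.3 * baseline_creatinine ~ "creatinine_rise",
      analyte == "sodium" & (value < 130 | value > 150) ~ "natremia",
      analyte == "potassium" & (value < 3.6 | value > 5.1) ~ "kalemia",
      analyte == "glucose_fasting" & value > 120 ~ "glucose",
      TRUE ~ NA_character_
    )) |>
    dplyr::filter(!is.na(.data$reason)) |>
    dplyr::select("patient_id", "day", "reason")

  ev_ae <- bundle$allergies |>
    dplyr::filter(.data$severity %in% c("moderate", "severe")) |>
    dplyr::inner_join(dplyr::select(ep, "patient_id", "start", "end_day"),
                      by = "patient_id") |>
    dplyr::mutate(day = as.integer(.data$date - .data$start)) |>
    in_episode(from = 0) |>
    dplyr::transmute(.data$patient_id, .data$day, reason = "documented_ae")

  ae <- dplyr::bind_rows(ev_hypo, ev_brady, ev_lab, ev_ae)
  ae_first <- if (nrow(ae) > 0) {
    ae |>
      dplyr::group_by(.data$patient_id) |>
      dplyr::arrange(.data$day, ae_priority[.data$reason], .by_group = TRUE) |>
      dplyr::slice_head(n = 1) |>
      dplyr::ungroup() |>
      dplyr::select("patient_id", ae_reason = "reason")
  } else {
    tibble::tibble(patient_id = integer(), ae_reason = character())
  }

  # --- window selection and control -------------------------------------
  readings <- bp_reading_pairs(filter_bp_measurements(bundle$vitals)) |>
    dplyr::inner_join(ep, by = "patient_id") |>
    dplyr::mutate(day = as.integer(.data$date - .data$start)) |>
    dplyr::filter(.data$day >= 1)

  ended_early <- !is.na(readings$end_day) & readings$end_day < DAYS_1_YEAR
  defs <- window_defs()
  readings$window <- NA_character_
  # Maintained episodes: month-window membership, readings only while on the
  # regimen for fallback windows.
  for (i in seq_len(nrow(defs))) {
    hit <- !ended_early & is.na(readings$window) &
      readings$day >= defs$lo[i] & readings$day <= defs$hi[i] &
      (is.na(readings$end_day) | readings$day <= readings$end_day)
    readings$window[hit] <- defs$window[i]
  }
  hit <- ended_early & readings$day >= MIN_POST_TREATMENT_DAYS &
    readings$day <= readings$end_day - DAYS_6_MONTHS
  readings$window[hit] <- "discontinuation"

  win_order <- c("6-12m" = 1, "12-14m" = 2, "14-18m" = 3, "18-24m" = 4,
                 "discontinuation" = 1)
  win_stats <- readings |>
    dplyr::filter(!is.na(.data$window)) |>
    dplyr::group_by(.data$patient_id, .data$window) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_sbp = mean(.data$sbp, na.rm = TRUE),
      mean_dbp = mean(.data$dbp, na.rm = TRUE),
      max_sbp = suppressWarnings(max(.data$sbp, na.rm = TRUE)),
      max_dbp = suppressWarnings(max(.data$dbp, na.rm = TRUE)),
      .groups = "drop"
    ) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::arrange(win_order[.data$window], .by_group = TRUE) |>
    dplyr::slice_head(n = 1) |>
    dplyr::ungroup()

  out <- ep |>
    dplyr::left_join(ae_first, by = "patient_id") |>
    dplyr::left_join(win_stats, by = "patient_id") |>
    dplyr::mutate(
      n = dplyr::coalesce(.data$n, 0L),
      ended_early = !is.na(.data$end_day) & .data$end_day < DAYS_1_YEAR,
      avg_fail = (!is.nan(.data$mean_sbp) &
                    .data$mean_sbp >= .data$avg_sbp_limit) |
        (!is.nan(.data$mean_dbp) & .data$mean_dbp >= .data$avg_dbp_limit),
      thr_fail = (is.finite(.data$max_sbp) &
                    .data$max_sbp > .data$max_sbp_limit) |
        (is.finite(.data$max_dbp) & .data$max_dbp > .data$max_dbp_limit),
      status = dplyr::case_when(
        !is.na(ae_reason) ~ "failure",
        n == 0 ~ "excluded",
        avg_fail | thr_fail ~ "failure",
        ended_early ~ "excluded",
        TRUE ~ "success"
      ),
      failure_reason = dplyr::case_when(
        !is.na(ae_reason) ~ ae_reason,
        status != "failure" ~ NA_character_,
        thr_fail ~ "bp_threshold",
        TRUE ~ "bp_average"
      ),
      bp_window_used = dplyr::if_else(
        !is.na(.data$window), .data$window, NA_character_
      )
    ) |>
    dplyr::transmute(
      .data$patient_id, .data$status, .data$failure_reason,
      .data$bp_window_used, n_bp_readings = as.integer(.data$n)
    )
  out[match(episodes$patient_id, out$patient_id), ]
}
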