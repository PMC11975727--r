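# JNC 8 first-line recommendation engine and the agreement statistic.

#' JNC 8 first-line permitted classes for patients
#'
#' Chronic kidney disease (any race) permits ACE inhibitors or ARBs; Black
#' patients without CKD, thiazides or CCBs; everyone else ACEi, ARB, thiazide
#' or CCB. A combination is permitted when every component class is in the
#' permitted set, except under the CKD rule where it suffices that the
#' combination contains at least one of ACEi/ARB. CKD takes precedence over
#' the race rule.
#'
#' @param patients Tibble with `patient_id`, `race`, and logical `ckd`.
#' @return A tibble: `patient_id`, `rule_fired` (`ckd`/`black`/`general`),
#'   `permitted_classes` (list-column of single-agent class sets).
#' @export
jnc8_recommended_classes <- function(patients) {
  stopifnot(all(c("race", "ckd") %in% names(patients)))
  rule <- dplyr::case_when(
    patients$ckd ~ "ckd",
    patients$race == "Black" ~ "black",
    TRUE ~ "general"
  )
  sets <- list(
    ckd = c("ACEi", "ARB"),
    black = c("thiazide", "CCB"),
    general = c("ACEi", "ARB", "thiazide", "CCB")
  )
  tibble::tibble(
    patient_id = patients$patient_id,
    rule_fired = rule,
    permitted_classes = unname(sets[rule])
  )
}

#' Is a class label permitted under a fired JNC 8 rule?
#'
#' Vectorized over class labels (single classes or `-`-joined combinations).
#'
#' @param class_labels Character vector of class labels.
#' @param rule_fired `"ckd"`, `"black"` or `"general"` (recycled).
#' @return Logical vector.
#' @export
jnc8_permits <- function(class_labels, rule_fired) {
  rule_fired <- rep_len(rule_fired, length(class_labels))
  purrr::map2_lgl(class_labels, rule_fired, function(lbl, rule) {
    comps <- strsplit(lbl, "-", fixed = TRUE)[[1]]
    if (rule == "ckd") {
      return(any(comps %in% c("ACEi", "ARB")))
    }
    permitted <- if (rule == "black") c("thiazide", "CCB") else
      c("ACEi", "ARB", "thiazide", "CCB")
    all(comps %in% permitted)
  })
}

#' Guideline agreement rate
#'
#' Percentage of patients whose model-suggested top drug class lies in their
#' JNC 8-permitted set, reported to one decimal. Patients without a
#' prediction are dropped from the denominator with a warning.
#'
#' @param top_classes Tibble `patient_id`, `class_label` (the model's top
#'   suggestion per patient).
#' @param recommendations Output of [jnc8_recommended_classes()].
#' @return Percentage in `[0, 100]`.
#' @export
agreement_rate <- function(top_classes, recommendations) {
  joined <- dplyr::left_join(
    dplyr::select(recommendations, "patient_id", "rule_fired"),
    top_classes, by = "patient_id"
  )
  missing <- is.na(joined$class_label)
  if (any(missing)) {
    warn(sprintf("%d patient(s) without a top-class prediction dropped",
                 sum(missing)))
    joined <- joined[!missing, ]
  }
  agree <- jnc8_permits(joined$class_label, joined$rule_fired)
  as_pct(mean(agree))
}
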