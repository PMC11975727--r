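# Evaluation: precision/recall/F1, confidence-stratified metrics, class
# success tables, guideline agreement, and success-curve sweeps.

#' Precision, recall and F1 for success prediction
#'
#' Positive class is `success`; `excluded` labels are dropped from the
#' denominator. Zero-denominator metrics come back `NA` (an undefined-metric
#' signal, never 0).
#'
#' @param labels Tibble `patient_id`, `status`.
#' @param predictions Tibble `patient_id`, `median` (predicted success
#'   probability).
#' @param threshold Probability at or above which success is predicted.
#' @return One-row tibble: `n`, `tp`, `fp`, `fn`, `precision`, `recall`,
#'   `f1` (percent, one decimal).
#' @export
precision_recall_f1 <- function(labels, predictions, threshold = 0.5) {
  stopifnot(threshold > 0, threshold < 1)
  dat <- dplyr::inner_join(
    dplyr::filter(labels, .data$status != "excluded"),
    dplyr::select(predictions, "patient_id", "median"),
    by = "patient_id"
  )
  actual <- dat$status == "success"
  predicted <- dat$median >= threshold
  tp <- sum(actual & predicted)
  fp <- sum(!actual & predicted)
  fn <- sum(actual & !predicted)
  precision <- if (tp + fp == 0) NA_real_ else 100 * tp / (tp + fp)
  recall <- if (tp + fn == 0) NA_real_ else 100 * tp / (tp + fn)
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0) {
    NA_real_
  } else {
    2 * precision * recall / (precision + recall)
  }
  tibble::tibble(
    n = nrow(dat), tp = tp, fp = fp, fn = fn,
    precision = round(precision, 1), recall = round(recall, 1),
    f1 = round(f1, 1)
  )
}

#' F1 from precision and recall
#'
#' Harmonic mean, same scale as the inputs.
#'
#' @param precision,recall Percentages in `(0, 100]`.
#' @return F1 on the same scale.
#' @export
#' @examples
#' f1_from_pr(51.7, 44.4) # 47.8
f1_from_pr <- function(precision, recall) {
  stopifnot(all(precision > 0), all(precision <= 100),
            all(recall > 0), all(recall <= 100))
  2 * precision * recall / (precision + recall)
}

#' Metrics stratified by confidence tier
#'
#' Recomputes precision/recall/F1 on all cases, the medium-or-high subset,
#' and the high subset, with subset sizes.
#'
#' @param labels Tibble `patient_id`, `status`.
#' @param predictions [predict_success()] output (needs `median`,
#'   `confidence_tier`).
#' @param threshold Classification threshold.
#' @return A tibble with one row per stratum (`all`, `medium+high`, `high`).
#' @export
confidence_stratified_metrics <- function(labels, predictions,
                                          threshold = 0.5) {
  strata <- list(
    "all" = c("low", "medium", "high"),
    "medium+high" = c("medium", "high"),
    "high" = "high"
  )
  purrr::imap_dfr(strata, function(tiers, nm) {
    sub <- dplyr::filter(predictions, .data$confidence_tier %in% tiers)
    dplyr::bind_cols(
      tibble::tibble(stratum = nm),
      precision_recall_f1(labels, sub, threshold)
    )
  })
}

#' Treatment likelihood and success rate by drug class
#'
#' Per class: likelihood = share of episodes prescribed that class; success
#' rate = share of successes among the class's non-excluded episodes
#' (undefined when a class has only excluded episodes). Sorted by likelihood
#' descending; percentages to one decimal.
#'
#' @param episodes Episode table with `patient_id`, `class_label`.
#' @param labels Outcome labels (`patient_id`, `status`).
#' @return A tibble: `class_label`, `n`, `likelihood`, `success_rate`.
#' @export
class_success_table <- function(episodes, labels) {
  dat <- dplyr::inner_join(
    dplyr::select(episodes, "patient_id", "class_label"),
    dplyr::select(labels, "patient_id", "status"), by = "patient_id"
  )
  total <- nrow(dat)
  dat |>
    dplyr::group_by(.data$class_label) |>
    dplyr::summarise(
      n = dplyr::n(),
      likelihood = as_pct(dplyr::n() / total),
      success_rate = {
        lab <- .data$status[.data$status != "excluded"]
        if (length(lab) == 0) NA_real_ else as_pct(mean(lab == "success"))
      },
      .groups = "drop"
    ) |>
    dplyr::arrange(dplyr::desc(.data$likelihood))
}

#' Predicted success curves across age or pretreatment systolic pressure
#'
#' For a reference patient, sweeps one variable over a grid and reports the
#' class-aggregated ensemble bands (each member's scores are aggregated to
#' class level with the prescription weights, then the 10/25/50/75/90
#' percentiles are taken across members).
#'
#' @param ensemble A trained `htn_ensemble`.
#' @param reference One-row covariate table (the swept column is overwritten).
#' @param sweep `"age"` or `"sbp"`.
#' @param grid Numeric grid of sweep values.
#' @param classes Class labels to include (default: the three
#'   highest-scoring classes at the grid midpoint).
#' @return A tibble of class `htn_curves`: `sweep`, `value`, `class_label`,
#'   `median`, `p10`, `p25`, `p75`, `p90`.
#' @export
success_curves <- function(ensemble, reference, sweep = c("age", "sbp"),
                           grid = NULL, classes = NULL) {
  sweep <- match.arg(sweep)
  col <- if (sweep == "age") "age" else "pre_sbp"
  grid <- grid %||% (if (sweep == "age") seq(30, 85, by = 5) else
    seq(110, 180, by = 5))
  menu <- treatment_menu()
  weights <- dplyr::transmute(menu$menu, .data$treatment_id,
                              .data$class_label,
                              weight = .data$weight_within_class)

  member_class_scores <- function(value) {
    pt <- reference
    pt[[col]] <- value
    feats <- featurize(pt[rep(1L, nrow(menu$menu)), , drop = FALSE],
                       menu$menu$treatment_id)
    scores <- predict_members(ensemble, feats)  # n_treat x members
    agg <- rowsum(scores * weights$weight, weights$class_label)
    agg  # class x members
  }

  if (is.null(classes)) {
    mid <- member_class_scores(grid[ceiling(length(grid) / 2)])
    med <- apply(mid, 1, median)
    classes <- names(sort(med, decreasing = TRUE))[seq_len(min(3, length(med)))]
  }

  rows <- purrr::map_dfr(grid, function(v) {
    agg <- member_class_scores(v)
    qs <- t(apply(agg, 1, quantile, probs = c(0.1, 0.25, 0.5, 0.75, 0.9),
                  type = 7, names = FALSE))
    tibble::tibble(
      sweep = sweep, value = v, class_label = rownames(agg),
      median = qs[, 3], p10 = qs[, 1], p25 = qs[, 2], p75 = qs[, 4],
      p90 = qs[, 5]
    )
  })
  out <- dplyr::filter(rows, .data$class_label %in% classes)
  class(out) <- c("htn_curves", class(out))
  out
}

#' Full evaluation report
#'
#' Overall and confidence-stratified precision/recall/F1 on the validation
#' set, the class success table on the training set, and guideline agreement
#' of the model's top class suggestions.
#'
#' @param ensemble A trained `htn_ensemble`.
#' @param validation_features Feature table for validation episodes (with the
#'   actually prescribed `treatment_id`).
#' @param validation_labels Outcome labels for the validation episodes.
#' @param train_episodes,train_labels Episode and label tables for the class
#'   success table (optional).
#' @param patients Covariate table with `ckd` flags for the guideline
#'   comparison (defaults to the validation features).
#' @param threshold Classification threshold.
#' @return A list of class `htn_eval_report`.
#' @export
evaluate_model <- function(ensemble, validation_features, validation_labels,
                           train_episodes = NULL, train_labels = NULL,
                           patients = NULL, threshold = 0.5) {
  preds <- predict_success(ensemble, validation_features)
  overall <- precision_recall_f1(validation_labels, preds, threshold)
  stratified <- confidence_stratified_metrics(validation_labels, preds,
                                              threshold)
  class_table <- if (!is.null(train_episodes) && !is.null(train_labels)) {
    class_success_table(train_episodes, train_labels)
  }

  patients <- patients %||% validation_features
  top <- top_class_per_patient(ensemble, patients)
  recs <- jnc8_recommended_classes(patients)
  agreement <- agreement_rate(top, recs)

  # physician practice: agreement of the actually prescribed class
  menu <- treatment_menu()
  actual <- tibble::tibble(
    patient_id = validation_features$patient_id,
    class_label = menu$menu$class_label[
      match(validation_features$treatment_id, menu$menu$treatment_id)
    ]
  )
  physician_agreement <- agreement_rate(actual, recs)

  structure(
    list(
      n_cases = overall$n, overall = overall, stratified = stratified,
      class_table = class_table,
      agreement = c(model = agreement, physician = physician_agreement),
      threshold = threshold
    ),
    class = "htn_eval_report"
  )
}

# Model's top suggested class per patient (class-aggregated scores),
# batched: one prediction pass over the patients x menu cross product.
top_class_per_patient <- function(ensemble, patients) {
  menu <- treatment_menu()
  k <- nrow(menu$menu)
  n <- nrow(patients)
  feats <- featurize(
    patients[rep(seq_len(n), each = k), , drop = FALSE],
    rep(menu$menu$treatment_id, times = n)
  )
  pred <- predict_success(ensemble, feats)
  pred$class_label <- menu$menu$class_label[
    match(pred$treatment_id, menu$menu$treatment_id)
  ]
  pred$weight <- menu$menu$weight_within_class[
    match(pred$treatment_id, menu$menu$treatment_id)
  ]
  pred |>
    dplyr::group_by(.data$patient_id, .data$class_label) |>
    dplyr::summarise(score = sum(.data$weight * .data$median),
                     .groups = "drop_last") |>
    dplyr::slice_max(.data$score, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::select("patient_id", "class_label")
}

#' @export
print.htn_eval_report <- function(x, ...) {
  cat("Evaluation report (", x$n_cases, " validation cases)\n", sep = "")
  cat(sprintf("  precision %.1f%%  recall %.1f%%  F1 %.1f%%\n",
              x$overall$precision, x$overall$recall, x$overall$f1))
  for (i in seq_len(nrow(x$stratified))) {
    s <- x$stratified[i, ]
    cat(sprintf("  [%s] n=%d P=%.1f R=%.1f F1=%.1f\n", s$stratum, s$n,
                s$precision, s$recall, s$f1))
  }
  cat(sprintf("  guideline agreement: model %.1f%%, physician %.1f%%\n",
              x$agreement[["model"]], x$agreement[["physician"]]))
  invisible(x)
}
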