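# broom-style tidiers and plotting methods.

#' Tidy an ensemble: one row per member
#'
#' @param x An `htn_ensemble`.
#' @param ... Unused.
#' @return A tibble with member index, seed, subsample size, and converged
#'   training deviance.
#' @method tidy htn_ensemble
#' @export
tidy.htn_ensemble <- function(x, ...) {
  tibble::tibble(
    member = seq_along(x$members),
    seed = purrr::map_int(x$members, "seed"),
    n_subsample = purrr::map_int(x$members, ~ length(.x$idx)),
    deviance = purrr::map_dbl(x$members, ~ .x$fit$value)
  )
}

#' One-row ensemble summary
#'
#' @param x An `htn_ensemble`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @method glance htn_ensemble
#' @export
glance.htn_ensemble <- function(x, ...) {
  tibble::tibble(
    members = length(x$members),
    n_train = x$n_train,
    hidden = x$config$hidden,
    subsample = x$config$subsample,
    support_cut_medium = x$tier_cuts$s_medium,
    support_cut_high = x$tier_cuts$s_high,
    dispersion_cap = x$tier_cuts$d_cap
  )
}

#' Tidy an evaluation report: the stratified metric rows
#'
#' @param x An `htn_eval_report`.
#' @param ... Unused.
#' @return A tibble of per-stratum metrics.
#' @method tidy htn_eval_report
#' @export
tidy.htn_eval_report <- function(x, ...) {
  x$stratified
}

#' One-row evaluation summary
#'
#' @param x An `htn_eval_report`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @method glance htn_eval_report
#' @export
glance.htn_eval_report <- function(x, ...) {
  tibble::tibble(
    n_cases = x$n_cases,
    precision = x$overall$precision,
    recall = x$overall$recall,
    f1 = x$overall$f1,
    model_agreement = x$agreement[["model"]],
    physician_agreement = x$agreement[["physician"]]
  )
}

#' Plot success curves with percentile bands
#'
#' Median line per class with the 25-75 and 10-90 percentile ribbons.
#'
#' @param object An `htn_curves` tibble from [success_curves()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot htn_curves
#' @export
autoplot.htn_curves <- function(object, ...) {
  xlab <- if (object$sweep[1] == "age") "Age (years)" else
    "Pretreatment systolic blood pressure (mm Hg)"
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$value, y = .data$median, colour = .data$class_label,
    fill = .data$class_label
  )) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$p10, ymax = .data$p90),
                         alpha = 0.15, colour = NA) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$p25, ymax = .data$p75),
                         alpha = 0.3, colour = NA) +
    ggplot2::geom_line(linewidth = 0.9) +
    ggplot2::labs(x = xlab, y = "Predicted success probability",
                  colour = "Drug class", fill = "Drug class") +
    ggplot2::theme_minimal()
}
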