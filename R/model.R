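# Ensemble success model: 20 feed-forward members on 80% subsamples,
# percentile bands, and a positivity-aware confidence tier.

#' Ensemble model configuration
#'
#' @param members Number of ensemble members (default 20).
#' @param subsample Fraction of the training set each member sees (default
#'   0.8, drawn without replacement, independently per member).
#' @param hidden Hidden-layer width of each feed-forward member.
#' @param decay Weight decay (L2) for member training.
#' @param maxit Maximum optimizer iterations per member.
#' @param threshold Median probability at or above which an episode is
#'   predicted a success.
#' @param support_min_medium,support_min_high Hard floors on training support
#'   (episodes with the candidate regimen among feature-similar patients)
#'   for the medium and high confidence tiers; the calibrated support
#'   cutoffs never fall below these.
#' @param tier_targets Calibration targets: fractions of predictions that
#'   should fall in the medium-or-high and high tiers.
#' @param dispersion_veto_quantile Predictions whose normalized ensemble
#'   dispersion exceeds this training quantile are demoted to the low tier
#'   regardless of support.
#' @return An `htn_ensemble_config` list.
#' @export
ensemble_config <- function(members = 20, subsample = 0.8, hidden = 5,
                            decay = 0.02, maxit = 250, threshold = 0.5,
                            support_min_medium = 5, support_min_high = 20,
                            tier_targets = c(medium_high = 0.418,
                                             high = 0.173),
                            dispersion_veto_quantile = 0.9) {
  structure(
    list(members = members, subsample = subsample, hidden = hidden,
         decay = decay, maxit = maxit, threshold = threshold,
         support_min_medium = support_min_medium,
         support_min_high = support_min_high, tier_targets = tier_targets,
         dispersion_veto_quantile = dispersion_veto_quantile),
    class = "htn_ensemble_config"
  )
}

#' Extract model covariates for episodes
#'
#' Per episode: age at treatment start, sex, race, the seven comorbidity
#' flags (any diagnosis code on or before start), the latest valid
#' pre-treatment blood-pressure pair, and the latest pre-treatment
#' creatinine.
#'
#' @param bundle An `ehr_bundle`.
#' @param episodes Episode table with `patient_id`, `start`.
#' @return A tibble of covariates, one row per episode.
#' @export
extract_features <- function(bundle, episodes) {
  ep <- dplyr::select(episodes, "patient_id", "start")
  base <- dplyr::left_join(ep, bundle$patients, by = "patient_id") |>
    dplyr::mutate(age = as.numeric(.data$start - .data$birth_date) / 365.25)

  pre_bp <- bp_reading_pairs(filter_bp_measurements(bundle$vitals)) |>
    dplyr::inner_join(ep, by = "patient_id") |>
    dplyr::filter(.data$date < .data$start,
                  .data$date >= .data$start - DAYS_1_YEAR) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::slice_max(.data$date, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::select("patient_id", pre_sbp = "sbp", pre_dbp = "dbp")

  pre_cr <- bundle$labs |>
    dplyr::filter(.data$analyte == "creatinine") |>
    dplyr::inner_join(ep, by = "patient_id") |>
    dplyr::filter(.data$date < .data$start,
                  .data$date >= .data$start - DAYS_1_YEAR) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::slice_max(.data$date, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::select("patient_id", creatinine = "value")

  dx <- bundle$diagnoses |>
    dplyr::inner_join(ep, by = "patient_id") |>
    dplyr::filter(.data$date <= .data$start)
  code_lookup <- setNames(names(CONDITION_CODES), CONDITION_CODES)
  dx$condition <- code_lookup[dx$code]
  flags <- dx |>
    dplyr::filter(.data$condition %in% COMORBIDITIES) |>
    dplyr::distinct(.data$patient_id, .data$condition) |>
    dplyr::mutate(value = TRUE) |>
    tidyr::pivot_wider(names_from = "condition", values_from = "value",
                       values_fill = FALSE)
  for (m in COMORBIDITIES) if (!m %in% names(flags)) flags[[m]] <- logical(0)

  out <- base |>
    dplyr::left_join(pre_bp, by = "patient_id") |>
    dplyr::left_join(pre_cr, by = "patient_id") |>
    dplyr::left_join(flags, by = "patient_id") |>
    dplyr::mutate(dplyr::across(dplyr::all_of(COMORBIDITIES),
                                ~ dplyr::coalesce(.x, FALSE)))
  dplyr::select(out, "patient_id", "age", "sex", "race", "pre_sbp", "pre_dbp",
                "creatinine", dplyr::all_of(COMORBIDITIES))
}

FEATURE_COLUMNS <- c("age", "sex", "race", "pre_sbp", "pre_dbp", "creatinine",
                     COMORBIDITIES)

#' Build a complete feature vector for a patient-treatment pair
#'
#' Deterministic encoding with a fixed categorical dictionary; every required
#' field must be present and non-missing — the causal completeness
#' requirement. Missing values are a hard error, never imputed.
#'
#' @param patient A data frame of patient covariates (see
#'   [extract_features()]); one or more rows.
#' @param treatment A `treatment_id` from [treatment_menu()] (scalar or one
#'   per row).
#' @return The feature tibble with a `treatment_id` column appended.
#' @export
featurize <- function(patient, treatment) {
  missing_cols <- setdiff(FEATURE_COLUMNS, names(patient))
  if (length(missing_cols) > 0) {
    abort(sprintf("Missing required feature(s): %s",
                  paste(missing_cols, collapse = ", ")),
          class = "htnrec_feature_error")
  }
  out <- dplyr::select(patient, dplyr::any_of(c("patient_id", FEATURE_COLUMNS)))
  bad <- vapply(out[FEATURE_COLUMNS], function(x) any(is.na(x)), logical(1))
  if (any(bad)) {
    abort(sprintf("Feature(s) with missing values: %s",
                  paste(names(bad)[bad], collapse = ", ")),
          class = "htnrec_feature_error")
  }
  if (!all(out$race %in% RACE_LEVELS)) {
    abort("Unknown race level", class = "htnrec_feature_error")
  }
  if (!all(out$sex %in% SEX_LEVELS)) {
    abort("Unknown sex level", class = "htnrec_feature_error")
  }
  menu <- treatment_menu()
  treatment <- rep_len(treatment, nrow(out))
  if (!all(treatment %in% menu$menu$treatment_id)) {
    abort("Unknown treatment id", class = "htnrec_domain_error")
  }
  out$treatment_id <- treatment
  out
}

# Numeric design matrix with fixed dictionaries; continuous columns scaled by
# the stored training mean/sd.
encode_features <- function(features, scaling = NULL) {
  menu <- treatment_menu()
  cont <- as.matrix(features[, c("age", "pre_sbp", "pre_dbp", "creatinine")])
  if (is.null(scaling)) {
    scaling <- list(center = colMeans(cont), scale = pmax(apply(cont, 2, stats::sd),
                                                          1e-8))
  }
  cont <- sweep(sweep(cont, 2, scaling$center), 2, scaling$scale, "/")
  treat <- outer(features$treatment_id, menu$menu$treatment_id, "==") * 1
  colnames(treat) <- paste0("tx_", menu$menu$treatment_id)
  x <- cbind(
    cont,
    sex_m = as.numeric(features$sex == "M"),
    race_black = as.numeric(features$race == "Black"),
    race_other = as.numeric(features$race == "Other"),
    as.matrix(features[, COMORBIDITIES]) * 1,
    treat
  )
  list(x = x, scaling = scaling)
}

age_support_band <- function(age) {
  cut(age, breaks = c(0, 40, 60, 80, Inf),
      labels = c("18-39", "40-59", "60-79", "80+"), right = FALSE)
}

#' Train the ensemble success model
#'
#' Fits `members` feed-forward probability estimators, each on an independent
#' 80% subsample of the training episodes drawn with its own seed, and builds
#' the treatment-support index (training episodes per regimen within
#' race-by-age-band neighborhoods) used by the positivity filter. Confidence
#' dispersion thresholds are calibrated on the training predictions so the
#' medium-or-high and high tiers hit the configured target fractions.
#'
#' @param features Episode feature table ([featurize()] output, one row per
#'   training episode, including `treatment_id`).
#' @param labels Outcome labels (`patient_id`, `status`); `excluded` episodes
#'   are dropped.
#' @param config An [ensemble_config()].
#' @param seed Integer seed; fixed seed reproduces the ensemble exactly.
#' @return An `htn_ensemble` object.
#' @export
train_ensemble <- function(features, labels, config = ensemble_config(),
                           seed = 1) {
  dat <- dplyr::inner_join(features, dplyr::select(labels, "patient_id",
                                                   "status"),
                           by = "patient_id") |>
    dplyr::filter(.data$status != "excluded")
  if (length(unique(dat$status)) < 2) {
    abort("Training labels are degenerate (single class)",
          class = "htnrec_training_error")
  }
  y <- as.numeric(dat$status == "success")
  enc <- encode_features(dat)
  n <- nrow(enc$x)
  m_size <- floor(config$subsample * n)

  member_seeds <- (abs(seed) * 131 + seq_len(config$members) * 1000003) %%
    2147483647
  members <- purrr::map(seq_len(config$members), function(m) {
    withr::with_seed(as.integer(member_seeds[m]), {
      idx <- sample.int(n, m_size)
      fit <- nnet::nnet(
        x = enc$x[idx, , drop = FALSE], y = y[idx], size = config$hidden,
        decay = config$decay, maxit = config$maxit, entropy = TRUE,
        trace = FALSE, MaxNWts = 5000
      )
      list(fit = fit, idx = idx, seed = as.integer(member_seeds[m]))
    })
  })

  support <- dat |>
    dplyr::mutate(age_band = age_support_band(.data$age)) |>
    dplyr::count(.data$treatment_id, .data$race, .data$age_band,
                 name = "support_count")

  ens <- structure(
    list(members = members, scaling = enc$scaling, config = config,
         support = support, n_train = n, seed = seed, tier_cuts = NULL),
    class = "htn_ensemble"
  )
  ens$tier_cuts <- calibrate_confidence(ens, dat)
  ens
}

predict_members <- function(ensemble, features) {
  enc <- encode_features(features, ensemble$scaling)
  vapply(ensemble$members,
         function(m) as.numeric(predict(m$fit, enc$x)),
         numeric(nrow(enc$x)))
}

support_for <- function(ensemble, features) {
  q <- features |>
    dplyr::mutate(age_band = age_support_band(.data$age)) |>
    dplyr::left_join(ensemble$support,
                     by = c("treatment_id", "race", "age_band"))
  dplyr::coalesce(q$support_count, 0L)
}

# Dispersion on the scale of the prediction's own sampling variability:
# (p90 - p10) relative to the binomial standard deviation at the predicted
# probability. Raw probability-scale dispersion shrinks mechanically as the
# median approaches 0 or 1; the normalized form instead approximates the
# inverse effective support of the estimate, which is the overlap quantity
# the tier is meant to filter on.
normalized_dispersion <- function(dispersion, median) {
  dispersion / sqrt(pmax(median * (1 - median), 0.01))
}

# Tier thresholds calibrated on the training predictions: support cutoffs at
# the quantiles that hit the target medium-or-high and high fractions, plus
# a dispersion veto that demotes the most member-discordant predictions.
calibrate_confidence <- function(ensemble, features) {
  scores <- predict_members(ensemble, features)
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1)
  qs <- t(apply(scores, 1, quantile, probs = c(0.1, 0.5, 0.9), type = 7,
                names = FALSE))
  nd <- normalized_dispersion(qs[, 3] - qs[, 1], qs[, 2])
  supp <- support_for(ensemble, features)
  cfg <- ensemble$config
  list(
    s_medium = max(cfg$support_min_medium,
                   quantile(supp, 1 - cfg$tier_targets[["medium_high"]],
                            type = 1, names = FALSE)),
    s_high = max(cfg$support_min_high,
                 quantile(supp, 1 - cfg$tier_targets[["high"]],
                          type = 1, names = FALSE)),
    d_cap = quantile(nd, cfg$dispersion_veto_quantile, type = 7,
                     names = FALSE)
  )
}

assign_tier <- function(ensemble, median_p, dispersion, support_count) {
  cuts <- ensemble$tier_cuts
  nd <- normalized_dispersion(dispersion, median_p)
  ok <- support_count > 0 & nd <= cuts$d_cap
  high <- ok & support_count >= cuts$s_high
  medium <- ok & support_count >= cuts$s_medium
  dplyr::case_when(high ~ "high", medium ~ "medium", TRUE ~ "low")
}

#' Predict success with percentile uncertainty bands
#'
#' The median of the member scores is the success probability; the
#' 10/25/75/90 percentiles (linear interpolation between order statistics)
#' form the uncertainty bands; the confidence tier combines ensemble
#' dispersion (p90 - p10) with training support for the candidate regimen.
#' Zero support always yields the low tier (a hard positivity violation).
#'
#' @param ensemble A trained `htn_ensemble`.
#' @param features [featurize()] output.
#' @return A tibble: `patient_id` (if present), `treatment_id`, `median`,
#'   `p10`, `p25`, `p75`, `p90`, `dispersion`, `support_count`,
#'   `confidence_tier`.
#' @export
predict_success <- function(ensemble, features) {
  if (!inherits(ensemble, "htn_ensemble")) {
    abort("`ensemble` is not a trained htn_ensemble", class = "htnrec_state_error")
  }
  scores <- predict_members(ensemble, features)
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1)
  qs <- t(apply(scores, 1, quantile, probs = c(0.1, 0.25, 0.5, 0.75, 0.9),
                type = 7, names = FALSE))
  supp <- support_for(ensemble, features)
  out <- tibble::tibble(
    treatment_id = features$treatment_id,
    median = qs[, 3], p10 = qs[, 1], p25 = qs[, 2], p75 = qs[, 4],
    p90 = qs[, 5],
    dispersion = qs[, 5] - qs[, 1],
    support_count = supp
  )
  out$confidence_tier <- assign_tier(ensemble, out$median, out$dispersion,
                                     out$support_count)
  if ("patient_id" %in% names(features)) {
    out <- dplyr::bind_cols(
      tibble::tibble(patient_id = features$patient_id), out
    )
  }
  out
}

#' Confidence tier for patient-treatment pairs
#'
#' @inheritParams predict_success
#' @return A tibble with `confidence_tier` and `support_count`.
#' @export
confidence_tier <- function(ensemble, features) {
  dplyr::select(predict_success(ensemble, features),
                dplyr::any_of("patient_id"), "treatment_id",
                "confidence_tier", "support_count")
}

tier_rank <- c(low = 1L, medium = 2L, high = 3L)

#' Rank candidate treatments for a patient
#'
#' Scores every candidate regimen, removes candidates below `min_tier`, and
#' sorts by median success probability (ties: higher support, then
#' lexicographic treatment id, so rankings are deterministic).
#'
#' @param ensemble A trained `htn_ensemble`.
#' @param patient One-row covariate table (see [extract_features()]).
#' @param candidates Treatment ids to consider; defaults to the full menu.
#' @param min_tier Minimum confidence tier (`"low"`, `"medium"`, `"high"`).
#' @return Ranked predictions; zero rows (with attribute
#'   `no_confident_recommendation = TRUE`) when every candidate is filtered.
#' @export
recommend <- function(ensemble, patient, candidates = NULL,
                      min_tier = "low") {
  stopifnot(nrow(patient) == 1)
  candidates <- candidates %||% treatment_menu()$menu$treatment_id
  feats <- featurize(patient[rep(1L, length(candidates)), , drop = FALSE],
                     candidates)
  pred <- predict_success(ensemble, feats)
  pred <- dplyr::filter(pred, tier_rank[.data$confidence_tier] >=
                          tier_rank[[min_tier]])
  pred <- dplyr::arrange(pred, dplyr::desc(.data$median),
                         dplyr::desc(.data$support_count), .data$treatment_id)
  pred$rank <- seq_len(nrow(pred))
  if (nrow(pred) == 0) {
    attr(pred, "no_confident_recommendation") <- TRUE
    warn("No candidate treatment meets the requested confidence tier")
  }
  pred
}

#' Aggregate ingredient-dose predictions to drug-class scores
#'
#' Class score is the prescription-probability-weighted mean of the member
#' medians of its regimens; weights must sum to 1 within each class.
#'
#' @param predictions [predict_success()] output for one patient.
#' @param weights Tibble `treatment_id`, `class_label`, `weight`; defaults to
#'   the packaged menu's within-class prescription weights.
#' @return A tibble `class_label`, `score`, sorted by score descending.
#' @export
aggregate_to_class <- function(predictions, weights = NULL) {
  if (is.null(weights)) {
    weights <- dplyr::transmute(treatment_menu()$menu, .data$treatment_id,
                                .data$class_label,
                                weight = .data$weight_within_class)
  }
  w <- dplyr::semi_join(weights, predictions, by = "treatment_id")
  sums <- dplyr::summarise(dplyr::group_by(w, .data$class_label),
                           s = sum(.data$weight), .groups = "drop")
  if (any(abs(sums$s - 1) > 1e-6)) {
    abort(sprintf("Within-class weights do not sum to 1 for: %s",
                  paste(sums$class_label[abs(sums$s - 1) > 1e-6],
                        collapse = ", ")),
          class = "htnrec_validation_error")
  }
  dplyr::inner_join(predictions, w, by = "treatment_id") |>
    dplyr::group_by(.data$class_label) |>
    dplyr::summarise(score = sum(.data$weight * .data$median),
                     .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$score))
}
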