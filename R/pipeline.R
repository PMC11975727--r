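# End-to-end orchestration: simulate -> build cohort -> label -> train ->
# evaluate, each stage writing its outputs under the artifact directory.

#' Run the full pipeline
#'
#' Generates (or reads) a bundle, constructs the cohort, labels outcomes,
#' splits train/validation, trains the ensemble, and writes every stage
#' output plus a manifest (config hash, seed, row counts) under `out_dir`.
#'
#' @param config A [generator_config()]; its `seed` drives every stage.
#' @param out_dir Artifact directory.
#' @param n_validation Validation-set size.
#' @param model_config An [ensemble_config()].
#' @param bundle Optional pre-built bundle (skips simulation).
#' @return A list of class `htn_pipeline`: `cohort`, `split`, `ensemble`,
#'   `report`, `paths`.
#' @export
run_pipeline <- function(config = generator_config(), out_dir = tempfile("htnrec_"),
                         n_validation = 1000, model_config = ensemble_config(),
                         bundle = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_line <- function(...) message(sprintf(...))

  if (is.null(bundle)) {
    sim <- generate_cohort(config)
    bundle <- sim$bundle
    write_bundle(bundle, file.path(out_dir, "bundle"))
    log_line("simulate: %d patients, %d vitals rows",
             nrow(bundle$patients), nrow(bundle$vitals))
  } else {
    sim <- NULL
  }

  cohort <- build_cohort(bundle)
  elig <- cohort$eligibility
  readr::write_csv(
    dplyr::mutate(elig, failed_criteria = purrr::map_chr(
      .data$failed_criteria, paste, collapse = ";")),
    file.path(out_dir, "eligibility.csv"), progress = FALSE
  )
  log_line("build-cohort: %d of %d included", sum(elig$included), nrow(elig))

  labels <- cohort$labels
  readr::write_csv(labels, file.path(out_dir, "labels.csv"), progress = FALSE)
  log_line("label: %d success / %d failure / %d excluded",
           sum(labels$status == "success"), sum(labels$status == "failure"),
           sum(labels$status == "excluded"))

  included_ids <- elig$patient_id[elig$included]
  split <- split_train_validation(included_ids,
                                  min(n_validation, length(included_ids) - 1),
                                  seed = config$seed)

  features <- extract_features(bundle, cohort$included_episodes)
  features <- featurize(
    features,
    cohort$included_episodes$treatment_id[
      match(features$patient_id, cohort$included_episodes$patient_id)
    ]
  )
  train_feats <- dplyr::filter(features, .data$patient_id %in% split$train)
  val_feats <- dplyr::filter(features, .data$patient_id %in% split$validation)
  train_labels <- dplyr::filter(labels, .data$patient_id %in% split$train)
  val_labels <- dplyr::filter(labels, .data$patient_id %in% split$validation)

  ensemble <- train_ensemble(train_feats, train_labels, model_config,
                             seed = config$seed)
  log_line("train: %d members on %d episodes", model_config$members,
           ensemble$n_train)

  preds <- predict_success(ensemble, val_feats)
  readr::write_csv(preds, file.path(out_dir, "predictions.csv"),
                   progress = FALSE)

  train_ep <- dplyr::filter(cohort$included_episodes,
                            .data$patient_id %in% split$train)
  report <- evaluate_model(
    ensemble, val_feats, val_labels,
    train_episodes = train_ep, train_labels = train_labels
  )
  readr::write_csv(report$stratified, file.path(out_dir, "metrics.csv"),
                   progress = FALSE)
  if (!is.null(report$class_table)) {
    readr::write_csv(report$class_table,
                     file.path(out_dir, "class_table.csv"), progress = FALSE)
  }

  manifest <- list(
    seed = config$seed, n_patients = config$n_patients,
    n_included = length(included_ids), n_train = length(split$train),
    n_validation = length(split$validation),
    config_hash = rlang::hash(config)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  structure(
    list(sim = sim, cohort = cohort, split = split, ensemble = ensemble,
         report = report, paths = list(out_dir = out_dir)),
    class = "htn_pipeline"
  )
}
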