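# The six-table EHR bundle shared by every stage.

BUNDLE_TABLES <- c(
  "patients", "diagnoses", "vitals", "labs", "medications", "allergies"
)

bundle_columns <- list(
  patients = c(patient_id = "integer", birth_date = "Date", sex = "character",
               race = "character"),
  diagnoses = c(patient_id = "integer", code = "character", date = "Date",
                setting = "character"),
  vitals = c(patient_id = "integer", kind = "character", value = "double",
             date = "Date", position = "character", body_site = "character",
             invasive_flag = "logical", context = "character"),
  labs = c(patient_id = "integer", analyte = "character", value = "double",
           units = "character", date = "Date"),
  medications = c(patient_id = "integer", code = "character",
                  name = "character", per_unit_dose_mg = "double",
                  sig_text = "character", start_date = "Date",
                  end_date = "Date"),
  allergies = c(patient_id = "integer", medication_code = "character",
                severity = "character", date = "Date")
)

col_spec_for <- function(table) {
  spec <- purrr::map(bundle_columns[[table]], function(type) {
    switch(type,
      integer = readr::col_integer(),
      double = readr::col_double(),
      character = readr::col_character(),
      logical = readr::col_logical(),
      Date = readr::col_date(format = "%Y-%m-%d")
    )
  })
  do.call(readr::cols, spec)
}

#' Construct and validate an EHR bundle
#'
#' Bundles the six linked tables (patients, diagnoses, vitals, labs,
#' medications, allergies) and checks the structural invariants: all declared
#' columns present, every non-patient row's `patient_id` known, end dates not
#' before start dates, positive vital values, and SBP above DBP on
#' same-timestamp pairs.
#'
#' @param patients,diagnoses,vitals,labs,medications,allergies Data frames
#'   with the columns documented in [read_bundle()].
#' @return A validated `ehr_bundle` object (a named list of tibbles).
#' @export
ehr_bundle <- function(patients, diagnoses = NULL, vitals = NULL, labs = NULL,
                       medications = NULL, allergies = NULL) {
  empty_tbl <- function(table) {
    cols <- bundle_columns[[table]]
    tibble::as_tibble(purrr::map(cols, function(type) {
      switch(type,
        integer = integer(), double = double(), character = character(),
        logical = logical(), Date = as.Date(character())
      )
    }))
  }
  tables <- list(
    patients = patients, diagnoses = diagnoses, vitals = vitals, labs = labs,
    medications = medications, allergies = allergies
  )
  tables <- purrr::imap(tables, function(tbl, nm) {
    if (is.null(tbl)) empty_tbl(nm) else tibble::as_tibble(tbl)
  })
  bundle <- structure(tables, class = "ehr_bundle")
  validate_bundle(bundle)
  bundle
}

validation_error <- function(table, rows, msg) {
  abort(
    sprintf("Bundle validation failed in `%s` (row %s): %s", table,
            paste(head(rows, 5), collapse = ", "), msg),
    class = "htnrec_validation_error"
  )
}

#' Validate an EHR bundle's invariants
#'
#' @param bundle An `ehr_bundle`.
#' @return The bundle, invisibly; errors of class `htnrec_validation_error`
#'   otherwise, naming the offending table and row.
#' @export
validate_bundle <- function(bundle) {
  for (nm in BUNDLE_TABLES) {
    tbl <- bundle[[nm]]
    missing_cols <- setdiff(names(bundle_columns[[nm]]), names(tbl))
    if (length(missing_cols) > 0) {
      abort(sprintf("Table `%s` is missing column(s): %s", nm,
                    paste(missing_cols, collapse = ", ")),
            class = "htnrec_validation_error")
    }
  }
  ids <- bundle$patients$patient_id
  if (anyDuplicated(ids)) {
    validation_error("patients", which(duplicated(ids)), "duplicate patient_id")
  }
  for (nm in setdiff(BUNDLE_TABLES, "patients")) {
    bad <- which(!(bundle[[nm]]$patient_id %in% ids))
    if (length(bad) > 0) {
      validation_error(nm, bad, "patient_id not present in patients table")
    }
  }

  v <- bundle$vitals
  bad <- which(!(v$kind %in% VITAL_KINDS))
  if (length(bad) > 0) validation_error("vitals", bad, "unknown vital kind")
  bad <- which(!(v$context %in% VITAL_CONTEXTS))
  if (length(bad) > 0) validation_error("vitals", bad, "unknown vital context")
  bad <- which(!is.finite(v$value) | v$value <= 0)
  if (length(bad) > 0) validation_error("vitals", bad, "non-positive vital value")

  bad <- which(!(bundle$labs$analyte %in% LAB_ANALYTES))
  if (length(bad) > 0) validation_error("labs", bad, "unknown lab analyte")
  bad <- which(!(bundle$allergies$severity %in% AE_SEVERITIES))
  if (length(bad) > 0) validation_error("allergies", bad, "unknown severity")

  m <- bundle$medications
  bad <- which(!is.na(m$end_date) & m$end_date < m$start_date)
  if (length(bad) > 0) {
    validation_error("medications", bad, "end_date before start_date")
  }

  # SBP must exceed DBP when both were recorded at the same timestamp under
  # the same measurement conditions.
  if (nrow(v) > 0) {
    pairs <- tidyr::pivot_wider(
      dplyr::filter(v, .data$kind %in% c("SBP", "DBP")),
      id_cols = c("patient_id", "date", "position", "body_site",
                  "invasive_flag", "context"),
      names_from = "kind", values_from = "value", values_fn = mean
    )
    if (all(c("SBP", "DBP") %in% names(pairs))) {
      bad <- which(!is.na(pairs$SBP) & !is.na(pairs$DBP) &
                     pairs$SBP <= pairs$DBP)
      if (length(bad) > 0) {
        validation_error("vitals", bad, "SBP not greater than paired DBP")
      }
    }
  }
  invisible(bundle)
}

#' Read an EHR bundle from a directory of CSV files
#'
#' Expects `patients.csv`, `diagnoses.csv`, `vitals.csv`, `labs.csv`,
#' `medications.csv`, `allergies.csv` with the declared headers (ISO-8601
#' dates, UTF-8). The bundle is validated on read.
#'
#' @param directory Path containing the six CSV files.
#' @return A validated `ehr_bundle`.
#' @export
read_bundle <- function(directory) {
  paths <- file.path(directory, paste0(BUNDLE_TABLES, ".csv"))
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0) {
    abort(sprintf("Missing bundle file(s): %s", paste(missing, collapse = ", ")),
          class = "htnrec_io_error")
  }
  tables <- purrr::map2(BUNDLE_TABLES, paths, function(nm, path) {
    readr::read_csv(path, col_types = col_spec_for(nm), progress = FALSE)
  })
  names(tables) <- BUNDLE_TABLES
  do.call(ehr_bundle, tables)
}

#' Write an EHR bundle to a directory of CSV files
#'
#' Output is deterministic: fixed column order, rows sorted by
#' (`patient_id`, date), so identical bundles produce byte-identical files.
#'
#' @param bundle A validated `ehr_bundle`.
#' @param directory Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_bundle <- function(bundle, directory) {
  validate_bundle(bundle)
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  sort_cols <- list(
    patients = "patient_id",
    diagnoses = c("patient_id", "date", "code"),
    vitals = c("patient_id", "date", "kind", "context", "value"),
    labs = c("patient_id", "date", "analyte", "value"),
    medications = c("patient_id", "start_date", "code"),
    allergies = c("patient_id", "date", "medication_code")
  )
  for (nm in BUNDLE_TABLES) {
    tbl <- dplyr::select(bundle[[nm]], dplyr::all_of(names(bundle_columns[[nm]])))
    tbl <- dplyr::arrange(tbl, dplyr::across(dplyr::all_of(sort_cols[[nm]])))
    readr::write_csv(tbl, file.path(directory, paste0(nm, ".csv")), progress = FALSE)
  }
  invisible(directory)
}
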