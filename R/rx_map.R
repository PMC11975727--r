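# Packaged RxNorm-style vocabulary: product code -> ingredient(s), class,
# per-unit strength. Combination products carry one row per ingredient.

the <- new.env(parent = emptyenv())

#' Packaged medication code table
#'
#' A small RxNorm-style mapping of product codes to ingredients, drug classes,
#' and per-unit strengths (mg). Combination products have one row per
#' ingredient. This is the vocabulary the rest of the package (and the
#' synthetic generator) operates over; it is not a full RxNorm extract.
#'
#' @return A tibble with columns `code`, `product_name`, `ingredient`,
#'   `drug_class`, `unit_mg`.
#' @export
rx_class_map <- function() {
  if (is.null(the$rx_map)) {
    path <- system.file("extdata", "rx_class_map.csv", package = "htnrec")
    the$rx_map <- readr::read_csv(
      path,
      col_types = readr::cols(
        code = readr::col_character(),
        product_name = readr::col_character(),
        ingredient = readr::col_character(),
        drug_class = readr::col_character(),
        unit_mg = readr::col_double()
      ),
      progress = FALSE
    )
  }
  the$rx_map
}

#' Map a medication code to ingredient(s) and drug class(es)
#'
#' Combination products return one row per ingredient. Unknown codes are never
#' silently dropped: they come back flagged `unmapped` (mirroring a manual
#' mapping queue), with `NA` ingredient and class.
#'
#' @param codes Character vector of medication product codes.
#' @return A tibble with one row per (code, ingredient): `code`, `ingredient`,
#'   `drug_class`, `unit_mg`, `unmapped`.
#' @export
#' @examples
#' map_to_class("104375") # lisinopril, ACEi
#' map_to_class("705120") # combination: lisinopril + hydrochlorothiazide
map_to_class <- function(codes) {
  codes <- as.character(codes)
  map <- rx_class_map()
  out <- dplyr::left_join(
    tibble::tibble(code = codes),
    dplyr::select(map, "code", "ingredient", "drug_class", "unit_mg"),
    by = "code", relationship = "many-to-many"
  )
  out$unmapped <- is.na(out$ingredient)
  if (any(out$unmapped)) {
    warn(sprintf(
      "%d medication code(s) not in the packaged mapping table: %s",
      sum(out$unmapped), paste(unique(out$code[out$unmapped]), collapse = ", ")
    ))
  }
  out
}

#' Parse prescription sig text into administrations per day
#'
#' Supports the closed grammar used throughout the package:
#' `"[take] <n> <unit>s daily"`, `"[take] <n> <unit>s once/twice a day"`,
#' `"take <n> <unit>s <m> times a day"`, and `"<n> <unit>s every <h> hours"`.
#' Unit words are pill/tablet/capsule. Anything else is a parse error; doses
#' are never guessed.
#'
#' @param sig_text Character vector of prescription instructions.
#' @param per_unit_dose_mg Per-dispense-unit strength in mg (recycled).
#' @return A tibble with `sig_text`, `units_per_day`, `daily_dose_mg`.
#' @export
#' @examples
#' parse_sig("take 2 pills 3 times a day", 10) # 60 mg/day
parse_sig <- function(sig_text, per_unit_dose_mg) {
  n <- length(sig_text)
  per_unit_dose_mg <- rep_len(per_unit_dose_mg, n)
  txt <- stringr::str_squish(tolower(sig_text))
  unit_re <- "(?:pills?|tablets?|capsules?)"
  num_re <- "([0-9]+(?:\\.[0-9]+)?)"

  units_per_day <- rep(NA_real_, n)

  m <- stringr::str_match(
    txt, paste0("^(?:take )?", num_re, " ", unit_re, " (?:daily|once a day)$")
  )
  hit <- !is.na(m[, 1])
  units_per_day[hit] <- as.numeric(m[hit, 2])

  m <- stringr::str_match(
    txt, paste0("^(?:take )?", num_re, " ", unit_re, " twice a day$")
  )
  hit <- !is.na(m[, 1])
  units_per_day[hit] <- as.numeric(m[hit, 2]) * 2

  m <- stringr::str_match(
    txt, paste0("^(?:take )?", num_re, " ", unit_re, " ", num_re, " times a day$")
  )
  hit <- !is.na(m[, 1])
  units_per_day[hit] <- as.numeric(m[hit, 2]) * as.numeric(m[hit, 3])

  m <- stringr::str_match(
    txt, paste0("^(?:take )?", num_re, " ", unit_re, " every ", num_re, " hours$")
  )
  hit <- !is.na(m[, 1])
  units_per_day[hit] <- as.numeric(m[hit, 2]) * 24 / as.numeric(m[hit, 3])

  if (anyNA(units_per_day)) {
    bad <- sig_text[is.na(units_per_day)]
    abort(
      sprintf("Unparseable sig text: %s",
              paste(sprintf('"%s"', unique(bad)), collapse = ", ")),
      class = "htnrec_sig_error"
    )
  }
  tibble::tibble(
    sig_text = sig_text,
    units_per_day = units_per_day,
    daily_dose_mg = units_per_day * per_unit_dose_mg
  )
}

#' Treatment menu: candidate ingredient-dose regimens
#'
#' Every candidate initial regimen the package models: 24 single-agent
#' ingredient-dose pairs plus 10 two-agent regimens, each with a canonical
#' `treatment_id`, a derived class label, and a within-class prescription
#' weight (the probability of that regimen given its class; weights sum to 1
#' within each class label).
#'
#' @return A list with `menu` (one row per regimen: `treatment_id`,
#'   `class_label`, `weight_within_class`, `n_components`) and `components`
#'   (one row per regimen component: `treatment_id`, `ingredient`,
#'   `drug_class`, `dose_mg`, `high_dose`).
#' @export
treatment_menu <- function() {
  if (!is.null(the$menu)) return(the$menu)

  single <- list(
    ACEi = list(
      c("lisinopril", 10, .40), c("lisinopril", 20, .25),
      c("enalapril", 5, .20), c("enalapril", 10, .15)
    ),
    ARB = list(
      c("losartan", 50, .40), c("losartan", 100, .25),
      c("valsartan", 80, .20), c("valsartan", 160, .15)
    ),
    thiazide = list(
      c("hydrochlorothiazide", 12.5, .40), c("hydrochlorothiazide", 25, .30),
      c("chlorthalidone", 25, .20), c("chlorthalidone", 50, .10)
    ),
    CCB = list(
      c("amlodipine", 5, .40), c("amlodipine", 10, .25),
      c("diltiazem", 120, .20), c("diltiazem", 240, .15)
    ),
    beta_blocker = list(
      c("metoprolol", 50, .40), c("metoprolol", 100, .25),
      c("atenolol", 25, .20), c("atenolol", 50, .15)
    ),
    other = list(
      c("clonidine", 0.1, .35), c("clonidine", 0.2, .15),
      c("hydralazine", 50, .30), c("hydralazine", 100, .20)
    )
  )
  combos <- list(
    list(c("lisinopril", 10), c("hydrochlorothiazide", 12.5), .6),
    list(c("lisinopril", 20), c("hydrochlorothiazide", 25), .4),
    list(c("lisinopril", 10), c("amlodipine", 5), .6),
    list(c("lisinopril", 20), c("amlodipine", 10), .4),
    list(c("losartan", 50), c("hydrochlorothiazide", 12.5), .6),
    list(c("losartan", 100), c("hydrochlorothiazide", 25), .4),
    list(c("metoprolol", 50), c("hydrochlorothiazide", 12.5), .6),
    list(c("metoprolol", 100), c("hydrochlorothiazide", 25), .4),
    list(c("amlodipine", 5), c("hydrochlorothiazide", 12.5), .6),
    list(c("amlodipine", 10), c("hydrochlorothiazide", 25), .4)
  )

  map <- rx_class_map()
  ing_class <- dplyr::distinct(map, .data$ingredient, .data$drug_class)
  ing_max <- dplyr::summarise(
    dplyr::group_by(map, .data$ingredient),
    max_mg = max(.data$unit_mg), .groups = "drop"
  )

  rows <- list()
  for (cls in names(single)) {
    for (it in single[[cls]]) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        ingredient = it[[1]], dose_mg = as.numeric(it[[2]]),
        weight = as.numeric(it[[3]])
      )
    }
  }
  single_tbl <- dplyr::bind_rows(rows)
  single_tbl <- dplyr::left_join(single_tbl, ing_class, by = "ingredient")
  single_tbl$treatment_id <- mapply(
    make_treatment_id, single_tbl$ingredient, single_tbl$dose_mg,
    USE.NAMES = FALSE
  )
  single_tbl$class_label <- single_tbl$drug_class

  combo_rows <- purrr::map(combos, function(cb) {
    comp <- tibble::tibble(
      ingredient = c(cb[[1]][1], cb[[2]][1]),
      dose_mg = as.numeric(c(cb[[1]][2], cb[[2]][2]))
    )
    comp <- dplyr::left_join(comp, ing_class, by = "ingredient")
    tibble::tibble(
      treatment_id = make_treatment_id(comp$ingredient, comp$dose_mg),
      class_label = class_label(comp$drug_class),
      weight = as.numeric(cb[[3]]),
      components = list(comp)
    )
  })
  combo_tbl <- dplyr::bind_rows(combo_rows)

  components <- dplyr::bind_rows(
    dplyr::transmute(
      single_tbl, .data$treatment_id, .data$ingredient, .data$drug_class,
      .data$dose_mg
    ),
    dplyr::bind_rows(purrr::map2(
      combo_tbl$treatment_id, combo_tbl$components,
      ~ dplyr::mutate(.y, treatment_id = .x)
    ))
  )
  components <- dplyr::left_join(components, ing_max, by = "ingredient")
  components$high_dose <- components$dose_mg >= components$max_mg
  components$max_mg <- NULL
  components <- dplyr::arrange(components, .data$treatment_id, .data$ingredient)

  menu <- dplyr::bind_rows(
    dplyr::transmute(
      single_tbl, .data$treatment_id, .data$class_label,
      weight_within_class = .data$weight
    ),
    dplyr::transmute(
      combo_tbl, .data$treatment_id, .data$class_label,
      weight_within_class = .data$weight
    )
  )
  menu <- dplyr::left_join(
    menu,
    dplyr::count(components, .data$treatment_id, name = "n_components"),
    by = "treatment_id"
  )
  menu <- dplyr::arrange(menu, .data$class_label, .data$treatment_id)

  the$menu <- list(menu = menu, components = components)
  the$menu
}
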