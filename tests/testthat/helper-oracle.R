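# Independent brute-force outcome labeler: a literal, loop-based walk of the
# blood-pressure-control and adverse-effect rules, kept deliberately free of
# the package's vectorized implementation so the two can disagree.

oracle_label <- function(pid, episode, bundle) {
  start <- episode$start
  end <- episode$end
  end_day <- if (is.na(end)) Inf else as.numeric(end - start)

  v <- bundle$vitals[bundle$vitals$patient_id == pid, , drop = FALSE]
  keep <- !v$invasive_flag & v$position == "sitting" &
    v$body_site == "arm" & v$context == "ambulatory"
  v <- v[keep, , drop = FALSE]
  v$day <- as.numeric(v$date - start)

  l <- bundle$labs[bundle$labs$patient_id == pid, , drop = FALSE]
  l$day <- as.numeric(l$date - start)
  base_cr <- NA_real_
  pre <- l[l$analyte == "creatinine" & l$day < 0, , drop = FALSE]
  if (nrow(pre) > 0) base_cr <- pre$value[which.max(pre$day)]

  a <- bundle$allergies[bundle$allergies$patient_id == pid, , drop = FALSE]
  a$day <- if (nrow(a) > 0) as.numeric(a$date - start) else numeric(0)

  # --- adverse events, literal sentence-by-sentence ---------------------
  events <- data.frame(day = numeric(0), reason = character(0), prio = numeric(0))
  add <- function(day, reason, prio) {
    events <<- rbind(events, data.frame(day = day, reason = reason, prio = prio))
  }
  for (i in seq_len(nrow(v))) {
    if (v$day[i] >= 1 && v$day[i] <= end_day) {
      if (v$kind[i] == "SBP" && v$value[i] < 90) add(v$day[i], "hypotension", 1)
      if (v$kind[i] == "DBP" && v$value[i] < 60) add(v$day[i], "hypotension", 1)
      if (v$kind[i] == "HR" && v$value[i] < 50) add(v$day[i], "bradycardia", 2)
    }
  }
  for (i in seq_len(nrow(l))) {
    if (l$day[i] >= 1 && l$day[i] <= end_day) {
      an <- l$analyte[i]; val <- l$value[i]
      if (an == "creatinine" && !is.na(base_cr) && val > 1.3 * base_cr) {
        add(l$day[i], "creatinine_rise", 3)
      }
      if (an == "sodium" && (val < 130 || val > 150)) add(l$day[i], "natremia", 4)
      if (an == "potassium" && (val < 3.6 || val > 5.1)) add(l$day[i], "kalemia", 5)
      if (an == "glucose_fasting" && val > 120) add(l$day[i], "glucose", 6)
    }
  }
  for (i in seq_len(nrow(a))) {
    if (a$day[i] >= 0 && a$day[i] <= end_day &&
          a$severity[i] %in% c("moderate", "severe")) {
      add(a$day[i], "documented_ae", 7)
    }
  }
  ae_reason <- NA_character_
  if (nrow(events) > 0) {
    events <- events[order(events$day, events$prio), , drop = FALSE]
    ae_reason <- events$reason[1]
  }

  # --- pair readings by date -------------------------------------------
  bp <- v[v$kind %in% c("SBP", "DBP") & v$day >= 1, , drop = FALSE]
  dates <- sort(unique(bp$date))
  sbp <- dbp <- day <- numeric(0)
  for (d in as.list(dates)) {
    rows <- bp[bp$date == d, , drop = FALSE]
    s <- rows$value[rows$kind == "SBP"]; di <- rows$value[rows$kind == "DBP"]
    sbp <- c(sbp, if (length(s) > 0) mean(s) else NA_real_)
    dbp <- c(dbp, if (length(di) > 0) mean(di) else NA_real_)
    day <- c(day, as.numeric(d - start))
  }

  # --- window selection -------------------------------------------------
  ended_early <- is.finite(end_day) && end_day < 365
  if (ended_early) {
    use <- day >= 14 & day <= end_day - 183
    win <- if (any(use)) "discontinuation" else NA_character_
  } else {
    windows <- list(`6-12m` = c(183, 365), `12-14m` = c(366, 426),
                    `14-18m` = c(427, 547), `18-24m` = c(548, 730))
    use <- rep(FALSE, length(day)); win <- NA_character_
    for (w in names(windows)) {
      cand <- day >= windows[[w]][1] & day <= windows[[w]][2] & day <= end_day
      if (any(cand)) { use <- cand; win <- w; break }
    }
  }

  mk <- function(status, reason = NA_character_) {
    tibble::tibble(patient_id = pid, status = status, failure_reason = reason,
                   bp_window_used = win, n_bp_readings = sum(use))
  }

  if (!is.na(ae_reason)) return(mk("failure", ae_reason))
  if (sum(use) == 0) return(mk("excluded"))

  age <- as.numeric(start - bundle$patients$birth_date[
    bundle$patients$patient_id == pid]) / 365.25
  if (age >= 60) {
    avg_s <- 150; max_s <- 170
  } else {
    avg_s <- 140; max_s <- 160
  }
  ws <- sbp[use]; wd <- dbp[use]
  mean_s <- mean(ws, na.rm = TRUE); mean_d <- mean(wd, na.rm = TRUE)
  avg_bad <- (!is.nan(mean_s) && mean_s >= avg_s) ||
    (!is.nan(mean_d) && mean_d >= 90)
  thr_bad <- any(ws > max_s, na.rm = TRUE) || any(wd > 90, na.rm = TRUE)

  if (thr_bad) return(mk("failure", "bp_threshold"))
  if (avg_bad) return(mk("failure", "bp_average"))
  if (ended_early) return(mk("excluded"))
  mk("success")
}
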