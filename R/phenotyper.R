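#' Bleeding phenotyping algorithm
#'
#' The phenotyper turns a linked EHR into classified bleeding events:
#'
#' 1. Coded bleeding diagnoses are assembled from primary care, hospital
#'    admissions (with diagnosis position and length of stay) and the death
#'    registry (underlying or contributory causes, dated at death).
#' 2. Records of one patient are grouped into events by single-linkage
#'    within a configurable window (default 30 days).
#' 3. An event is *fatal* if it contains a bleeding cause of death, or if
#'    all-cause death occurs within 7 days of a primary-care or hospital
#'    bleeding record.
#' 4. Four markers of severity are evaluated: bleeding as the primary
#'    reason for hospitalisation with at least 14 days of hospitalisation;
#'    a critical bleeding site (intracranial, ruptured aortic aneurysm or
#'    haemopericardium); bleeding from more than one site on the same day;
#'    and a hospital transfusion record within 30 days of a bleeding
#'    record.
#' 5. Non-fatal events are categorised as `hospitalised_ms`,
#'    `primary_care_ms`, `hospitalised` or `primary_care`; for patients
#'    without any coded bleeding diagnosis, *inferred* bleeds are detected
#'    from indirect evidence through four routes.
#'
#' Categories map to prognostic classes: `hospitalised_ms` = I;
#' `hospitalised`, `primary_care_ms` and `inferred` = II; `primary_care` =
#' III; fatal events form their own class.
#'
#' @name phenotyper
NULL

.bleed_categories <- c("fatal", "hospitalised_ms", "primary_care_ms",
                       "hospitalised", "primary_care", "inferred")

#' Map severity categories to prognostic classes
#'
#' @param category character vector of bleeding event categories.
#' @return Character vector: `fatal`, `I`, `II`, `III` (or `NA`).
#' @export
prognostic_class <- function(category) {
  data.table::fcase(
    category == "fatal", "fatal",
    category == "hospitalised_ms", "I",
    category %in% c("hospitalised", "primary_care_ms", "inferred"), "II",
    category == "primary_care", "III",
    default = NA_character_
  )
}

#' Assemble coded bleeding records from all sources
#'
#' @param ehr a `linked_ehr` object (see [simulate_ehr()] / [read_ehr()]).
#' @param codelist a `codelist`.
#' @return `data.table` with one row per coded bleeding diagnosis:
#'   `record_id`, `patient_id`, `date`, `source` (`primary_care`,
#'   `hospital`, `death_registry`), `site`, `diagnosis_position` and
#'   `episode_length_days` (hospital only), `episode_id`. Hospital records
#'   are dated at admission; death-registry records at death.
#' @export
assemble_bleeding_records <- function(ehr, codelist) {
  stopifnot(inherits(ehr, "linked_ehr"))
  ids <- ehr$patients$patient_id
  check_ref <- function(tbl, what) {
    if (nrow(tbl) && !all(tbl$patient_id %in% ids)) {
      stop("linkage error: ", what, " references unknown patient id(s)")
    }
  }
  check_ref(ehr$primary_care, "primary care table")
  check_ref(ehr$hospital_diagnoses, "hospital diagnoses")
  check_ref(ehr$deaths, "death registry")

  recs <- list()
  pc <- ehr$primary_care
  if (nrow(pc)) {
    cls <- classify_code(codelist, pc$code, "readlike")
    keep <- which(cls$category == "bleeding")
    recs$pc <- data.table(
      patient_id = pc$patient_id[keep], date = as.Date(pc$date[keep]),
      source = "primary_care", site = cls$site[keep],
      diagnosis_position = NA_integer_, episode_length_days = NA_integer_,
      episode_id = NA_integer_)
  }
  hd <- ehr$hospital_diagnoses
  if (nrow(hd)) {
    cls <- classify_code(codelist, hd$code, "icd10")
    keep <- which(cls$category == "bleeding")
    if (length(keep)) {
      h <- hd[keep]
      h[, c("site") := cls$site[keep]]
      ep <- ehr$hospital_episodes[, .(episode_id,
                                      admission_date = as.Date(admission_date),
                                      discharge_date = as.Date(discharge_date))]
      h <- ep[h, on = "episode_id"]
      if (any(h$discharge_date < h$admission_date, na.rm = TRUE)) {
        stop("linkage error: hospital episode with discharge before admission")
      }
      recs$hosp <- h[, .(
        patient_id, date = admission_date, source = "hospital", site,
        diagnosis_position = as.integer(position),
        episode_length_days = as.integer(discharge_date - admission_date),
        episode_id)]
    }
  }
  dc <- ehr$death_causes
  if (nrow(dc)) {
    cls <- classify_code(codelist, dc$code, "icd10")
    keep <- which(cls$category == "bleeding")
    if (length(keep)) {
      d <- dc[keep]
      d[, c("site") := cls$site[keep]]
      d <- ehr$deaths[, .(patient_id, date = as.Date(date))][d, on = "patient_id"]
      recs$death <- unique(d[, .(
        patient_id, date, source = "death_registry", site,
        diagnosis_position = NA_integer_, episode_length_days = NA_integer_,
        episode_id = NA_integer_)])
    }
  }
  out <- data.table::rbindlist(recs, use.names = TRUE)
  if (!nrow(out)) {
    out <- data.table(patient_id = integer(), date = as.Date(character()),
                      source = character(), site = character(),
                      diagnosis_position = integer(),
                      episode_length_days = integer(), episode_id = integer())
  }
  data.table::setorder(out, patient_id, date, source)
  out[, record_id := sprintf("r%06d", .I)]
  data.table::setcolorder(out, "record_id")
  out[]
}

#' Group bleeding records of a patient into events
#'
#' Single-linkage chaining: consecutive records of one patient at most
#' `window_days` apart belong to the same event. The grouping is a
#' partition of the records and does not depend on input order.
#'
#' @param records output of [assemble_bleeding_records()].
#' @param window_days linkage window in days.
#' @return The records with an added integer `event_id` column (unique
#'   across patients).
#' @export
group_records <- function(records, window_days = 30) {
  recs <- data.table::as.data.table(records)
  if (!nrow(recs)) {
    recs[, event_id := integer()]
    return(recs[])
  }
  data.table::setorder(recs, patient_id, date, source, record_id)
  recs[, grp := cumsum(c(1L, as.integer(diff(as.integer(date)) > window_days))),
       by = patient_id]
  recs[, event_id := .GRP, by = .(patient_id, grp)]
  recs[, grp := NULL]
  recs[]
}

#' Flag fatal bleeding events
#'
#' An event is fatal if it contains a death-registry bleeding record
#' (bleeding cause of death, underlying or otherwise), or if the patient's
#' all-cause death falls within `[0, window_days]` days of any primary-care
#' or hospital bleeding record in the event. Deaths preceding the record do
#' not count.
#'
#' @param grouped records with `event_id`, from [group_records()].
#' @param deaths death registry table (`patient_id`, `date`).
#' @param window_days fatal window (days), inclusive at both ends.
#' @return Integer vector of fatal `event_id`s.
#' @export
detect_fatal <- function(grouped, deaths, window_days = 7) {
  if (!nrow(grouped)) return(integer())
  by_cause <- unique(grouped[source == "death_registry", event_id])
  if (is.null(deaths) || !nrow(deaths)) return(sort(by_cause))
  d <- data.table::as.data.table(deaths)[, .(patient_id,
                                             death_date = as.Date(date))]
  g <- d[grouped[source != "death_registry"], on = "patient_id", nomatch = NULL]
  lag <- as.integer(g$death_date - g$date)
  by_death <- unique(g$event_id[!is.na(lag) & lag >= 0 & lag <= window_days])
  sort(unique(c(by_cause, by_death)))
}

#' Evaluate the four markers of severity per event
#'
#' @param grouped records with `event_id`.
#' @param procedures hospital procedures table (`patient_id`, `code`,
#'   `date`).
#' @param codelist a `codelist` (identifies transfusion procedures).
#' @param transfusion_window_days window around a bleeding record in which
#'   a hospital transfusion marks severity.
#' @param transfusion_direction `"symmetric"` (default, +/- window; a
#'   transfusion may precede the coding date within an admission) or
#'   `"forward"` (record date to record date + window only).
#' @param long_stay_days minimum length of hospitalisation (days,
#'   discharge minus admission) for the long-admission marker; satisfied at
#'   exactly `long_stay_days`.
#' @return `data.table` keyed by `event_id` with logical columns
#'   `long_primary_admission`, `critical_site`, `multi_site_same_day`,
#'   `transfusion_within_30d`.
#' @export
mark_severity <- function(grouped, procedures, codelist,
                          transfusion_window_days = 30,
                          transfusion_direction = c("symmetric", "forward"),
                          long_stay_days = 14) {
  transfusion_direction <- match.arg(transfusion_direction)
  ev <- unique(grouped[, .(event_id)])
  if (!nrow(ev)) {
    return(data.table(event_id = integer(), long_primary_admission = logical(),
                      critical_site = logical(), multi_site_same_day = logical(),
                      transfusion_within_30d = logical()))
  }
  m1 <- grouped[, .(long_primary_admission = any(
    source == "hospital" & !is.na(diagnosis_position) &
      diagnosis_position == 1L & !is.na(episode_length_days) &
      episode_length_days >= long_stay_days)), by = event_id]
  m2 <- grouped[, .(critical_site = any(site %in% .critical_sites)),
                by = event_id]
  # >= 2 distinct sites among the patient's coded records on one day
  day_sites <- grouped[, .(n_sites = data.table::uniqueN(site)),
                       by = .(patient_id, date)]
  g <- day_sites[grouped, on = c("patient_id", "date")]
  m3 <- g[, .(multi_site_same_day = any(n_sites >= 2L)), by = event_id]
  # hospital transfusion near any record of the event
  pr <- data.table::as.data.table(procedures)
  tx <- if (nrow(pr)) {
    pr[classify_code(codelist, pr$code, "opcs4")$category == "transfusion",
       .(patient_id, tx_date = as.Date(date))]
  } else {
    data.table(patient_id = integer(), tx_date = as.Date(character()))
  }
  if (nrow(tx)) {
    j <- tx[grouped, on = "patient_id", allow.cartesian = TRUE, nomatch = NULL]
    lag <- as.integer(j$tx_date - j$date)
    near <- if (transfusion_direction == "symmetric") {
      abs(lag) <= transfusion_window_days
    } else {
      lag >= 0L & lag <= transfusion_window_days
    }
    m4 <- unique(j[near, .(event_id)])
    m4[, transfusion_within_30d := TRUE]
  } else {
    m4 <- data.table(event_id = integer(), transfusion_within_30d = logical())
  }
  out <- Reduce(function(a, b) b[a, on = "event_id"], list(m1, m2, m3), ev)
  out <- m4[out, on = "event_id"]
  out[is.na(transfusion_within_30d), transfusion_within_30d := FALSE]
  data.table::setcolorder(out, c("event_id", "long_primary_admission",
                                 "critical_site", "multi_site_same_day",
                                 "transfusion_within_30d"))
  data.table::setorder(out, event_id)
  out[]
}

#' Infer uncoded bleeding events from indirect evidence
#'
#' Applied only to patients with no coded bleeding diagnosis in primary
#' care or hospital records. Four routes are evaluated in order (first
#' match wins per evidence span):
#'
#' 1. hospital transfusion and an iron-deficiency-anaemia diagnosis within
#'    `window_days` of each other;
#' 2. a surgical procedure to arrest bleeding or evacuate a haematoma;
#' 3. haemoglobin below `hb_threshold` g/dL, iron-deficiency anaemia and an
#'    endoscopic examination within a `window_days` span, with no cancer,
#'    liver-disease or renal-disease record in the `lookback_days` before
#'    the anchor date;
#' 4. transfusion, haemoglobin below `hb_threshold` and endoscopy within a
#'    `window_days` span, with the same exclusion.
#'
#' The event date (anchor) is the earliest component date. Candidate events
#' whose anchors fall within `window_days` of an already accepted anchor
#' are suppressed, so one evidence span yields one event.
#'
#' @param ehr a `linked_ehr`.
#' @param codelist a `codelist`.
#' @param window_days evidence span (days).
#' @param lookback_days exclusion lookback, ending the day before the
#'   anchor.
#' @param hb_threshold haemoglobin threshold in g/dL (strictly below).
#' @param require_hb_in_span if `TRUE` (default, the stricter reading) the
#'   low haemoglobin in route 3 must fall inside the same `window_days`
#'   span as the anaemia diagnosis and the endoscopy; if `FALSE` it may
#'   fall up to `3 * window_days` before the anchor.
#' @return `data.table` of inferred events: `patient_id`, `date`, `route`
#'   (`route1`..`route4`).
#' @export
infer_uncoded_bleeds <- function(ehr, codelist, window_days = 30,
                                 lookback_days = 365, hb_threshold = 10,
                                 require_hb_in_span = TRUE) {
  stopifnot(inherits(ehr, "linked_ehr"))
  empty <- data.table(patient_id = integer(), date = as.Date(character()),
                      route = character())
  coded <- assemble_bleeding_records(ehr, codelist)
  blocked <- unique(coded[source %in% c("primary_care", "hospital"),
                          patient_id])

  pc <- ehr$primary_care
  pc_cls <- if (nrow(pc)) classify_code(codelist, pc$code, "readlike")$category
            else character()
  hd <- ehr$hospital_diagnoses
  hd_cls <- if (nrow(hd)) classify_code(codelist, hd$code, "icd10")$category
            else character()
  hd_dates <- if (nrow(hd)) {
    ehr$hospital_episodes[, .(episode_id, adm = as.Date(admission_date))][
      hd, on = "episode_id"]$adm
  } else as.Date(character())
  pr <- ehr$hospital_procedures
  pr_cls <- if (nrow(pr)) classify_code(codelist, pr$code, "opcs4")$category
            else character()

  diag_dates <- function(cats) {
    rbind(
      data.table(patient_id = pc$patient_id, date = as.Date(pc$date))[
        pc_cls %in% cats],
      data.table(patient_id = hd$patient_id, date = hd_dates)[hd_cls %in% cats])
  }
  proc_dates <- function(cats) {
    data.table(patient_id = pr$patient_id, date = as.Date(pr$date))[
      pr_cls %in% cats]
  }
  tx <- proc_dates("transfusion")
  endo <- proc_dates("endoscopy")
  surg <- proc_dates(c("surgical_arrest_bleeding", "haematoma_evacuation"))
  ida <- diag_dates("iron_deficiency_anaemia")
  excl <- diag_dates(c("cancer", "liver_disease", "renal_disease"))
  lb <- ehr$labs
  hb <- if (nrow(lb)) {
    data.table::as.data.table(lb)[analyte == "haemoglobin" &
                                    value < hb_threshold,
                                  .(patient_id, date = as.Date(date))]
  } else empty[, .(patient_id, date)]

  drop_blocked <- function(tbl) tbl[!patient_id %in% blocked]
  tx <- drop_blocked(tx); endo <- drop_blocked(endo)
  surg <- drop_blocked(surg); ida <- drop_blocked(ida)
  hb <- drop_blocked(hb)

  no_exclusion <- function(cand) {
    # no cancer/liver/renal record in [anchor - lookback, anchor)
    if (!nrow(cand) || !nrow(excl)) return(cand)
    j <- excl[cand, on = "patient_id", allow.cartesian = TRUE, nomatch = NULL]
    if (nrow(j)) {
      j[, lag := as.integer(i.date - date)]  # anchor - exclusion record
      bad <- unique(j[lag >= 1L & lag <= lookback_days,
                      .(patient_id, date = i.date)])
      cand <- cand[!bad, on = c("patient_id", "date")]
    }
    cand
  }
  pair_within <- function(a, b, w = window_days) {
    # earliest anchor per qualifying pair
    if (!nrow(a) || !nrow(b)) return(empty[, .(patient_id, date)])
    j <- a[b, on = "patient_id", allow.cartesian = TRUE, nomatch = NULL]
    j <- j[abs(as.integer(date - i.date)) <= w]
    if (!nrow(j)) return(empty[, .(patient_id, date)])
    j[, .(patient_id, date = pmin(date, i.date))]
  }
  # routes 1 and 2
  r1 <- pair_within(tx, ida)
  if (nrow(r1)) r1[, route := "route1"]
  r2 <- surg[, .(patient_id, date)]
  if (nrow(r2)) r2[, route := "route2"]

  # routes 3 and 4: all components within one span of width window_days
  span_triple <- function(x, y, z) {
    if (!nrow(x) || !nrow(y) || !nrow(z)) return(empty[, .(patient_id, date)])
    xy <- x[, .(patient_id, dx = date)][y[, .(patient_id, dy = date)],
                                        on = "patient_id",
                                        allow.cartesian = TRUE, nomatch = NULL]
    xy <- xy[abs(as.integer(dx - dy)) <= window_days]
    if (!nrow(xy)) return(empty[, .(patient_id, date)])
    xyz <- xy[z[, .(patient_id, dz = date)], on = "patient_id",
              allow.cartesian = TRUE, nomatch = NULL]
    if (!nrow(xyz)) return(empty[, .(patient_id, date)])
    lo <- pmin(xyz$dx, xyz$dy, xyz$dz)
    hi <- pmax(xyz$dx, xyz$dy, xyz$dz)
    ok <- as.integer(hi - lo) <= window_days
    unique(data.table(patient_id = xyz$patient_id[ok], date = lo[ok]))
  }
  relaxed_triple <- function(x, y, hb_tbl) {
    # x, y within the span; low haemoglobin allowed earlier (looser reading)
    xy <- pair_within(x, y)
    if (!nrow(xy)) return(xy)
    j <- hb_tbl[xy, on = "patient_id", allow.cartesian = TRUE, nomatch = NULL]
    if (!nrow(j)) return(empty[, .(patient_id, date)])
    lag <- as.integer(j$i.date - j$date)  # anchor - hb date
    ok <- lag >= -window_days & lag <= 3L * window_days
    unique(j[ok, .(patient_id, date = pmin(date, i.date))])
  }
  r3 <- if (require_hb_in_span) span_triple(hb, ida, endo)
        else relaxed_triple(ida, endo, hb)
  r3 <- no_exclusion(unique(r3))
  if (nrow(r3)) r3[, route := "route3"]
  r4 <- span_triple(tx, hb, endo)
  r4 <- no_exclusion(unique(r4))
  if (nrow(r4)) r4[, route := "route4"]

  cand <- data.table::rbindlist(list(r1, r2, r3, r4), use.names = TRUE,
                                fill = TRUE)
  if (!nrow(cand)) return(empty)
  cand <- unique(cand)
  cand[, rk := match(route, paste0("route", 1:4))]
  data.table::setorder(cand, patient_id, date, rk)
  # greedy acceptance: one event per evidence span
  accept <- cand[, {
    keep <- logical(.N)
    last <- as.Date(NA)
    for (i in seq_len(.N)) {
      if (is.na(last) || as.integer(date[i] - last) > window_days) {
        keep[i] <- TRUE
        last <- date[i]
      }
    }
    .SD[keep]
  }, by = patient_id]
  accept[, rk := NULL]
  accept[]
}

#' Classify grouped bleeding records into events
#'
#' Applies the category precedence fatal > hospitalised_ms >
#' primary_care_ms > hospitalised > primary_care. `hospitalised_ms`
#' requires a hospital record plus any marker of severity;
#' `primary_care_ms` requires primary-care-only records plus any marker (a
#' tie between the two cannot occur because hospital presence decides).
#' Inferred events, supplied separately, keep category `inferred`.
#'
#' @param grouped records with `event_id` from [group_records()].
#' @param markers per-event markers from [mark_severity()].
#' @param fatal_ids integer vector of fatal event ids from [detect_fatal()].
#' @param inferred optional inferred events from [infer_uncoded_bleeds()].
#' @return `data.table` of events: `patient_id`, `event_id`, `event_date`
#'   (earliest contributing record), `category`, `prognostic_class`, the
#'   four marker flags, `route`, `sources` and `record_ids`
#'   (semicolon-joined provenance).
#' @export
classify_events <- function(grouped, markers, fatal_ids,
                            inferred = NULL) {
  if (nrow(grouped)) {
    ev <- grouped[, .(
      patient_id = patient_id[1L],
      event_date = min(date),
      has_hospital = any(source == "hospital"),
      has_pc = any(source == "primary_care"),
      sources = paste(sort(unique(source)), collapse = ";"),
      record_ids = paste(record_id[order(date, record_id)], collapse = ";"),
      n_records = .N), by = event_id]
  } else {
    ev <- data.table(event_id = integer(), patient_id = integer(),
                     event_date = as.Date(character()),
                     has_hospital = logical(), has_pc = logical(),
                     sources = character(), record_ids = character(),
                     n_records = integer())
  }
  ev <- markers[ev, on = "event_id"]
  ev[, ms := long_primary_admission | critical_site | multi_site_same_day |
       transfusion_within_30d]
  ev[, category := data.table::fcase(
    event_id %in% fatal_ids, "fatal",
    has_hospital & ms, "hospitalised_ms",
    !has_hospital & has_pc & ms, "primary_care_ms",
    has_hospital, "hospitalised",
    has_pc, "primary_care",
    default = "fatal")]  # death-registry-only events
  ev[, route := NA_character_]
  out <- ev[, .(patient_id, event_id, event_date, category,
                long_primary_admission, critical_site, multi_site_same_day,
                transfusion_within_30d, route, sources, record_ids, n_records)]
  if (!is.null(inferred) && nrow(inferred)) {
    inf <- data.table::as.data.table(inferred)
    add <- inf[, .(patient_id, event_id = NA_integer_,
                   event_date = as.Date(date), category = "inferred",
                   long_primary_admission = FALSE, critical_site = FALSE,
                   multi_site_same_day = FALSE, transfusion_within_30d = FALSE,
                   route, sources = "inferred", record_ids = "",
                   n_records = 0L)]
    out <- rbind(out, add)
  }
  out[, prognostic_class := prognostic_class(category)]
  data.table::setorder(out, patient_id, event_date)
  base_id <- max(c(0L, out$event_id), na.rm = TRUE)
  out[is.na(event_id), event_id := base_id + seq_len(.N)]
  data.table::setcolorder(out, c("patient_id", "event_id", "event_date",
                                 "category", "prognostic_class"))
  out[]
}

#' Run the full bleeding phenotyping algorithm
#'
#' Convenience wrapper: assembles records, groups them, applies the fatal
#' rule and markers of severity, classifies events, and (optionally)
#' appends inferred bleeds for patients without coded bleeding diagnoses.
#'
#' @param ehr a `linked_ehr`.
#' @param codelist a `codelist`; defaults to the bundled illustrative list.
#' @param window_days event-grouping window (days); also the evidence span
#'   for inferred bleeds and the transfusion marker window.
#' @param fatal_window_days window of the fatal rule.
#' @param long_stay_days threshold for the long-admission marker.
#' @param infer whether to detect inferred bleeds.
#' @param include_death_only whether a death-registry-only bleeding cause
#'   with no nearby records forms its own fatal event (default `TRUE`).
#' @param ... passed to [mark_severity()] and [infer_uncoded_bleeds()].
#' @return Event table as from [classify_events()].
#' @export
phenotype_bleeding <- function(ehr, codelist = default_codelist(),
                               window_days = 30, fatal_window_days = 7,
                               long_stay_days = 14, infer = TRUE,
                               include_death_only = TRUE, ...) {
  dots <- list(...)
  recs <- assemble_bleeding_records(ehr, codelist)
  grouped <- group_records(recs, window_days)
  fatal_ids <- detect_fatal(grouped, ehr$deaths, fatal_window_days)
  mk_args <- dots[names(dots) %in% c("transfusion_window_days",
                                     "transfusion_direction")]
  markers <- do.call(mark_severity,
                     c(list(grouped, ehr$hospital_procedures, codelist,
                            long_stay_days = long_stay_days), mk_args))
  inferred <- NULL
  if (infer) {
    inf_args <- dots[names(dots) %in% c("lookback_days", "hb_threshold",
                                        "require_hb_in_span")]
    inferred <- do.call(infer_uncoded_bleeds,
                        c(list(ehr, codelist, window_days = window_days),
                          inf_args))
  }
  ev <- classify_events(grouped, markers, fatal_ids, inferred)
  if (!include_death_only) {
    ev <- ev[!(category == "fatal" & sources == "death_registry")]
  }
  ev[]
}

#' Per-patient first bleeding events
#'
#' Two selectors: the first event of any severity and the first fatal or
#' with-markers-of-severity event (`fatal`, `hospitalised_ms`,
#' `primary_care_ms`). Same-day ties are resolved by severity precedence
#' (fatal > hospitalised_ms > primary_care_ms > hospitalised >
#' primary_care > inferred).
#'
#' @param events event table from [phenotype_bleeding()].
#' @return `data.table` keyed by `patient_id` with `first_any_date`,
#'   `first_any_category`, `first_severe_date`, `first_severe_category`
#'   (`NA` where no qualifying event exists).
#' @export
first_events <- function(events) {
  ev <- data.table::as.data.table(events)
  if (!nrow(ev)) {
    return(data.table(patient_id = integer(),
                      first_any_date = as.Date(character()),
                      first_any_category = character(),
                      first_severe_date = as.Date(character()),
                      first_severe_category = character()))
  }
  ev[, rk := match(category, .bleed_categories)]
  data.table::setorder(ev, patient_id, event_date, rk)
  any_ <- ev[, .(first_any_date = event_date[1L],
                 first_any_category = category[1L]), by = patient_id]
  sev <- ev[category %in% c("fatal", "hospitalised_ms", "primary_care_ms"),
            .(first_severe_date = event_date[1L],
              first_severe_category = category[1L]), by = patient_id]
  out <- sev[any_, on = "patient_id"]
  data.table::setcolorder(out, c("patient_id", "first_any_date",
                                 "first_any_category", "first_severe_date",
                                 "first_severe_category"))
  out[]
}

#' Share of coded bleeding events captured in two or more sources
#'
#' @param records coded bleeding records from
#'   [assemble_bleeding_records()].
#' @param window_days grouping window.
#' @return Fraction of grouped events whose records span at least two of
#'   the three sources (`NaN` when there are no events).
#' @export
source_overlap <- function(records, window_days = 30) {
  g <- group_records(records, window_days)
  if (!nrow(g)) return(NaN)
  ns <- g[, .(k = data.table::uniqueN(source)), by = event_id]
  mean(ns$k >= 2L)
}

#' Flag hospital episodes carrying a coded bleeding diagnosis
#'
#' Fills the `algorithm_flag` column of a validation sample (see
#' [make_validation_sample()]): an episode is flagged when any of its
#' diagnoses is a bleeding code.
#'
#' @param sample `data.table` with an `episode_id` column.
#' @param ehr a `linked_ehr`.
#' @param codelist a `codelist`.
#' @return The sample with `algorithm_flag` set (logical).
#' @export
flag_bleeding_episodes <- function(sample, ehr, codelist) {
  s <- data.table::as.data.table(sample)
  hd <- ehr$hospital_diagnoses
  flagged <- if (nrow(hd)) {
    unique(hd$episode_id[classify_code(codelist, hd$code,
                                       "icd10")$category == "bleeding"])
  } else integer()
  s[, algorithm_flag := episode_id %in% flagged]
  s[]
}
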