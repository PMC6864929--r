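#' Cohort construction
#'
#' Patients enter the cohort at their first diagnosis of atrial
#' fibrillation, acute myocardial infarction, unstable angina or stable
#' angina in primary-care or hospital records, provided they are at least
#' 18 years old at that date. Follow-up ends at death, transfer out of the
#' practice, or administrative censoring, whichever comes first.
#'
#' @name cohort
NULL

.index_diseases <- c(cvd_af = "af", cvd_mi = "mi", cvd_ua = "ua",
                     cvd_sa = "sa")
# same-day multi-disease tie-break precedence
.disease_precedence <- c("mi", "ua", "af", "sa")

.baseline_flag_categories <- c(
  diabetes = "comorbidity_diabetes", stroke = "comorbidity_stroke",
  pad = "comorbidity_pad", cancer = "cancer", renal = "renal_disease",
  peptic_ulcer = "comorbidity_peptic_ulcer",
  bleeding_diathesis = "comorbidity_bleeding_diathesis",
  chronic_anaemia = "comorbidity_chronic_anaemia")

# all classified diagnosis dates across primary care and hospital
.all_diagnoses <- function(ehr, codelist) {
  pc <- ehr$primary_care
  out <- list()
  if (nrow(pc)) {
    cls <- classify_code(codelist, pc$code, "readlike")
    out$pc <- data.table(patient_id = pc$patient_id, date = as.Date(pc$date),
                         category = cls$category)
  }
  hd <- ehr$hospital_diagnoses
  if (nrow(hd)) {
    cls <- classify_code(codelist, hd$code, "icd10")
    adm <- ehr$hospital_episodes[, .(episode_id,
                                     adm = as.Date(admission_date))][
      hd, on = "episode_id"]$adm
    out$hd <- data.table(patient_id = hd$patient_id, date = adm,
                         category = cls$category)
  }
  dx <- data.table::rbindlist(out)
  if (!nrow(dx)) {
    dx <- data.table(patient_id = integer(), date = as.Date(character()),
                     category = character())
  }
  dx[!is.na(category)]
}

#' Build the study cohort
#'
#' @param ehr a `linked_ehr`.
#' @param codelist a `codelist`.
#' @param censor_date administrative censoring date (follow-up never
#'   extends past it; patients whose first qualifying diagnosis falls
#'   after it are excluded).
#' @param min_age minimum age (years) at entry.
#' @return `data.table` with one row per cohort member: `patient_id`,
#'   `entry_date`, `index_disease` (`af`, `mi`, `ua`, `sa`; same-day ties
#'   resolved by the precedence mi > ua > af > sa), `age_at_entry`, `sex`,
#'   `end_of_follow_up`, `end_reason` (`death`, `transfer_out`,
#'   `admin_censor`), eight logical `base_*` comorbidity flags (any record
#'   strictly before entry) and baseline biomarkers `sbp`, `haemoglobin`,
#'   `creatinine` (nearest record in the year before entry, `NA` if none).
#'   Patients without a qualifying diagnosis are excluded, not an error.
#' @export
build_cohort <- function(ehr, codelist,
                         censor_date = as.Date("2010-03-31"),
                         min_age = 18) {
  stopifnot(inherits(ehr, "linked_ehr"))
  dx <- .all_diagnoses(ehr, codelist)
  cvd <- dx[category %in% names(.index_diseases)]
  if (!nrow(cvd)) {
    return(data.table(patient_id = integer()))
  }
  cvd[, disease := .index_diseases[category]]
  cvd[, prec := match(disease, .disease_precedence)]
  data.table::setorder(cvd, patient_id, date, prec)
  first <- cvd[, .(entry_date = date[1L], index_disease = disease[1L]),
               by = patient_id]
  first <- first[entry_date <= censor_date]

  pat <- ehr$patients[, .(patient_id, sex, birth_date = as.Date(birth_date),
                          transfer_out_date = as.Date(transfer_out_date))]
  m <- pat[first, on = "patient_id", nomatch = NULL]
  m[, age_at_entry := as.numeric(entry_date - birth_date) / 365.25]
  m <- m[age_at_entry >= min_age]
  if (!nrow(m)) return(data.table(patient_id = integer()))

  d <- ehr$deaths[, .(patient_id, death_date = as.Date(date))]
  m <- d[m, on = "patient_id"]
  end_int <- pmin(as.integer(m$death_date), as.integer(m$transfer_out_date),
                  as.integer(censor_date), na.rm = TRUE)
  m[, end_of_follow_up := as.Date(end_int, origin = "1970-01-01")]
  # death takes precedence over transfer on ties, transfer over censoring
  m[, end_reason := data.table::fcase(
    !is.na(death_date) & as.integer(death_date) == end_int, "death",
    !is.na(transfer_out_date) & as.integer(transfer_out_date) == end_int,
    "transfer_out",
    default = "admin_censor")]
  m <- m[end_of_follow_up >= entry_date]

  # baseline comorbidity flags: any record strictly before entry
  for (fl in names(.baseline_flag_categories)) {
    cats <- .baseline_flag_categories[[fl]]
    hit <- dx[category %in% cats][m[, .(patient_id, entry_date)],
                                  on = "patient_id", nomatch = NULL]
    flagged <- unique(hit[date < entry_date, patient_id])
    m[, (paste0("base_", fl)) := patient_id %in% flagged]
  }

  # baseline biomarkers: nearest record in [entry - 365, entry)
  lb <- data.table::as.data.table(ehr$labs)
  for (an in c("sbp", "haemoglobin", "creatinine")) {
    if (nrow(lb)) {
      v <- lb[analyte == an][m[, .(patient_id, entry_date)],
                             on = "patient_id", nomatch = NULL]
      v <- v[as.Date(date) < entry_date &
               as.Date(date) >= entry_date - 365L]
      v <- v[order(-as.Date(date)), .SD[1L], by = patient_id]
      m[, (an) := v[m, on = "patient_id", x.value]]
    } else {
      m[, (an) := NA_real_]
    }
  }
  out <- m[, c("patient_id", "entry_date", "index_disease", "age_at_entry",
               "sex", "end_of_follow_up", "end_reason",
               paste0("base_", names(.baseline_flag_categories)),
               "sbp", "haemoglobin", "creatinine"), with = FALSE]
  data.table::setorder(out, patient_id)
  out[]
}

#' Baseline biomarker lookup for one patient
#'
#' Returns the value of the record nearest to entry within the half-open
#' window `[entry - window_days, entry)`; the entry day itself is
#' excluded ("prior to entry").
#'
#' @param ehr a `linked_ehr`.
#' @param patient_id patient identifier.
#' @param entry_date entry date (`Date`).
#' @param analyte one of the analytes in the labs table (e.g.
#'   `"haemoglobin"`).
#' @param window_days lookback window length.
#' @return Numeric value or `NA` if no record qualifies.
#' @export
baseline_biomarker <- function(ehr, patient_id, entry_date, analyte,
                               window_days = 365) {
  lb <- data.table::as.data.table(ehr$labs)
  entry_date <- as.Date(entry_date)
  v <- lb[lb$patient_id == patient_id & lb$analyte == analyte]
  if (!nrow(v)) return(NA_real_)
  v[, date := as.Date(date)]
  v <- v[date < entry_date & date >= entry_date - window_days]
  if (!nrow(v)) return(NA_real_)
  v$value[which.max(as.integer(v$date))]
}
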