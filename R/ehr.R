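#' Linked EHR container
#'
#' A `linked_ehr` bundles the four linked sources the phenotyper consumes
#' (primary-care clinical events, prescriptions and lab tests; hospital
#' episodes with positioned diagnoses and dated procedures; and a death
#' registry with underlying and contributory causes) plus, when produced
#' by the simulator, a `ground_truth` table that downstream phenotyping
#' never reads.
#'
#' @name linked_ehr
NULL

.empty_ehr_tables <- function() {
  list(
    patients = data.table(patient_id = integer(), sex = character(),
                          birth_date = as.Date(character()),
                          transfer_out_date = as.Date(character())),
    primary_care = data.table(patient_id = integer(),
                              date = as.Date(character()), code = character()),
    prescriptions = data.table(patient_id = integer(),
                               date = as.Date(character()),
                               code = character()),
    labs = data.table(patient_id = integer(), date = as.Date(character()),
                      analyte = character(), value = numeric()),
    hospital_episodes = data.table(episode_id = integer(),
                                   patient_id = integer(),
                                   admission_date = as.Date(character()),
                                   discharge_date = as.Date(character())),
    hospital_diagnoses = data.table(episode_id = integer(),
                                    patient_id = integer(), code = character(),
                                    position = integer()),
    hospital_procedures = data.table(episode_id = integer(),
                                     patient_id = integer(),
                                     code = character(),
                                     date = as.Date(character())),
    deaths = data.table(patient_id = integer(), date = as.Date(character())),
    death_causes = data.table(patient_id = integer(), code = character(),
                              role = character()),
    ground_truth = data.table(patient_id = integer(),
                              bleed_date = as.Date(character()),
                              site = character(), therapy_state = character(),
                              uncoded = logical(), route = character(),
                              fatal = logical(), observed = logical(),
                              category = character(),
                              prognostic_class = character(),
                              episode_id = integer())
  )
}

#' Construct a linked EHR object
#'
#' Missing tables default to empty; basic invariants are checked: every
#' row references a known patient, discharges do not precede admissions,
#' and no record is dated after the patient's death.
#'
#' @param ... named tables (see [linked_ehr]).
#' @param config optional simulation configuration to attach.
#' @return A `linked_ehr` object.
#' @export
new_linked_ehr <- function(..., config = NULL) {
  tabs <- .empty_ehr_tables()
  supplied <- list(...)
  for (nm in names(supplied)) {
    if (!nm %in% names(tabs)) stop("unknown linked_ehr table: ", nm)
    tabs[[nm]] <- data.table::as.data.table(supplied[[nm]])
  }
  ehr <- structure(tabs, class = "linked_ehr")
  ehr$config <- config
  validate_linked_ehr(ehr)
  ehr
}

#' @rdname new_linked_ehr
#' @param ehr a `linked_ehr`.
#' @export
validate_linked_ehr <- function(ehr) {
  ids <- ehr$patients$patient_id
  for (nm in c("primary_care", "prescriptions", "labs", "hospital_episodes",
               "deaths")) {
    tbl <- ehr[[nm]]
    if (nrow(tbl) && !all(tbl$patient_id %in% ids)) {
      stop("linked_ehr invariant violated: ", nm,
           " references unknown patient id(s)")
    }
  }
  he <- ehr$hospital_episodes
  if (nrow(he) && any(as.Date(he$discharge_date) < as.Date(he$admission_date))) {
    stop("linked_ehr invariant violated: discharge before admission")
  }
  d <- ehr$deaths
  if (nrow(d)) {
    dd <- d[, .(patient_id, death_date = as.Date(date))]
    for (nm in c("primary_care", "prescriptions", "labs")) {
      j <- dd[ehr[[nm]], on = "patient_id", nomatch = NULL]
      if (nrow(j) && any(as.Date(j$date) > j$death_date)) {
        stop("linked_ehr invariant violated: ", nm, " record after death")
      }
    }
  }
  invisible(ehr)
}

#' @export
print.linked_ehr <- function(x, ...) {
  cat("<linked_ehr>", nrow(x$patients), "patients\n")
  for (nm in c("primary_care", "prescriptions", "labs", "hospital_episodes",
               "hospital_diagnoses", "hospital_procedures", "deaths",
               "ground_truth")) {
    cat(sprintf("  %-20s %8d rows\n", nm, nrow(x[[nm]])))
  }
  invisible(x)
}

#' Write a linked EHR as a directory of CSV files
#'
#' Hospital diagnoses are packed into `hospital.csv` as
#' `code:position` pairs joined by `;`, procedures as `code@date` pairs;
#' contributory death causes are `;`-joined. All dates are ISO-8601.
#'
#' @param ehr a `linked_ehr`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_ehr <- function(ehr, dir) {
  stopifnot(inherits(ehr, "linked_ehr"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fw <- function(x, f) data.table::fwrite(x, file.path(dir, f))
  fw(ehr$patients, "patients.csv")
  fw(ehr$primary_care, "primary_care.csv")
  fw(ehr$prescriptions, "prescriptions.csv")
  fw(ehr$labs, "labs.csv")
  dx <- ehr$hospital_diagnoses[, .(
    diagnoses = paste(paste0(code, ":", position), collapse = ";")),
    by = episode_id]
  pr <- ehr$hospital_procedures[, .(
    procedures = paste(paste0(code, "@", date), collapse = ";")),
    by = episode_id]
  hosp <- pr[dx[ehr$hospital_episodes, on = "episode_id"], on = "episode_id"]
  data.table::setcolorder(hosp, c("episode_id", "patient_id",
                                  "admission_date", "discharge_date",
                                  "diagnoses", "procedures"))
  fw(hosp, "hospital.csv")
  dc <- ehr$death_causes
  und <- dc[role == "underlying", .(underlying_cause = code[1L]),
            by = patient_id]
  ctr <- dc[role == "contributory",
            .(contributory_causes = paste(code, collapse = ";")),
            by = patient_id]
  deaths <- ctr[und[ehr$deaths, on = "patient_id"], on = "patient_id"]
  data.table::setcolorder(deaths, c("patient_id", "date", "underlying_cause",
                                    "contributory_causes"))
  fw(deaths, "deaths.csv")
  fw(ehr$ground_truth, "ground_truth.csv")
  invisible(dir)
}

#' Read a linked EHR from a directory of CSV files
#'
#' @param dir directory written by [write_ehr()].
#' @return A `linked_ehr` object.
#' @export
read_ehr <- function(dir) {
  fr <- function(f) {
    p <- file.path(dir, f)
    if (file.exists(p)) data.table::fread(p) else NULL
  }
  date_cols <- function(x, cols) {
    for (cl in intersect(cols, names(x))) x[[cl]] <- as.Date(x[[cl]])
    x
  }
  pats <- date_cols(fr("patients.csv"), c("birth_date", "transfer_out_date"))
  pc <- date_cols(fr("primary_care.csv"), "date")
  rx <- date_cols(fr("prescriptions.csv"), "date")
  labs <- date_cols(fr("labs.csv"), "date")
  hosp <- date_cols(fr("hospital.csv"), c("admission_date", "discharge_date"))
  deaths <- date_cols(fr("deaths.csv"), "date")
  gt <- fr("ground_truth.csv")
  if (!is.null(gt) && nrow(gt)) gt <- date_cols(gt, "bleed_date")

  epi <- hosp[, .(episode_id, patient_id, admission_date, discharge_date)]
  unpack <- function(col, split_fun) {
    rows <- hosp[!is.na(get(col)) & get(col) != ""]
    if (!nrow(rows)) return(NULL)
    parts <- strsplit(rows[[col]], ";", fixed = TRUE)
    data.table(episode_id = rep(rows$episode_id, lengths(parts)),
               patient_id = rep(rows$patient_id, lengths(parts)),
               token = unlist(parts))
  }
  dxl <- unpack("diagnoses")
  dx <- if (is.null(dxl)) NULL else {
    sp <- data.table::tstrsplit(dxl$token, ":", fixed = TRUE)
    data.table(episode_id = dxl$episode_id, patient_id = dxl$patient_id,
               code = sp[[1]], position = as.integer(sp[[2]]))
  }
  prl <- unpack("procedures")
  pr <- if (is.null(prl)) NULL else {
    sp <- data.table::tstrsplit(prl$token, "@", fixed = TRUE)
    data.table(episode_id = prl$episode_id, patient_id = prl$patient_id,
               code = sp[[1]], date = as.Date(sp[[2]]))
  }
  dc <- NULL
  if (!is.null(deaths) && nrow(deaths)) {
    und <- deaths[!is.na(underlying_cause) & underlying_cause != "",
                  .(patient_id, code = underlying_cause, role = "underlying")]
    ctr <- NULL
    if ("contributory_causes" %in% names(deaths)) {
      rows <- deaths[!is.na(contributory_causes) & contributory_causes != ""]
      if (nrow(rows)) {
        parts <- strsplit(rows$contributory_causes, ";", fixed = TRUE)
        ctr <- data.table(patient_id = rep(rows$patient_id, lengths(parts)),
                          code = unlist(parts), role = "contributory")
      }
    }
    dc <- rbind(und, ctr)
  }
  args <- list(patients = pats, primary_care = pc, prescriptions = rx,
               labs = labs, hospital_episodes = epi,
               deaths = if (is.null(deaths)) NULL else
                 deaths[, .(patient_id, date)],
               hospital_diagnoses = dx, hospital_procedures = pr,
               death_causes = dc, ground_truth = gt)
  do.call(new_linked_ehr, Filter(Negate(is.null), args))
}
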