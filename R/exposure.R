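#' Antithrombotic exposure model
#'
#' Prescription issues are turned into continuous drug-exposure episodes
#' using a gap rule: consecutive same-class issues at most `gap_days` apart
#' belong to one episode (90 days is the longest prescription duration
#' allowed in UK primary care, hence the default). An episode is assumed to
#' cover `gap_days` beyond its last issue. Episodes of the three drug
#' classes (aspirin, ADP-receptor inhibitor, VKA) are then overlaid into a
#' seven-state therapy timeline: none, aspirin monotherapy, ADP-inhibitor
#' monotherapy, dual antiplatelet therapy, VKA monotherapy, VKA plus one
#' antiplatelet, and triple therapy.
#'
#' All intervals are half-open `[start, end)` in whole days.
#'
#' @name exposure
NULL

.drug_classes <- c("aspirin", "adp", "vka")

.therapy_states <- c("none", "aspirin_mono", "adp_mono", "dapt",
                     "vka_mono", "vka_plus_one", "triple")

#' Map active drug classes to a therapy state
#'
#' @param aspirin,adp,vka logical vectors: is the class active?
#' @return Character vector of therapy states.
#' @export
therapy_state <- function(aspirin, adp, vka) {
  n_ap <- aspirin + adp
  state <- rep("none", length(aspirin))
  state[!vka & n_ap == 1 & aspirin] <- "aspirin_mono"
  state[!vka & n_ap == 1 & adp] <- "adp_mono"
  state[!vka & n_ap == 2] <- "dapt"
  state[vka & n_ap == 0] <- "vka_mono"
  state[vka & n_ap == 1] <- "vka_plus_one"
  state[vka & n_ap == 2] <- "triple"
  state
}

#' Build prescription episodes with a gap rule
#'
#' @param prescriptions data frame with columns `patient_id`, `date`
#'   (`Date`) and either `drug_class` (one of `aspirin`, `adp`, `vka`) or
#'   `code` (classified through `codelist`).
#' @param gap_days maximum gap (days) between issues of one continuous
#'   episode; also the assumed coverage after the last issue.
#' @param codelist optional `codelist` used to map `code` to a drug class
#'   via the `antithrombotic_*` categories when `drug_class` is absent.
#' @return `data.table` with columns `patient_id`, `drug_class`, `start`,
#'   `end` (`Date`, half-open), `n_issues`. Issues whose class cannot be
#'   determined are dropped with a warning. Order of input rows is
#'   irrelevant and the operation is idempotent.
#' @export
build_episodes <- function(prescriptions, gap_days = 90, codelist = NULL) {
  rx <- data.table::as.data.table(prescriptions)
  if (!nrow(rx)) {
    return(data.table(patient_id = integer(), drug_class = character(),
                      start = as.Date(character()), end = as.Date(character()),
                      n_issues = integer()))
  }
  if (!"drug_class" %in% names(rx)) {
    if (is.null(codelist) || !"code" %in% names(rx)) {
      stop("prescriptions need a 'drug_class' column, or a 'code' column ",
           "plus a codelist")
    }
    cat_ <- classify_code(codelist, rx$code, "readlike")$category
    rx[, drug_class := data.table::fcase(
      cat_ == "antithrombotic_aspirin", "aspirin",
      cat_ == "antithrombotic_adp", "adp",
      cat_ == "antithrombotic_vka", "vka",
      default = NA_character_)]
  }
  unknown <- is.na(rx$drug_class) | !rx$drug_class %in% .drug_classes
  if (any(unknown)) {
    warning(sum(unknown), " prescription(s) with unknown drug class skipped",
            call. = FALSE)
    rx <- rx[!unknown]
  }
  rx[, date := as.Date(date)]
  rx <- unique(rx[, .(patient_id, drug_class, date)])
  data.table::setorder(rx, patient_id, drug_class, date)
  rx[, grp := cumsum(c(1L, as.integer(diff(as.integer(date)) > gap_days))),
     by = .(patient_id, drug_class)]
  ep <- rx[, .(start = min(date), end = max(date) + gap_days,
               n_issues = .N),
           by = .(patient_id, drug_class, grp)]
  ep[, grp := NULL]
  ep[]
}

#' Overlay drug episodes into a tiled therapy timeline
#'
#' Sweeps over all episode boundaries of a patient and assigns each
#' resulting interval the state of the concurrently active drug classes.
#' Intervals tile the follow-up exactly: they are pairwise disjoint,
#' contiguous, and their union is `[entry, end)`.
#'
#' @param episodes `data.table` as produced by [build_episodes()].
#' @param follow_up data frame with columns `patient_id`, `entry`, `end`
#'   (`Date`); episodes are clipped to this window. Patients present in
#'   `follow_up` but without episodes get a single `none` interval.
#' @return `data.table` with columns `patient_id`, `start`, `end` (`Date`,
#'   half-open) and `state`.
#' @export
therapy_timeline <- function(episodes, follow_up) {
  fu <- data.table::as.data.table(follow_up)[, .(patient_id,
                                                 entry = as.Date(entry),
                                                 end = as.Date(end))]
  if (any(fu$end < fu$entry)) stop("follow-up ends before entry")
  ep <- data.table::as.data.table(episodes)
  if (nrow(ep)) {
    ep <- ep[fu, on = "patient_id", nomatch = NULL,
             .(patient_id, drug_class, start = pmax(start, entry),
               end = pmin(end, i.end))][end > start]
  }
  # boundary sweep, all patients at once
  bounds <- rbind(fu[, .(patient_id, day = entry)],
                  fu[, .(patient_id, day = end)],
                  if (nrow(ep)) ep[, .(patient_id, day = start)],
                  if (nrow(ep)) ep[, .(patient_id, day = end)])
  bounds <- unique(bounds)
  data.table::setorder(bounds, patient_id, day)
  iv <- bounds[, .(start = head(day, -1L), end = tail(day, -1L)),
               by = patient_id][end > start]
  if (!nrow(iv)) {
    return(data.table(patient_id = fu$patient_id[0],
                      start = as.Date(character()),
                      end = as.Date(character()), state = character()))
  }
  for (cls in .drug_classes) {
    cls_ep <- if (nrow(ep)) ep[drug_class == cls] else ep
    if (nrow(cls_ep)) {
      act <- cls_ep[iv, on = .(patient_id, start <= start, end > start),
                    nomatch = NA, mult = "first", which = TRUE]
      iv[, (cls) := !is.na(act)]
    } else {
      iv[, (cls) := FALSE]
    }
  }
  iv[, state := therapy_state(aspirin, adp, vka)]
  iv[, c(.drug_classes) := NULL]
  # merge adjacent intervals with identical state
  iv[, grp := cumsum(c(1L, as.integer(state[-1L] != state[-.N] |
                                      start[-1L] != end[-.N]))),
     by = patient_id]
  out <- iv[, .(start = min(start), end = max(end), state = state[1L]),
            by = .(patient_id, grp)]
  out[, grp := NULL]
  out[]
}

#' Summarise therapy duration up to the first bleeding event
#'
#' For each patient, days spent in each therapy state between cohort entry
#' and the first bleeding event (or end of follow-up if none) are summed;
#' the summary across patients ever exposed to a state reports the number
#' of patients and median and interquartile range of days (linear
#' interpolation, quantile type 7).
#'
#' @param timeline `data.table` from [therapy_timeline()].
#' @param first_bleed optional data frame `patient_id`, `date` of the first
#'   bleeding event; follow-up is truncated there.
#' @return `data.table` with columns `state`, `n_patients`, `median_days`,
#'   `q1_days`, `q3_days`. States never held by any patient are omitted.
#' @export
duration_summary <- function(timeline, first_bleed = NULL) {
  tl <- data.table::as.data.table(timeline)
  if (!is.null(first_bleed)) {
    fb <- data.table::as.data.table(first_bleed)[, .(patient_id,
                                                     bleed = as.Date(date))]
    tl <- fb[tl, on = "patient_id"]
    tl[!is.na(bleed), end := pmin(end, bleed)]
    tl <- tl[end > start]
  }
  per <- tl[, .(days = sum(as.integer(end) - as.integer(start))),
            by = .(patient_id, state)][days > 0]
  per[, .(n_patients = .N,
          median_days = as.numeric(median(days)),
          q1_days = as.numeric(quantile(days, 0.25, type = 7)),
          q3_days = as.numeric(quantile(days, 0.75, type = 7))),
      by = state][]
}
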