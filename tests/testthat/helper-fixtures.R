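# Shared fixtures and independent oracles. The oracles are deliberately
# naive (loops, pairwise comparisons, day-by-day evaluation) so they stay
# independent of the vectorised implementation paths they check.

library(data.table)

base_day <- as.Date("2000-01-01")
d_ <- function(day) base_day + day

# --- tiny linked-EHR builder -------------------------------------------------
# pc / labs / deaths / procs are data.frames with a `day` column relative to
# base_day; hosp rows become one episode each (adm, dis, code, pos).
tiny_ehr <- function(n_patients = 1, pc = NULL, hosp = NULL, procs = NULL,
                     deaths = NULL, death_codes = NULL, labs = NULL,
                     rx = NULL) {
  pats <- data.table(patient_id = seq_len(n_patients), sex = "F",
                     birth_date = as.Date("1940-01-01"),
                     transfer_out_date = as.Date(NA))
  args <- list(patients = pats)
  if (!is.null(pc)) {
    pc <- as.data.table(pc)
    args$primary_care <- pc[, .(patient_id, date = d_(day), code)]
  }
  epi_n <- 0L
  epis <- dxs <- prs <- NULL
  if (!is.null(hosp)) {
    hosp <- as.data.table(hosp)
    hosp[, episode_id := seq_len(.N)]
    epi_n <- nrow(hosp)
    epis <- hosp[, .(episode_id, patient_id, admission_date = d_(adm),
                     discharge_date = d_(dis))]
    dxs <- hosp[!is.na(code), .(episode_id, patient_id, code,
                                position = as.integer(pos))]
  }
  if (!is.null(procs)) {
    procs <- as.data.table(procs)
    procs[, episode_id := epi_n + seq_len(.N)]
    pe <- procs[, .(episode_id, patient_id, admission_date = d_(day),
                    discharge_date = d_(day))]
    epis <- rbind(epis, pe)
    prs <- procs[, .(episode_id, patient_id, code, date = d_(day))]
  }
  if (!is.null(epis)) args$hospital_episodes <- epis
  if (!is.null(dxs) && nrow(dxs)) args$hospital_diagnoses <- dxs
  if (!is.null(prs)) args$hospital_procedures <- prs
  if (!is.null(deaths)) {
    deaths <- as.data.table(deaths)
    args$deaths <- deaths[, .(patient_id, date = d_(day))]
    if (!is.null(death_codes)) {
      dcd <- as.data.table(death_codes)
      if (!"role" %in% names(dcd)) dcd[, role := "underlying"]
      args$death_causes <- dcd[, .(patient_id, code, role)]
    }
  }
  if (!is.null(labs)) {
    labs <- as.data.table(labs)
    if (!"analyte" %in% names(labs)) labs[, analyte := "haemoglobin"]
    args$labs <- labs[, .(patient_id, date = d_(day), analyte, value)]
  }
  if (!is.null(rx)) {
    rx <- as.data.table(rx)
    args$prescriptions <- rx[, .(patient_id, date = d_(day), code)]
  }
  do.call(new_linked_ehr, args)
}

# --- synthetic bleeding-record tables (module-level interface) ---------------
make_records <- function(patient_id, day, source, site = "gastrointestinal",
                         pos = NA_integer_, len = NA_integer_) {
  n <- length(day)
  dt <- data.table(
    record_id = sprintf("t%03d", seq_len(n)),
    patient_id = rep_len(patient_id, n), date = d_(day),
    source = rep_len(source, n), site = rep_len(site, n),
    diagnosis_position = as.integer(rep_len(pos, n)),
    episode_length_days = as.integer(rep_len(len, n)),
    episode_id = NA_integer_)
  dt
}

# --- oracle: union-find grouping over pairwise date proximity ----------------
oracle_group <- function(patient_id, day, window = 30) {
  n <- length(day)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && patient_id[i] == patient_id[j] &&
        abs(day[i] - day[j]) <= window) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  vapply(seq_len(n), find, integer(1))
}

# --- oracle: naive per-event severity marking and classification -------------
# records: data.table(patient_id, day, source, site, pos, len)
# deaths:  data.table(patient_id, day); death_bleed: patients with a bleeding
# cause of death; tx: data.table(patient_id, day) hospital transfusions.
oracle_classify <- function(records, deaths = NULL, death_bleed = integer(),
                            tx = NULL, window = 30, fatal_window = 7,
                            long_stay = 14) {
  critical <- c("intracranial", "aortic_aneurysm_ruptured", "haemopericardium")
  grp <- oracle_group(records$patient_id, records$day, window)
  out <- list()
  for (g in unique(grp)) {
    rs <- records[grp == g]
    pid <- rs$patient_id[1]
    death_day <- if (!is.null(deaths)) deaths$day[deaths$patient_id == pid]
                 else numeric()
    fatal <- pid %in% death_bleed && any(rs$source == "death_registry")
    if (!fatal && length(death_day)) {
      for (i in seq_len(nrow(rs))) {
        if (rs$source[i] %in% c("primary_care", "hospital")) {
          lag <- death_day[1] - rs$day[i]
          if (lag >= 0 && lag <= fatal_window) fatal <- TRUE
        }
      }
    }
    if (any(rs$source == "death_registry")) fatal <- TRUE
    long_adm <- FALSE; crit <- FALSE; multi <- FALSE; txn <- FALSE
    for (i in seq_len(nrow(rs))) {
      r <- rs[i]
      if (!is.na(r$pos) && r$pos == 1 && !is.na(r$len) && r$len >= long_stay) {
        long_adm <- TRUE
      }
      if (r$site %in% critical) crit <- TRUE
      same_day <- records[patient_id == pid & day == r$day]
      if (length(unique(same_day$site)) >= 2) multi <- TRUE
      if (!is.null(tx)) {
        for (td in tx$day[tx$patient_id == pid]) {
          if (abs(td - r$day) <= 30) txn <- TRUE
        }
      }
    }
    ms <- long_adm || crit || multi || txn
    has_h <- any(rs$source == "hospital")
    has_p <- any(rs$source == "primary_care")
    cat_ <- if (fatal) "fatal"
      else if (has_h && ms) "hospitalised_ms"
      else if (!has_h && has_p && ms) "primary_care_ms"
      else if (has_h) "hospitalised"
      else if (has_p) "primary_care"
      else "fatal"
    out[[length(out) + 1L]] <- data.table(
      patient_id = pid, event_day = min(rs$day), category = cat_,
      n_records = nrow(rs))
  }
  rbindlist(out)[order(patient_id, event_day)]
}

# --- oracle: day-resolution therapy timeline ---------------------------------
oracle_state_by_day <- function(episodes, entry, end) {
  days <- seq(entry, end - 1L)
  st <- character(length(days))
  for (k in seq_along(days)) {
    dd <- days[k]
    a <- any(episodes$drug_class == "aspirin" & episodes$start <= dd &
               episodes$end > dd)
    p <- any(episodes$drug_class == "adp" & episodes$start <= dd &
               episodes$end > dd)
    v <- any(episodes$drug_class == "vka" & episodes$start <= dd &
               episodes$end > dd)
    st[k] <- if (v && a && p) "triple"
      else if (v && (a || p)) "vka_plus_one"
      else if (v) "vka_mono"
      else if (a && p) "dapt"
      else if (a) "aspirin_mono"
      else if (p) "adp_mono"
      else "none"
  }
  st
}

expand_timeline_days <- function(tl, entry, end) {
  days <- seq(entry, end - 1L)
  out <- rep(NA_character_, length(days))
  for (i in seq_len(nrow(tl))) {
    sel <- days >= tl$start[i] & days < tl$end[i]
    out[sel] <- tl$state[i]
  }
  out
}

# --- oracle: Cox partial likelihood on counting-process rows -----------------
# single numeric covariate x, no ties assumed
oracle_partial_loglik <- function(rows, beta) {
  ev <- rows[event == 1]
  ll <- 0
  for (i in seq_len(nrow(ev))) {
    t_i <- ev$stop[i]
    risk <- rows[start < t_i & stop >= t_i]
    ll <- ll + ev$x[i] * beta - log(sum(exp(risk$x * beta)))
  }
  ll
}

# Clopper-Pearson interval from beta quantiles (independent of binom.test)
oracle_cp_interval <- function(x, n, level = 0.95) {
  a <- (1 - level) / 2
  lo <- if (x == 0) 0 else qbeta(a, x, n - x + 1)
  hi <- if (x == n) 1 else qbeta(1 - a, x + 1, n - x)
  c(lo, hi)
}

# fast deterministic permutations of small vectors
perms <- function(n) {
  if (n == 1) return(matrix(1L))
  p <- perms(n - 1L)
  out <- NULL
  for (i in seq_len(n)) {
    out <- rbind(out, cbind(i, p + (p >= i)))
  }
  unname(out)
}
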