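#' Simulation configuration
#'
#' Builds and validates the configuration for the synthetic linked-EHR
#' generator. Defaults describe a cohort of older cardiovascular patients
#' followed 1997--2010: a mix of atrial fibrillation, myocardial
#' infarction, unstable angina and stable angina as index diseases; a
#' baseline bleeding hazard of 1.4e-4 per day (about a quarter of patients
#' bleed within five years); therapy-state hazard ratios rising from
#' monotherapy to triple therapy; and per-source capture probabilities
#' under which roughly 60% of bleeds are coded in primary care and 50% in
#' hospital admissions.
#'
#' @param n_patients number of patients.
#' @param seed integer seed; identical seed and configuration give
#'   identical output.
#' @param study_start,study_end study window (cohort entry is uniform over
#'   it; follow-up is administratively censored at `study_end`).
#' @param index_disease_mix probabilities over `af`, `mi`, `ua`, `sa`
#'   (must sum to 1).
#' @param age_mean_sd mean and SD of age at entry (years, truncated at 18).
#' @param female_fraction proportion female.
#' @param baseline_bleed_hazard bleeding hazard per day off therapy.
#' @param therapy_hazard_ratios named hazard ratios for the seven therapy
#'   states (reference `none` = 1).
#' @param mortality_hazard all-cause death hazard per day.
#' @param hr_death_given_bleed_class mortality hazard multipliers applied
#'   from the first bleed, by prognostic class `I`, `II`, `III`.
#' @param athero_hazard hazard per day of an atherothrombotic event
#'   (ischaemic stroke or MI).
#' @param hr_athero_given_bleed_class multipliers as above for the
#'   atherothrombotic hazard.
#' @param hr_recurrent_bleed bleeding hazard multiplier after a first
#'   bleed.
#' @param p_record_in_source capture probabilities for a true bleed:
#'   `primary_care` (a coded primary-care record), `hospital` (a bleeding
#'   diagnosis, given hospital attendance), `death_registry` (a bleeding
#'   cause of death; such bleeds are fatal).
#' @param p_hospital_attend probability a bleed leads to a hospital
#'   episode at all.
#' @param p_uncoded_bleed probability a bleed leaves only indirect
#'   evidence (transfusion / anaemia / haemoglobin / endoscopy / surgery).
#' @param uncoded_route_mix distribution of indirect-evidence patterns
#'   over the four inference routes.
#' @param record_jitter_days records of one bleed are dated up to this
#'   many days after the true bleed day (0 = exact dating).
#' @param prescription_interval_days named `mean`, `sd` of the gap between
#'   consecutive prescription issues (days; clamped well below the 90-day
#'   continuity rule).
#' @param prescription_gap_days episode continuity gap used when emitting
#'   issues (matches the analysis-side gap rule).
#' @param p_drug_user named probabilities that a patient ever receives
#'   aspirin / an ADP-receptor inhibitor / a VKA.
#' @param p_transfer_out probability of transfer out of the practice
#'   during follow-up.
#' @param p_false_bleed_code probability a background (non-bleed) hospital
#'   episode is miscoded with a bleeding diagnosis.
#' @param background_admission_rate rate per day of non-bleed hospital
#'   admissions.
#' @param min_bleed_gap_days minimum separation between successive true
#'   bleeds of one patient (distinct clinical events).
#' @param max_bleeds cap on true bleeds per patient.
#' @param beta_age_bleed,beta_female_bleed log-hazard effects on bleeding
#'   (age centred at 70 years; female indicator).
#' @param beta_age_death,beta_female_death log-hazard effects on death.
#' @param site_mix distribution of anatomical bleeding sites.
#' @param p_primary_position probability a coded hospital bleed sits in
#'   diagnosis position 1.
#' @param mean_stay_days mean hospital stay (days, exponential).
#' @param p_transfusion_given_admitted probability of a transfusion
#'   procedure during a bleed admission.
#' @param p_endoscopy_given_gi probability of endoscopy for an admitted
#'   gastrointestinal bleed.
#' @param hb_mean_sd,hb_low_mean_sd haemoglobin value distributions (g/dL)
#'   for routine tests and for uncoded-bleed tests.
#' @param lab_rate_per_year rate of routine haemoglobin tests (SBP and
#'   creatinine are drawn at 0.8 times this rate).
#' @param comorbidity_prevalence named prevalences of baseline
#'   comorbidities (recorded before entry); `liver` feeds only the
#'   inference exclusion.
#' @return A validated `sim_config` object (a named list).
#' @export
sim_config <- function(
    n_patients = 1000,
    seed = 1L,
    study_start = as.Date("1997-01-01"),
    study_end = as.Date("2010-03-31"),
    index_disease_mix = c(af = 0.210, mi = 0.194, ua = 0.074, sa = 0.522),
    age_mean_sd = c(71.5, 13),
    female_fraction = 0.485,
    baseline_bleed_hazard = 1.4e-4,
    therapy_hazard_ratios = c(none = 1, aspirin_mono = 1.3, adp_mono = 1.4,
                              dapt = 2.0, vka_mono = 1.7, vka_plus_one = 2.9,
                              triple = 3.4),
    mortality_hazard = 8e-5,
    hr_death_given_bleed_class = c(I = 3.0, II = 2.0, III = 1.2),
    athero_hazard = 2.5e-5,
    hr_athero_given_bleed_class = c(I = 2.5, II = 1.6, III = 1.1),
    hr_recurrent_bleed = 1.5,
    p_record_in_source = c(primary_care = 0.594, hospital = 0.71,
                           death_registry = 0.038),
    p_hospital_attend = 0.707,
    p_uncoded_bleed = 0.04,
    uncoded_route_mix = c(route1 = 0.46, route2 = 0.32, route3 = 0.17,
                          route4 = 0.05),
    record_jitter_days = 3,
    prescription_interval_days = c(mean = 30, sd = 7),
    prescription_gap_days = 90,
    p_drug_user = c(aspirin = 0.60, adp = 0.12, vka = 0.15),
    p_transfer_out = 0.12,
    p_false_bleed_code = 0.005,
    background_admission_rate = 0.08 / 365.25,
    min_bleed_gap_days = 31,
    max_bleeds = 5,
    beta_age_bleed = 0.02, beta_female_bleed = -0.05,
    beta_age_death = 0.08, beta_female_death = -0.15,
    site_mix = c(gastrointestinal = 0.55, intracranial = 0.08,
                 aortic_aneurysm_ruptured = 0.01, haemopericardium = 0.02,
                 other_site = 0.34),
    p_primary_position = 0.7,
    mean_stay_days = 6,
    p_transfusion_given_admitted = 0.25,
    p_endoscopy_given_gi = 0.35,
    hb_mean_sd = c(13.5, 1.8),
    hb_low_mean_sd = c(8.6, 0.8),
    lab_rate_per_year = 0.5,
    comorbidity_prevalence = c(diabetes = 0.12, stroke = 0.06, pad = 0.09,
                               cancer = 0.13, renal = 0.07,
                               peptic_ulcer = 0.07,
                               bleeding_diathesis = 0.01,
                               chronic_anaemia = 0.13, liver = 0.03)) {
  cfg <- as.list(environment())
  cfg$study_start <- as.Date(study_start)
  cfg$study_end <- as.Date(study_end)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_patients >= 0, cfg$study_end > cfg$study_start)
  if (abs(sum(cfg$index_disease_mix) - 1) > 1e-9) {
    stop("index_disease_mix must sum to 1")
  }
  probs <- c(cfg$female_fraction, cfg$p_record_in_source,
             cfg$p_hospital_attend, cfg$p_uncoded_bleed, cfg$p_drug_user,
             cfg$p_transfer_out, cfg$p_false_bleed_code,
             cfg$p_primary_position, cfg$p_transfusion_given_admitted,
             cfg$p_endoscopy_given_gi, cfg$uncoded_route_mix)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  hz <- c(cfg$baseline_bleed_hazard, cfg$mortality_hazard, cfg$athero_hazard,
          cfg$therapy_hazard_ratios, cfg$hr_death_given_bleed_class,
          cfg$hr_athero_given_bleed_class, cfg$hr_recurrent_bleed)
  if (any(hz <= 0)) stop("hazards and hazard ratios must be positive")
  if (!all(.therapy_states %in% names(cfg$therapy_hazard_ratios))) {
    stop("therapy_hazard_ratios must name all seven states")
  }
  invisible(cfg)
}

# piecewise-exponential first event after t_cur, over per-patient constant-
# hazard segments [start, end) with column 'rate'; returns patient_id, t
.piecewise_first_event <- function(segs, active, rate_mult = 1) {
  cand <- segs[active, on = "patient_id", allow.cartesian = TRUE,
               nomatch = NULL]
  cand <- cand[end > t_cur]
  if (!nrow(cand)) return(data.table(patient_id = integer(), t = numeric()))
  cand[, s := pmax(start, t_cur)]
  data.table::setorder(cand, patient_id, s)
  cand[, t := s + rexp(.N, rate * rate_mult)]
  hits <- cand[t < end]
  if (!nrow(hits)) return(data.table(patient_id = integer(), t = numeric()))
  hits[, .SD[1L], by = patient_id][, .(patient_id, t)]
}

#' Simulate a linked EHR with known ground truth
#'
#' Generates the four linked sources for `n_patients` with a fully known
#' event history. Bleeding and death times are drawn from piecewise
#' exponential waiting times: the bleeding hazard multiplies the baseline
#' by the hazard ratio of the current therapy state (exposure is
#' piecewise-constant, reconstructed identically by the analysis-side gap
#' rule because issue streams are emitted with the same continuity
#' parameter), and the mortality and atherothrombotic hazards are
#' multiplied from the first bleed by class-specific ratios. Each true
#' bleed materialises as coded records per source-capture probabilities,
#' or, with probability `p_uncoded_bleed`, as indirect evidence only.
#'
#' @param config a [sim_config()] object.
#' @param codelist codelist supplying the code vocabulary (defaults to the
#'   bundled illustrative list).
#' @return A `linked_ehr` with a `ground_truth` table (one row per true
#'   bleed: date, site, therapy state at the bleed, capture pattern,
#'   intended category and prognostic class, `observed` flag, linked
#'   hospital episode id).
#' @export
simulate_ehr <- function(config = sim_config(), codelist = default_codelist()) {
  validate_sim_config(config)
  cfg <- config
  set.seed(cfg$seed)
  n <- cfg$n_patients
  if (n == 0L) return(new_linked_ehr(config = cfg))

  pick <- function(category, system, k, site = NULL) {
    pool <- codes_for(codelist, category, system = system, site = site)
    if (!length(pool)) stop("codelist lacks codes for ", category)
    pool[sample.int(length(pool), k, replace = TRUE)]
  }
  d0 <- as.integer(cfg$study_start)
  d1 <- as.integer(cfg$study_end)

  ## -- patients ------------------------------------------------------------
  pat <- data.table(
    patient_id = seq_len(n),
    disease = sample(names(cfg$index_disease_mix), n, TRUE,
                     prob = cfg$index_disease_mix),
    age = pmax(18, rnorm(n, cfg$age_mean_sd[1], cfg$age_mean_sd[2])),
    female = runif(n) < cfg$female_fraction)
  pat[, entry := d0 + floor(runif(n) * (d1 - d0 - 30L))]
  pat[, birth := entry - as.integer(round(age * 365.25))]
  has_transfer <- runif(n) < cfg$p_transfer_out
  t_transfer <- pat$entry + pmax(30, round(rexp(n, 1 / (4 * 365.25))))
  pat[, transfer := data.table::fifelse(has_transfer & t_transfer < d1,
                                        t_transfer, NA_integer_)]
  pat[, admin_end := pmin(data.table::fifelse(is.na(transfer), d1, transfer),
                          d1)]
  pat[, admin_end := pmax(admin_end, entry + 1L)]

  ## -- prescriptions and true exposure episodes ----------------------------
  rx_int <- cfg$prescription_interval_days
  gap <- cfg$prescription_gap_days
  ep_list <- list()
  for (cls in .drug_classes) {
    users <- pat[runif(n) < cfg$p_drug_user[[cls]]]
    if (!nrow(users)) next
    k_ep <- 1L + rbinom(nrow(users), 1L, 0.4)
    ep <- users[rep(seq_len(nrow(users)), k_ep),
                .(patient_id, entry, admin_end)]
    ep[, drug_class := cls]
    fu_len <- pmax(1L, ep$admin_end - ep$entry)
    ep[, start := entry + floor(runif(.N) * pmax(1, fu_len - 60L))]
    ep[, dur := pmax(30L, as.integer(round(rlnorm(.N, log(300), 0.9))))]
    ep_list[[cls]] <- ep
  }
  if (length(ep_list)) {
    eps <- data.table::rbindlist(ep_list)
    eps[, ep_id := .I]
    # issue stream: first issue at start, then gaps well under the 90-day rule
    k_iss <- pmax(1L, as.integer(round(eps$dur / rx_int[["mean"]])))
    iss <- eps[rep(seq_len(nrow(eps)), k_iss),
               .(ep_id, patient_id, drug_class, start)]
    iss[, gap_draw := pmax(7, pmin(gap - 10,
                                   round(rnorm(.N, rx_int[["mean"]],
                                               rx_int[["sd"]]))))]
    iss[, first := seq_len(.N) == 1L, by = ep_id]
    iss[first == TRUE, gap_draw := 0]
    iss[, date := start + cumsum(gap_draw), by = ep_id]
    # truth episode = issue span + trailing coverage, as the gap rule sees it
    truth_ep <- iss[, .(patient_id = patient_id[1L],
                        drug_class = drug_class[1L],
                        start = min(date), end = max(date) + gap), by = ep_id]
    # enforce separation between same-class episodes of one patient
    data.table::setorder(truth_ep, patient_id, drug_class, start)
    truth_ep[, keep := {
      k <- logical(.N); last_end <- -Inf
      for (i in seq_len(.N)) {
        if (start[i] > last_end + gap + 5) { k[i] <- TRUE; last_end <- end[i] }
      }
      k
    }, by = .(patient_id, drug_class)]
    truth_ep <- truth_ep[keep == TRUE][, keep := NULL]
    iss <- iss[ep_id %in% truth_ep$ep_id]
  } else {
    truth_ep <- data.table(ep_id = integer(), patient_id = integer(),
                           drug_class = character(), start = integer(),
                           end = integer())
    iss <- data.table(ep_id = integer(), patient_id = integer(),
                      drug_class = character(), date = integer())
  }

  fu <- pat[, .(patient_id, entry = as.Date(entry, origin = "1970-01-01"),
                end = as.Date(admin_end, origin = "1970-01-01"))]
  tl <- therapy_timeline(
    truth_ep[, .(patient_id, drug_class,
                 start = as.Date(start, origin = "1970-01-01"),
                 end = as.Date(end, origin = "1970-01-01"))], fu)

  ## -- bleeding events (piecewise exponential over therapy segments) -------
  segs <- tl[, .(patient_id, start = as.integer(start), end = as.integer(end),
                 state)]
  segs <- pat[, .(patient_id, age, female)][segs, on = "patient_id"]
  segs[, rate := cfg$baseline_bleed_hazard *
         cfg$therapy_hazard_ratios[state] *
         exp(cfg$beta_age_bleed * (age - 70) +
               cfg$beta_female_bleed * female)]
  active <- pat[, .(patient_id, t_cur = entry + 0.0)]
  bleed_rounds <- list()
  for (r in seq_len(cfg$max_bleeds)) {
    mult <- if (r == 1L) 1 else cfg$hr_recurrent_bleed
    hit <- .piecewise_first_event(segs, active, mult)
    if (!nrow(hit)) break
    bleed_rounds[[r]] <- hit
    active <- hit[, .(patient_id, t_cur = floor(t) + cfg$min_bleed_gap_days)]
  }
  bl <- data.table::rbindlist(bleed_rounds)
  if (nrow(bl)) {
    bl[, day := as.integer(floor(t))][, t := NULL]
    bl <- pat[, .(patient_id, entry, admin_end)][bl, on = "patient_id"]
    bl <- bl[day >= entry & day < admin_end]
    data.table::setorder(bl, patient_id, day)
    # therapy state at the bleed
    st <- segs[bl, on = .(patient_id, start <= day, end > day),
               mult = "first", x.state]
    bl[, state := st]
    nb <- nrow(bl)
    bl[, site := sample(names(cfg$site_mix), nb, TRUE, prob = cfg$site_mix)]
    bl[, uncoded := runif(nb) < cfg$p_uncoded_bleed]
    bl[, route := data.table::fifelse(
      uncoded, sample(names(cfg$uncoded_route_mix), nb, TRUE,
                      prob = cfg$uncoded_route_mix), NA_character_)]
    bl[, cap_pc := !uncoded & runif(nb) < cfg$p_record_in_source[["primary_care"]]]
    bl[, attend := !uncoded & runif(nb) < cfg$p_hospital_attend]
    bl[, cap_hosp := attend & runif(nb) < cfg$p_record_in_source[["hospital"]]]
    bl[, cap_dr := !uncoded & runif(nb) < cfg$p_record_in_source[["death_registry"]]]
    j <- cfg$record_jitter_days
    bl[, pc_day := day + sample(0:max(0L, j), nb, TRUE)]
    bl[, adm_day := day + sample(0:max(0L, j), nb, TRUE)]
    bl[, stay := as.integer(round(rexp(nb, 1 / cfg$mean_stay_days)))]
    bl[, position := data.table::fifelse(
      runif(nb) < cfg$p_primary_position, 1L, 1L + sample(1:3, nb, TRUE))]
    bl[, transfusion := attend & runif(nb) < cfg$p_transfusion_given_admitted]
    bl[, endoscopy := attend & site == "gastrointestinal" &
         runif(nb) < cfg$p_endoscopy_given_gi]
    bl[, fatal_day := data.table::fifelse(
      cap_dr, day + sample(0:7, nb, TRUE), NA_integer_)]
    bl[!is.na(fatal_day) & fatal_day > admin_end, `:=`(
      cap_dr = FALSE, fatal_day = NA_integer_)]
    # uncoded bleeds need their evidence episode
    bl[uncoded == TRUE, `:=`(attend = route %in% c("route1", "route2",
                                                   "route3", "route4"),
                             adm_day = day, stay = pmax(2L, pmin(stay, 8L)))]
  } else {
    bl <- data.table(patient_id = integer(), entry = integer(),
                     admin_end = integer(), day = integer(),
                     state = character(), site = character(),
                     uncoded = logical(), route = character(),
                     cap_pc = logical(), attend = logical(),
                     cap_hosp = logical(), cap_dr = logical(),
                     pc_day = integer(), adm_day = integer(),
                     stay = integer(), position = integer(),
                     transfusion = logical(), endoscopy = logical(),
                     fatal_day = integer())
  }

  ## -- death and atherothrombotic events ------------------------------------
  # attribute-based severity class of the first bleed drives later hazards
  class_attr <- function(b) {
    markers <- b$site %in% .critical_sites |
      (b$attend & !b$uncoded & b$transfusion) |
      (b$attend & !b$uncoded & b$position == 1L & b$stay >= 14L)
    data.table::fcase(b$attend & !b$uncoded & markers, "I",
                      (b$attend & !b$uncoded) | markers | b$uncoded, "II",
                      default = "III")
  }
  first_bl <- if (nrow(bl)) bl[, .SD[1L], by = patient_id] else bl
  pat2 <- data.table::copy(pat)
  if (nrow(first_bl)) {
    first_bl[, cls1 := class_attr(first_bl)]
    pat2 <- first_bl[, .(patient_id, t_b1 = day, cls1)][pat2, on = "patient_id"]
  } else {
    pat2[, `:=`(t_b1 = NA_integer_, cls1 = NA_character_)]
  }
  two_phase_event <- function(base_rate, mult_by_class) {
    rate0 <- base_rate * exp(cfg$beta_age_death * (pat2$age - 70) +
                               cfg$beta_female_death * pat2$female)
    e1 <- pat2$entry + rexp(n, rate0)
    split <- data.table::fifelse(is.na(pat2$t_b1), Inf, as.numeric(pat2$t_b1))
    mult <- data.table::fifelse(is.na(pat2$cls1), 1,
                                mult_by_class[pat2$cls1])
    t <- data.table::fifelse(e1 < split, e1,
                             split + rexp(n, rate0 * mult))
    t
  }
  t_death_nat <- two_phase_event(cfg$mortality_hazard,
                                 cfg$hr_death_given_bleed_class)
  t_athero <- two_phase_event(cfg$athero_hazard,
                              cfg$hr_athero_given_bleed_class)
  t_fatal <- rep(Inf, n)
  if (nrow(bl) && any(!is.na(bl$fatal_day))) {
    fb <- bl[!is.na(fatal_day)][, .(fd = min(fatal_day)), by = patient_id]
    t_fatal[match(fb$patient_id, pat2$patient_id)] <- fb$fd
  }
  death_cont <- pmin(floor(t_death_nat), t_fatal)
  death_day <- rep(NA_integer_, n)
  ok <- is.finite(death_cont) & death_cont <= pat2$admin_end
  death_day[ok] <- as.integer(death_cont[ok])
  fatal_death <- !is.na(death_day) & is.finite(t_fatal) &
    death_day == t_fatal
  pat2[, death := death_day]
  pat2[, end_final := pmin(admin_end,
                           data.table::fifelse(is.na(death), d1 + 1L, death))]
  has_athero <- is.finite(t_athero) &
    floor(t_athero) < pat2$end_final
  athero_day <- rep(NA_integer_, n)
  athero_day[has_athero] <- as.integer(floor(t_athero[has_athero]))
  athero <- data.table(patient_id = pat2$patient_id[has_athero],
                       day = athero_day[has_athero])
  if (nrow(athero)) {
    athero[, type := sample(c("stroke", "mi"), .N, TRUE, prob = c(0.55, 0.45))]
  }

  # truncate bleeds at death; cap record days at death
  if (nrow(bl)) {
    bl <- pat2[, .(patient_id, death)][bl, on = "patient_id"]
    bl <- bl[is.na(death) | day <= death]
    bl[!is.na(death), `:=`(pc_day = pmin(pc_day, death),
                           adm_day = pmin(adm_day, death))]
    bl[, fatal := !is.na(death) & cap_dr & death == fatal_day]
  }

  ## -- materialise tables ---------------------------------------------------
  pc_rows <- list()
  lab_rows <- list()
  epi_rows <- list()
  dx_rows <- list()
  pr_rows <- list()
  next_epi <- 1L
  new_epi_ids <- function(k) {
    ids <- seq.int(next_epi, length.out = k)
    next_epi <<- next_epi + k
    ids
  }
  DT <- function(pid, day, code) {
    data.table(patient_id = pid, date = as.Date(day, origin = "1970-01-01"),
               code = code)
  }

  # index diagnoses (codes drawn per disease group)
  pc_rows$index <- pat[, .(patient_id, day = entry,
                           code = pick(paste0("cvd_", disease[1L]),
                                       "readlike", .N)),
                       by = disease][, DT(patient_id, day, code)]
  idx_hosp <- pat[disease %in% c("mi", "ua")][runif(.N) < 0.8]
  if (nrow(idx_hosp)) {
    idx_hosp[, episode_id := new_epi_ids(.N)]
    stay <- pmax(1L, as.integer(round(rexp(nrow(idx_hosp), 1 / 7))))
    epi_rows$index <- data.table(episode_id = idx_hosp$episode_id,
                                 patient_id = idx_hosp$patient_id,
                                 adm = idx_hosp$entry,
                                 dis = idx_hosp$entry + stay)
    dx_rows$index <- idx_hosp[, .(episode_id, patient_id,
                                  code = pick(paste0("cvd_", disease[1L]),
                                              "icd10", .N),
                                  position = 1L), by = disease][
      , .(episode_id, patient_id, code, position)]
  }

  # baseline comorbidities (before entry)
  como_cat <- c(diabetes = "comorbidity_diabetes",
                stroke = "comorbidity_stroke", pad = "comorbidity_pad",
                cancer = "cancer", renal = "renal_disease",
                peptic_ulcer = "comorbidity_peptic_ulcer",
                bleeding_diathesis = "comorbidity_bleeding_diathesis",
                chronic_anaemia = "comorbidity_chronic_anaemia",
                liver = "liver_disease")
  for (nm in names(como_cat)) {
    hasit <- which(runif(n) < cfg$comorbidity_prevalence[[nm]])
    if (!length(hasit)) next
    day <- pat$entry[hasit] - as.integer(round(runif(length(hasit), 30, 1500)))
    pc_rows[[paste0("como_", nm)]] <-
      DT(pat$patient_id[hasit], day, pick(como_cat[[nm]], "readlike",
                                          length(hasit)))
  }

  # routine labs over [entry - 2y, end_final)
  lab_span <- pmax(30L, (pat2$end_final - pat2$entry) + 730L)
  routine_lab <- function(analyte, rate_per_year, mean, sd) {
    k <- rpois(n, rate_per_year * lab_span / 365.25)
    idx <- rep(seq_len(n), k)
    if (!length(idx)) return(NULL)
    day <- pat2$entry[idx] - 730L +
      as.integer(floor(runif(length(idx)) * lab_span[idx]))
    data.table(patient_id = pat2$patient_id[idx],
               date = as.Date(day, origin = "1970-01-01"), analyte = analyte,
               value = round(rnorm(length(idx), mean, sd), 1))
  }
  lab_rows$hb <- routine_lab("haemoglobin", cfg$lab_rate_per_year,
                             cfg$hb_mean_sd[1], cfg$hb_mean_sd[2])
  lab_rows$sbp <- routine_lab("sbp", 0.8 * cfg$lab_rate_per_year, 141, 21)
  lab_rows$cr <- routine_lab("creatinine", 0.8 * cfg$lab_rate_per_year,
                             105, 52)

  # coded bleed records
  if (nrow(bl)) {
    bl[, bleed_id := .I]
    cap_pc_rows <- bl[cap_pc == TRUE]
    if (nrow(cap_pc_rows)) {
      pc_rows$bleed <- cap_pc_rows[, .(patient_id, day = pc_day,
                                       code = pick("bleeding", "readlike",
                                                   .N, site = site[1L])),
                                   by = site][, DT(patient_id, day, code)]
    }
    adm_rows <- bl[attend == TRUE & uncoded == FALSE]
    if (nrow(adm_rows)) {
      eid <- new_epi_ids(nrow(adm_rows))
      adm_rows[, episode_id := eid]
      dis <- adm_rows$adm_day + adm_rows$stay
      dis <- data.table::fifelse(!is.na(adm_rows$death),
                                 pmin(dis, adm_rows$death), dis)
      dis <- pmax(dis, adm_rows$adm_day)
      epi_rows$bleed <- data.table(episode_id = eid,
                                   patient_id = adm_rows$patient_id,
                                   adm = adm_rows$adm_day, dis = dis)
      coded <- adm_rows[cap_hosp == TRUE]
      if (nrow(coded)) {
        dx_rows$bleed <- coded[, .(episode_id, patient_id,
                                   code = pick("bleeding", "icd10", .N,
                                               site = site[1L]),
                                   position = position), by = site][
          , .(episode_id, patient_id, code, position)]
      }
      uncoded_adm <- adm_rows[cap_hosp == FALSE]
      if (nrow(uncoded_adm)) {
        dx_rows$bleed_miss <- data.table(
          episode_id = uncoded_adm$episode_id,
          patient_id = uncoded_adm$patient_id,
          code = pick("comorbidity_chronic_anaemia", "icd10",
                      nrow(uncoded_adm)),
          position = 1L)
      }
      tx <- adm_rows[transfusion == TRUE]
      if (nrow(tx)) {
        pr_rows$tx <- data.table(episode_id = tx$episode_id,
                                 patient_id = tx$patient_id,
                                 code = pick("transfusion", "opcs4", nrow(tx)),
                                 day = tx$adm_day +
                                   sample(0:3, nrow(tx), TRUE))
      }
      en <- adm_rows[endoscopy == TRUE]
      if (nrow(en)) {
        pr_rows$endo <- data.table(episode_id = en$episode_id,
                                   patient_id = en$patient_id,
                                   code = pick("endoscopy", "opcs4", nrow(en)),
                                   day = en$adm_day +
                                     sample(0:3, nrow(en), TRUE))
      }
      bl[adm_rows, on = "bleed_id", episode_id := i.episode_id]
    }

    # uncoded bleeds: indirect evidence per route
    un <- bl[uncoded == TRUE]
    if (nrow(un)) {
      eid <- new_epi_ids(nrow(un))
      un[, episode_id := eid]
      bl[un, on = "bleed_id", episode_id := i.episode_id]
      dis <- un$adm_day + un$stay
      dis <- data.table::fifelse(!is.na(un$death), pmin(dis, un$death), dis)
      epi_rows$uncoded <- data.table(episode_id = eid,
                                     patient_id = un$patient_id,
                                     adm = un$adm_day,
                                     dis = pmax(dis, un$adm_day))
      # non-bleeding admission diagnosis
      dx_rows$uncoded <- data.table(
        episode_id = eid, patient_id = un$patient_id,
        code = data.table::fifelse(un$route %in% c("route1", "route3"),
                                   pick("iron_deficiency_anaemia", "icd10",
                                        nrow(un)),
                                   pick("comorbidity_chronic_anaemia",
                                        "icd10", nrow(un))),
        position = 1L)
      ucap <- function(d) {
        dd <- data.table::fifelse(!is.na(un$death), pmin(d, un$death), d)
        pmax(dd, un$day)
      }
      r14 <- un[route %in% c("route1", "route4")]
      if (nrow(r14)) {
        pr_rows$un_tx <- data.table(episode_id = r14$episode_id,
                                    patient_id = r14$patient_id,
                                    code = pick("transfusion", "opcs4",
                                                nrow(r14)),
                                    day = r14$adm_day +
                                      sample(0:3, nrow(r14), TRUE))
      }
      r13 <- un[route %in% c("route1", "route3")]
      if (nrow(r13)) {
        pc_rows$un_ida <- DT(r13$patient_id,
                             pmin(r13$day + sample(0:10, nrow(r13), TRUE),
                                  data.table::fifelse(is.na(r13$death),
                                                      .Machine$integer.max,
                                                      r13$death)),
                             pick("iron_deficiency_anaemia", "readlike",
                                  nrow(r13)))
      }
      r2 <- un[route == "route2"]
      if (nrow(r2)) {
        pr_rows$un_surg <- data.table(
          episode_id = r2$episode_id, patient_id = r2$patient_id,
          code = pick(c("surgical_arrest_bleeding", "haematoma_evacuation"),
                      "opcs4", nrow(r2)),
          day = r2$adm_day + sample(0:2, nrow(r2), TRUE))
      }
      r34 <- un[route %in% c("route3", "route4")]
      if (nrow(r34)) {
        hb_day <- pmin(r34$day + sample(0:5, nrow(r34), TRUE),
                       data.table::fifelse(is.na(r34$death),
                                           .Machine$integer.max, r34$death))
        lab_rows$un_hb <- data.table(
          patient_id = r34$patient_id,
          date = as.Date(hb_day, origin = "1970-01-01"),
          analyte = "haemoglobin",
          value = round(pmin(rnorm(nrow(r34), cfg$hb_low_mean_sd[1],
                                   cfg$hb_low_mean_sd[2]), 9.9), 1))
        pr_rows$un_endo <- data.table(
          episode_id = r34$episode_id, patient_id = r34$patient_id,
          code = pick("endoscopy", "opcs4", nrow(r34)),
          day = r34$adm_day + sample(0:3, nrow(r34), TRUE))
      }
    }
  }

  # atherothrombotic events: primary-care record, sometimes an admission
  if (nrow(athero)) {
    pc_rows$athero <- athero[, .(patient_id, day,
                                 code = pick(data.table::fifelse(
                                   type[1L] == "stroke", "comorbidity_stroke",
                                   "cvd_mi"), "readlike", .N)),
                             by = type][, DT(patient_id, day, code)]
  }

  # background (non-bleed) admissions
  bg_k <- rpois(n, cfg$background_admission_rate *
                  pmax(0L, pat2$end_final - pat2$entry))
  bg_idx <- rep(seq_len(n), bg_k)
  if (length(bg_idx)) {
    bg_day <- pat2$entry[bg_idx] +
      as.integer(floor(runif(length(bg_idx)) *
                         pmax(1L, pat2$end_final[bg_idx] -
                                pat2$entry[bg_idx])))
    eid <- new_epi_ids(length(bg_idx))
    bg_stay <- as.integer(round(rexp(length(bg_idx), 1 / 3)))
    bg_dis <- pmin(bg_day + bg_stay,
                   data.table::fifelse(is.na(pat2$death[bg_idx]),
                                       .Machine$integer.max,
                                       pat2$death[bg_idx]))
    epi_rows$bg <- data.table(episode_id = eid,
                              patient_id = pat2$patient_id[bg_idx],
                              adm = bg_day, dis = pmax(bg_dis, bg_day))
    bg_pool <- c("J44", "R99", "E11", "K27", "D64")
    bg_code <- bg_pool[sample.int(length(bg_pool), length(bg_idx), TRUE)]
    mis <- runif(length(bg_idx)) < cfg$p_false_bleed_code
    if (any(mis)) bg_code[mis] <- pick("bleeding", "icd10", sum(mis))
    dx_rows$bg <- data.table(episode_id = eid,
                             patient_id = pat2$patient_id[bg_idx],
                             code = bg_code, position = 1L)
  }

  ## -- deaths ---------------------------------------------------------------
  dead <- pat2[!is.na(death)]
  deaths <- dc <- NULL
  if (nrow(dead)) {
    deaths <- data.table(patient_id = dead$patient_id,
                         date = as.Date(dead$death, origin = "1970-01-01"))
    fat <- fatal_death[!is.na(pat2$death)]
    # underlying cause: bleeding site code for fatal bleeds, else CV or other
    und_code <- character(nrow(dead))
    if (any(fat)) {
      fb_site <- bl[fatal == TRUE, .(site = site[1L]), by = patient_id]
      m <- fb_site[dead[fat, .(patient_id)], on = "patient_id"]
      m[is.na(site), site := "gastrointestinal"]
      m[, code := pick("bleeding", "icd10", .N, site = site[1L]), by = site]
      und_code[fat] <- m$code
    }
    cv <- !fat & runif(nrow(dead)) < 0.45
    und_code[cv] <- sample(c("I21", "I64"), sum(cv), TRUE)
    oth <- !fat & !cv
    und_code[oth] <- sample(c("C34", "J44", "R99"), sum(oth), TRUE)
    dc <- data.table(patient_id = dead$patient_id, code = und_code,
                     role = "underlying")
    ctr <- runif(nrow(dead)) < 0.2
    if (any(ctr)) {
      dc <- rbind(dc, data.table(patient_id = dead$patient_id[ctr],
                                 code = sample(c("E11", "N18", "J44"),
                                               sum(ctr), TRUE),
                                 role = "contributory"))
    }
  }

  ## -- assemble, truncate at death ------------------------------------------
  rbind_or <- function(rows, proto) {
    out <- data.table::rbindlist(rows, use.names = TRUE)
    if (nrow(out)) out else proto
  }
  pc <- rbind_or(pc_rows, data.table(patient_id = integer(),
                                     date = as.Date(character()),
                                     code = character()))
  labs <- rbind_or(lab_rows, data.table(patient_id = integer(),
                                        date = as.Date(character()),
                                        analyte = character(),
                                        value = numeric()))
  epis <- rbind_or(epi_rows, data.table(episode_id = integer(),
                                        patient_id = integer(),
                                        adm = integer(), dis = integer()))
  dxs <- rbind_or(dx_rows, data.table(episode_id = integer(),
                                      patient_id = integer(),
                                      code = character(),
                                      position = integer()))
  prs <- rbind_or(pr_rows, data.table(episode_id = integer(),
                                      patient_id = integer(),
                                      code = character(), day = integer()))
  rx <- if (nrow(iss)) {
    iss[, .(patient_id, date = as.Date(date, origin = "1970-01-01"),
            code = pick(paste0("antithrombotic_", drug_class[1L]),
                        "readlike", .N)), by = drug_class][
      , .(patient_id, date, code)]
  } else {
    data.table(patient_id = integer(), date = as.Date(character()),
               code = character())
  }

  death_lu <- pat2[, .(patient_id, death)]
  trunc_tbl <- function(x) {
    if (is.null(x) || !nrow(x)) return(x)
    x <- death_lu[x, on = "patient_id"]
    x <- x[is.na(death) | as.integer(date) <= death]
    x[, death := NULL]
    x[]
  }
  pc <- trunc_tbl(pc)
  labs <- trunc_tbl(labs)
  rx <- trunc_tbl(rx)
  if (nrow(epis)) {
    epis <- death_lu[epis, on = "patient_id"]
    epis <- epis[is.na(death) | adm <= death]
    epis[!is.na(death), dis := pmin(dis, death)]
    epis[, death := NULL]
    dxs <- dxs[episode_id %in% epis$episode_id]
    prs <- prs[episode_id %in% epis$episode_id]
    prs <- death_lu[prs, on = "patient_id"]
    prs[!is.na(death), day := pmin(day, death)]
    prs[, death := NULL]
  }

  ## -- ground truth ----------------------------------------------------------
  gt <- .empty_ehr_tables()$ground_truth
  if (nrow(bl)) {
    if (!"episode_id" %in% names(bl)) bl[, episode_id := NA_integer_]
    blocked <- unique(bl[cap_pc | cap_hosp, patient_id])
    excl_pc <- pc[code %in% codes_for(codelist,
                                      c("cancer", "liver_disease",
                                        "renal_disease"),
                                      system = "readlike")]
    excl_by_pat <- split(as.integer(excl_pc$date), excl_pc$patient_id)
    has_excl <- function(pid, anchor) {
      dts <- excl_by_pat[[as.character(pid)]]
      !is.null(dts) && any(dts >= anchor - 365L & dts < anchor)
    }
    bl[, excluded := FALSE]
    r34 <- which(bl$uncoded & bl$route %in% c("route3", "route4"))
    for (i in r34) {
      bl$excluded[i] <- has_excl(bl$patient_id[i], bl$day[i])
    }
    rec_day <- pmin(data.table::fifelse(bl$cap_pc, bl$pc_day, NA_integer_),
                    data.table::fifelse(bl$cap_hosp, bl$adm_day, NA_integer_),
                    na.rm = TRUE)
    death_near <- !is.na(bl$death) & !is.na(rec_day) &
      (bl$death - rec_day) >= 0L & (bl$death - rec_day) <= 7L
    fatal_any <- (!is.na(bl$death) & bl$cap_dr & bl$death == bl$fatal_day) |
      death_near
    markers_obs <- bl$site %in% .critical_sites &
      (bl$cap_pc | bl$cap_hosp)
    markers_obs <- markers_obs |
      (bl$cap_hosp & bl$position == 1L & bl$stay >= 14L) |
      (bl$transfusion & (bl$cap_pc | bl$cap_hosp))
    category <- data.table::fcase(
      bl$uncoded & !(bl$patient_id %in% blocked) & !bl$excluded, "inferred",
      bl$uncoded, NA_character_,
      fatal_any, "fatal",
      bl$cap_hosp & markers_obs, "hospitalised_ms",
      bl$cap_pc & !bl$cap_hosp & markers_obs, "primary_care_ms",
      bl$cap_hosp, "hospitalised",
      bl$cap_pc, "primary_care",
      default = NA_character_)
    gt <- data.table(
      patient_id = bl$patient_id,
      bleed_date = as.Date(bl$day, origin = "1970-01-01"),
      site = bl$site, therapy_state = bl$state, uncoded = bl$uncoded,
      route = bl$route, fatal = !is.na(category) & category == "fatal",
      observed = !is.na(category), category = category,
      prognostic_class = prognostic_class(category),
      episode_id = bl$episode_id)
  }

  args <- list(
    patients = data.table(
      patient_id = pat$patient_id,
      sex = data.table::fifelse(pat$female, "F", "M"),
      birth_date = as.Date(pat$birth, origin = "1970-01-01"),
      transfer_out_date = as.Date(pat$transfer, origin = "1970-01-01")),
    primary_care = pc[, .(patient_id, date, code)],
    prescriptions = rx,
    labs = labs,
    hospital_episodes = if (nrow(epis)) {
      data.table(episode_id = epis$episode_id, patient_id = epis$patient_id,
                 admission_date = as.Date(epis$adm, origin = "1970-01-01"),
                 discharge_date = as.Date(epis$dis, origin = "1970-01-01"))
    },
    hospital_diagnoses = if (nrow(dxs)) dxs,
    hospital_procedures = if (nrow(prs)) {
      data.table(episode_id = prs$episode_id, patient_id = prs$patient_id,
                 code = prs$code,
                 date = as.Date(prs$day, origin = "1970-01-01"))
    },
    deaths = deaths,
    death_causes = dc,
    ground_truth = gt)
  args <- Filter(Negate(is.null), args)
  do.call(new_linked_ehr, c(args, list(config = cfg)))
}

#' Sample hospital episodes for a validation sub-study
#'
#' Emulates a case-note review: samples hospital episodes, attaches the
#' ground-truth bleeding status of each episode, and leaves the
#' algorithm's flag empty for [flag_bleeding_episodes()] to fill.
#'
#' @param ehr a simulated `linked_ehr` (needs `ground_truth`).
#' @param n_episodes number of episodes to sample (without replacement).
#' @param seed sampling seed.
#' @return `data.table` with `episode_id`, `patient_id`, `algorithm_flag`
#'   (`NA`), `truth_flag`.
#' @export
make_validation_sample <- function(ehr, n_episodes, seed = 1L) {
  stopifnot(inherits(ehr, "linked_ehr"))
  epi <- ehr$hospital_episodes
  if (n_episodes > nrow(epi)) {
    stop("n_episodes exceeds the ", nrow(epi), " available episodes")
  }
  set.seed(seed)
  take <- epi[sample.int(nrow(epi), n_episodes)]
  bleed_epis <- unique(ehr$ground_truth[!is.na(episode_id), episode_id])
  out <- take[, .(episode_id, patient_id, algorithm_flag = NA,
                  truth_flag = episode_id %in% bleed_epis)]
  data.table::setorder(out, episode_id)
  out[]
}
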