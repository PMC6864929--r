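#' Survival analysis layer
#'
#' Kaplan-Meier incidence with Greenwood variance, monthly event rates per
#' 1000 patients with loess trend smoothing, counting-process construction
#' for time-dependent covariates (therapy state, bleeding-severity state),
#' Cox model fitting with Efron tie handling, recurrent-bleeding curves,
#' diagnostic-accuracy metrics with exact binomial confidence intervals,
#' and proportional-hazards diagnostics.
#'
#' Exposure and bleeding-severity states enter Cox models as
#' time-dependent covariates: each patient's follow-up is split at every
#' state change, so person-time before attaining a state is never
#' attributed to it (avoiding immortal time bias).
#'
#' @name survival_layer
NULL

#' Kaplan-Meier estimate
#'
#' Product-limit estimator with Greenwood standard errors and log-log
#' confidence intervals, via the survival package.
#'
#' @param time follow-up durations.
#' @param event event indicators (1/TRUE = event, 0/FALSE = censored).
#' @param conf_level confidence level.
#' @return A `km_curve` object: `data.table` fields `time`, `n_risk`,
#'   `n_event`, `surv`, `se` (of S(t)), `lower`, `upper`, plus `n`.
#' @export
km_estimate <- function(time, event, conf_level = 0.95) {
  stopifnot(length(time) == length(event))
  fit <- survival::survfit(survival::Surv(time, as.integer(event)) ~ 1,
                           conf.type = "log-log", conf.int = conf_level)
  structure(list(
    curve = data.table(time = fit$time, n_risk = fit$n.risk,
                       n_event = fit$n.event, surv = fit$surv,
                       se = fit$std.err * fit$surv,
                       lower = fit$lower, upper = fit$upper),
    n = fit$n), class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat("<km_curve> n =", x$n, ",", sum(x$curve$n_event), "events\n")
  print(head(x$curve), ...)
  invisible(x)
}

#' Cumulative incidence at a time point
#'
#' @param km a `km_curve`.
#' @param t time point(s).
#' @param ci return the (transformed) confidence bounds as well?
#' @return If `ci = FALSE`, `1 - S(t)` as a numeric vector; otherwise a
#'   `data.table` with `risk`, `lower`, `upper` (bounds from the log-log
#'   interval of S).
#' @export
km_risk_at <- function(km, t, ci = FALSE) {
  cv <- km$curve
  step <- function(col) {
    vapply(t, function(tt) {
      i <- findInterval(tt, cv$time)
      if (i == 0L) if (identical(col, "surv")) 1 else NA_real_
      else cv[[col]][i]
    }, numeric(1))
  }
  s <- step("surv")
  if (!ci) return(1 - s)
  data.table(risk = 1 - s, lower = 1 - step("upper"), upper = 1 - step("lower"))
}

#' Monthly event rates per 1000 patients at risk
#'
#' A patient is at risk in a calendar month when their follow-up interval
#' `[entry, end)` overlaps any day of the month (default), or when it
#' covers the first day of the month (`at_risk = "month_start"`). The 95%
#' interval uses a normal approximation to the Poisson count.
#'
#' @param event_dates `Date` vector of event dates.
#' @param entry_dates,end_dates `Date` vectors of per-patient follow-up.
#' @param at_risk denominator rule.
#' @return `data.table` with `month` (first day), `n_events`, `n_at_risk`,
#'   `rate_per_1000`, `lo`, `hi` (lower bound clamped at 0). Months with
#'   no patients at risk are omitted.
#' @export
monthly_rates <- function(event_dates, entry_dates, end_dates,
                          at_risk = c("overlap", "month_start")) {
  at_risk <- match.arg(at_risk)
  entry_dates <- as.Date(entry_dates); end_dates <- as.Date(end_dates)
  event_dates <- as.Date(event_dates)
  if (!length(entry_dates)) return(data.table())
  first_month <- function(d) as.Date(format(d, "%Y-%m-01"))
  months <- seq(first_month(min(entry_dates)), first_month(max(end_dates)),
                by = "month")
  m0 <- as.integer(months)
  m1 <- as.integer(c(months[-1], seq(months[length(months)], by = "month",
                                     length.out = 2)[2]))  # exclusive ends
  en <- as.integer(entry_dates); ex <- as.integer(end_dates)
  ev <- as.integer(event_dates)
  out <- data.table(month = months)
  out[, n_at_risk := vapply(seq_along(m0), function(i) {
    if (at_risk == "overlap") sum(en < m1[i] & ex > m0[i])
    else sum(en <= m0[i] & ex > m0[i])
  }, integer(1))]
  out[, n_events := vapply(seq_along(m0), function(i) {
    sum(ev >= m0[i] & ev < m1[i])
  }, integer(1))]
  out <- out[n_at_risk > 0]
  out[, rate_per_1000 := 1000 * n_events / n_at_risk]
  out[, half := 1.96 * 1000 * sqrt(n_events) / n_at_risk]
  out[, `:=`(lo = pmax(0, rate_per_1000 - half), hi = rate_per_1000 + half)]
  out[, half := NULL]
  out[]
}

#' Loess trend smoothing
#'
#' Locally weighted linear regression with tricube weights, evaluated at
#' the input grid.
#'
#' @param x,y numeric vectors.
#' @param span smoothing span (fraction of points in each local fit).
#' @param degree local polynomial degree (1 = local linear).
#' @return Numeric vector of fitted values at `x`.
#' @export
loess_smooth <- function(x, y, span = 0.75, degree = 1) {
  fit <- loess(y ~ x, span = span, degree = degree, family = "gaussian",
               surface = "direct")
  as.numeric(predict(fit, data.frame(x = x)))
}

#' Build counting-process rows for time-dependent Cox models
#'
#' Splits each patient's follow-up at every covariate-change time; time is
#' measured in days since entry. The outcome terminates follow-up: the
#' terminal row carries `event = 1` and no rows extend past it. An outcome
#' on the entry day is counted at half a day so the row has positive
#' length.
#'
#' @param follow_up data frame `patient_id`, `entry`, `end` (`Date`).
#' @param states optional tiling of follow-up with a time-varying state
#'   (`patient_id`, `start`, `end`, `state`), e.g. from
#'   [therapy_timeline()] or [bleed_state_intervals()]. Patients without
#'   rows get the first level/`"none"`.
#' @param outcomes data frame `patient_id`, `date` of the (first) outcome
#'   event per patient; dates after `end` are ignored (censored).
#' @param fixed optional data frame of per-patient fixed covariates to
#'   join (must contain `patient_id`).
#' @param default_state state label for person-time not covered by
#'   `states` (patients without state rows, e.g. zero-length follow-up).
#' @return `data.table` with `patient_id`, `start`, `stop` (days since
#'   entry), `event` and covariate columns. Row durations of one patient
#'   sum to the follow-up duration (up to the half-day event convention).
#' @export
build_counting_process <- function(follow_up, states = NULL, outcomes,
                                   fixed = NULL, default_state = "none") {
  fu <- data.table::as.data.table(follow_up)[, .(
    patient_id, entry = as.Date(entry), end = as.Date(end))]
  oc <- data.table::as.data.table(outcomes)
  oc <- if (nrow(oc)) {
    oc[, .(patient_id, odate = as.Date(date))][
      , .(odate = min(odate)), by = patient_id]
  } else {
    data.table(patient_id = fu$patient_id[0], odate = as.Date(character()))
  }
  fu <- oc[fu, on = "patient_id"]
  fu[, T_end := as.numeric(end - entry)]
  fu[, o := as.numeric(odate - entry)]
  fu[, event_in := !is.na(o) & o >= 0 & o <= T_end]
  fu[, stop_day := data.table::fifelse(event_in, pmax(o, 0.5), T_end)]
  fu <- fu[stop_day > 0]

  cuts <- fu[, .(patient_id, day = 0)]
  if (!is.null(states)) {
    st <- data.table::as.data.table(states)
    st <- fu[, .(patient_id, entry, stop_day)][st, on = "patient_id",
                                               nomatch = NULL]
    st[, `:=`(s = as.numeric(as.Date(start) - entry),
              e = as.numeric(as.Date(end) - entry))]
    extra <- st[s > 0 & s < stop_day, .(patient_id, day = s)]
    cuts <- rbind(cuts, extra)
  }
  cuts <- rbind(cuts, fu[, .(patient_id, day = stop_day)])
  cuts <- unique(cuts)
  data.table::setorder(cuts, patient_id, day)
  rows <- cuts[, .(start = head(day, -1L), stop = tail(day, -1L)),
               by = patient_id]
  rows <- rows[stop > start]
  rows <- fu[, .(patient_id, stop_day, event_in)][rows, on = "patient_id"]
  rows[, event := as.integer(event_in & stop == stop_day)]
  rows[, c("stop_day", "event_in") := NULL]
  if (!is.null(states)) {
    st2 <- st[, .(patient_id, s, e, state)]
    rows[, state := st2[rows, on = .(patient_id, s <= start, e > start),
                        mult = "first", x.state]]
    rows[is.na(state), state := default_state]
  }
  if (!is.null(fixed)) {
    rows <- data.table::as.data.table(fixed)[rows, on = "patient_id"]
  }
  data.table::setcolorder(rows, c("patient_id", "start", "stop", "event"))
  data.table::setorder(rows, patient_id, start)
  rows[]
}

#' Bleeding-severity state intervals for prognosis models
#'
#' Every patient starts follow-up in the `no_bleed` state and switches to
#' the severity class of their first bleeding event at its date, where
#' they remain (the first transition defines the state). Fatal first
#' events are excluded by default: a fatal bleed is an outcome, not a
#' state a patient survives in, so those patients stay `no_bleed` until
#' their death.
#'
#' @param events phenotyped events (from [phenotype_bleeding()]).
#' @param follow_up data frame `patient_id`, `entry`, `end`.
#' @param use_class use prognostic class (`I`, `II`, `III`) rather than
#'   category as the state label.
#' @param exclude_fatal ignore fatal first events when assigning states.
#' @return State tiling suitable for [build_counting_process()] (pass
#'   `default_state = "no_bleed"` there).
#' @export
bleed_state_intervals <- function(events, follow_up, use_class = TRUE,
                                  exclude_fatal = TRUE) {
  fu <- data.table::as.data.table(follow_up)[, .(
    patient_id, entry = as.Date(entry), end = as.Date(end))]
  ev_in <- data.table::as.data.table(events)
  if (exclude_fatal) ev_in <- ev_in[category != "fatal"]
  fe <- first_events(ev_in)[!is.na(first_any_date)]
  fe <- fe[, .(patient_id, bdate = first_any_date,
               lab = if (use_class) prognostic_class(first_any_category)
                     else first_any_category)]
  m <- fe[fu, on = "patient_id"]
  pre <- m[, .(patient_id, start = entry,
               end = pmin(data.table::fifelse(is.na(bdate), end, bdate), end),
               state = "no_bleed")]
  post <- m[!is.na(bdate) & bdate < end,
            .(patient_id, start = pmax(bdate, entry), end, state = lab)]
  out <- rbind(pre[end > start], post[end > start])
  data.table::setorder(out, patient_id, start)
  out[]
}

#' Fit a Cox model on counting-process rows
#'
#' Maximises the partial likelihood over `(start, stop, event)` rows with
#' Efron handling of tied event times (Breslow available). Character
#' covariates become factors; a `none` / `no_bleed` level, when present,
#' is the reference.
#'
#' @param rows counting-process rows from [build_counting_process()].
#' @param terms character vector of covariate column names.
#' @param ties `"efron"` or `"breslow"`.
#' @param conf_level confidence level for hazard-ratio intervals.
#' @return A `cox_td_fit`: `table` (`data.table` of term, coef, se, hr,
#'   lo, hi), `n_events`, `loglik`, `converged`, and the underlying
#'   `coxph` fit as `model`.
#' @export
cox_td_fit <- function(rows, terms, ties = c("efron", "breslow"),
                       conf_level = 0.95) {
  ties <- match.arg(ties)
  rows <- data.table::as.data.table(rows)
  missing_terms <- setdiff(terms, names(rows))
  if (length(missing_terms)) {
    stop("term(s) not in rows: ", paste(missing_terms, collapse = ", "))
  }
  dat <- as.data.frame(rows)
  for (tm in terms) {
    v <- dat[[tm]]
    if (length(unique(v[!is.na(v)])) < 2L) {
      stop("degenerate design: covariate '", tm, "' has zero variance")
    }
    if (is.character(v) || is.factor(v)) {
      v <- factor(v)
      for (ref in c("none", "no_bleed")) {
        if (ref %in% levels(v)) v <- stats::relevel(v, ref = ref)
      }
      dat[[tm]] <- v
    }
  }
  fml <- stats::as.formula(paste(
    "survival::Surv(start, stop, event) ~", paste(terms, collapse = " + ")))
  warn <- NULL
  fit <- withCallingHandlers(
    survival::coxph(fml, data = dat, ties = ties,
                    control = survival::coxph.control(eps = 1e-9,
                                                      iter.max = 50)),
    warning = function(w) {
      warn <<- conditionMessage(w)
      invokeRestart("muffleWarning")
    })
  converged <- is.null(warn) ||
    !grepl("did not converge|infinite|out of iterations|beta may be",
           warn, ignore.case = TRUE)
  if (!converged) {
    warning("possible non-convergence or separation: ", warn, call. = FALSE)
  }
  z <- qnorm(1 - (1 - conf_level) / 2)
  co <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  tab <- data.table(term = names(co), coef = unname(co), se = unname(se))
  tab[, `:=`(hr = exp(coef), lo = exp(coef - z * se), hi = exp(coef + z * se))]
  structure(list(table = tab, n_events = sum(rows$event),
                 loglik = fit$loglik[length(fit$loglik)],
                 converged = converged, model = fit),
            class = "cox_td_fit")
}

#' @export
print.cox_td_fit <- function(x, digits = 3, ...) {
  cat("<cox_td_fit>", x$n_events, "events; partial log-likelihood",
      format(x$loglik, digits = 8), "\n")
  tab <- data.table::copy(x$table)
  num <- c("coef", "se", "hr", "lo", "hi")
  tab[, (num) := lapply(.SD, round, digits), .SDcols = num]
  print(tab)
  invisible(x)
}

#' Recurrent-bleeding Kaplan-Meier curves
#'
#' Follows patients from their first non-fatal bleeding event to the next
#' event, stratified by whether the initial event carried markers of
#' severity.
#'
#' @param events phenotyped events.
#' @param follow_up data frame `patient_id`, `entry`, `end`.
#' @param outcome `"any"` (next event of any severity) or `"severe"` (next
#'   fatal or with-markers event).
#' @return Named list of `km_curve`s: `all`, `ms` (initial event with
#'   markers), `no_ms`; strata without patients are `NULL`.
#' @export
recurrent_bleed_curves <- function(events, follow_up,
                                   outcome = c("any", "severe")) {
  outcome <- match.arg(outcome)
  ev <- data.table::as.data.table(events)
  fu <- data.table::as.data.table(follow_up)[, .(
    patient_id, end = as.Date(end))]
  nonfatal <- ev[category != "fatal"]
  if (!nrow(nonfatal)) return(list(all = NULL, ms = NULL, no_ms = NULL))
  nonfatal[, rk := match(category, .bleed_categories)]
  data.table::setorder(nonfatal, patient_id, event_date, rk)
  idx <- nonfatal[, .(t0 = event_date[1L], cat0 = category[1L]),
                  by = patient_id]
  severe_cats <- c("fatal", "hospitalised_ms", "primary_care_ms")
  nxt_pool <- if (outcome == "any") ev else ev[category %in% severe_cats]
  nxt <- nxt_pool[idx, on = "patient_id"][event_date > t0]
  nxt <- nxt[, .(tnext = min(event_date)), by = patient_id]
  d <- nxt[idx, on = "patient_id"]
  d <- fu[d, on = "patient_id", nomatch = NULL]
  d[, time := as.numeric(data.table::fifelse(is.na(tnext), end, tnext) - t0)]
  d[, ev_flag := as.integer(!is.na(tnext))]
  d <- d[time > 0 | ev_flag == 1]
  d[time <= 0, time := 0.5]
  d[, stratum := data.table::fifelse(
    cat0 %in% c("hospitalised_ms", "primary_care_ms"), "ms", "no_ms")]
  res <- list(all = km_estimate(d$time, d$ev_flag))
  for (s in c("ms", "no_ms")) {
    ds <- d[stratum == s]
    res[[s]] <- if (nrow(ds)) km_estimate(ds$time, ds$ev_flag) else NULL
  }
  res
}

#' Diagnostic accuracy of a binary phenotype against a gold standard
#'
#' @param tp,fp,fn,tn confusion-matrix counts.
#' @param conf_level confidence level for the exact (Clopper-Pearson)
#'   binomial intervals.
#' @return `data.table` with rows `ppv`, `npv`, `sensitivity`,
#'   `specificity`: `estimate`, `lower`, `upper` (NA when the denominator
#'   is zero).
#' @export
diagnostic_metrics <- function(tp, fp, fn, tn, conf_level = 0.95) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0, tn >= 0)
  one <- function(x, n) {
    if (n == 0) return(c(NA_real_, NA_real_, NA_real_))
    ci <- binom.test(x, n, conf.level = conf_level)$conf.int
    c(x / n, ci[1], ci[2])
  }
  vals <- rbind(ppv = one(tp, tp + fp), npv = one(tn, tn + fn),
                sensitivity = one(tp, tp + fn),
                specificity = one(tn, tn + fp))
  data.table(metric = rownames(vals), estimate = vals[, 1],
             lower = vals[, 2], upper = vals[, 3])
}

#' Proportional-hazards diagnostics
#'
#' Schoenfeld-residual trend tests per term (via `survival::cox.zph`) and,
#' when a grouping state is supplied, log(-log) survival series per
#' stratum for visual inspection.
#'
#' @param fit a `cox_td_fit`.
#' @param rows counting-process rows (needed for the log(-log) curves).
#' @param group optional name of a state column in `rows` to stratify the
#'   log(-log) curves by.
#' @param transform time transform for the trend test (see
#'   [survival::cox.zph()]).
#' @return List with `schoenfeld` (`data.table`: term, chisq, df, p),
#'   `zph` (the `cox.zph` object) and `loglog` (`data.table`: group,
#'   time, loglog, or `NULL`).
#' @export
ph_diagnostics <- function(fit, rows = NULL, group = NULL,
                           transform = "km") {
  stopifnot(inherits(fit, "cox_td_fit"))
  zph <- survival::cox.zph(fit$model, transform = transform)
  tab <- data.table(term = rownames(zph$table),
                    chisq = zph$table[, "chisq"], df = zph$table[, "df"],
                    p = zph$table[, "p"])
  ll <- NULL
  if (!is.null(rows) && !is.null(group)) {
    rows <- data.table::as.data.table(rows)
    sf <- survival::survfit(
      survival::Surv(start, stop, event) ~ g,
      data = data.frame(start = rows$start, stop = rows$stop,
                        event = rows$event, g = rows[[group]]))
    strata_names <- rep(sub("^g=", "", names(sf$strata)), sf$strata)
    keep <- sf$surv > 0 & sf$surv < 1
    ll <- data.table(group = strata_names[keep], time = sf$time[keep],
                     loglog = log(-log(sf$surv[keep])))
  }
  list(schoenfeld = tab, zph = zph, loglog = ll)
}
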