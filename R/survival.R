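# Real-world overall survival from claims event streams.
#
# Vital status is inferred from the claims record: a patient with no claim
# for more than `gap_days` (default 100) before the data cutoff is assumed
# dead, with the death date imputed at the last claim; otherwise the
# patient is censored at last contact. Overall survival is measured from
# treatment initiation. Castration state is assigned by the 90-day rule:
# systemic therapy started within 90 days of first-line ADT is
# hormone-sensitive, later starts are castration-resistant.

EVENT_KINDS <- c("claim", "treatment_start", "last_contact")
DRUG_CATEGORIES <- c("first_line_ADT", "second_gen_ARSI", "taxane",
                     "pembrolizumab", "other")

#' Infer vital status from one patient's claims
#'
#' Applies the no-claim gap rule: if more than `gap_days` elapse between
#' the patient's last claim (claims and treatment starts both count as
#' contact) and the data cutoff, the patient is assumed dead at the
#' last-claim date; otherwise the patient is censored at the last contact.
#' The boundary is strict: a gap of exactly `gap_days` is censored.
#'
#' @param events Data frame of one patient's events with columns `date`
#'   (`Date`) and `kind` (one of `claim`, `treatment_start`,
#'   `last_contact`).
#' @param cutoff_date Data cutoff (`Date`), at or after the last event.
#' @param gap_days Gap threshold in days (default 100).
#' @return List with `event` (1 = assumed death, 0 = censored) and
#'   `terminal_date`.
#' @export
infer_vital_status <- function(events, cutoff_date, gap_days = 100) {
  if (nrow(events) == 0L) stop("patient has no events; vital status undeterminable")
  cutoff_date <- as.Date(cutoff_date)
  dates <- as.Date(events$date)
  if (cutoff_date < max(dates)) stop("cutoff_date precedes the last event date")
  claim_dates <- dates[events$kind %in% c("claim", "treatment_start")]
  if (length(claim_dates) == 0L) stop("patient has no claims; vital status undeterminable")
  last_claim <- max(claim_dates)
  gap <- as.numeric(cutoff_date - last_claim)
  if (gap > gap_days) {
    list(event = 1L, terminal_date = last_claim)
  } else {
    list(event = 0L, terminal_date = max(dates))
  }
}

#' Label treatments with castration state
#'
#' Systemic therapies started within `window_days` of the patient's first
#' first-line ADT start are `hormone_sensitive`; strictly later starts are
#' `castration_resistant`; treatments for patients with no ADT on record
#' are `unknown`. The boundary is strict: a start exactly `window_days`
#' after ADT is hormone-sensitive.
#'
#' @param events Data frame of one patient's events (columns `date`,
#'   `kind`, `drug_category`).
#' @param window_days Window in days (default 90).
#' @return `events` with a `castration_state` column (`NA` for non-treatment
#'   rows).
#' @export
annotate_castration_state <- function(events, window_days = 90) {
  events$castration_state <- NA_character_
  trt <- events$kind == "treatment_start"
  if (!any(trt)) return(events)
  adt <- trt & events$drug_category == "first_line_ADT"
  if (!any(adt, na.rm = TRUE)) {
    events$castration_state[trt] <- "unknown"
    return(events)
  }
  adt0 <- min(as.Date(events$date)[which(adt)])
  delta <- as.numeric(as.Date(events$date) - adt0)
  events$castration_state[trt] <- ifelse(delta[trt] <= window_days,
                                         "hormone_sensitive",
                                         "castration_resistant")
  events
}

#' Build overall-survival records from a classified cohort
#'
#' One record per patient per requested treatment category, indexed at the
#' first start of that category (`category = "any"` indexes at the earliest
#' systemic treatment of any kind). Time runs from the index date to the
#' terminal date from [infer_vital_status()]; records whose terminal date
#' does not fall strictly after the index date are dropped with a warning.
#'
#' @param samples Data frame with columns `patient_id`, `class` and any
#'   further strata columns (e.g. `biopsy_site`); one row per patient.
#' @param claims Cohort-wide claims data frame (`patient_id`, `date`,
#'   `kind`, `drug`, `drug_category`).
#' @param category Treatment category to index on: `"any"` or one of
#'   `first_line_ADT`, `second_gen_ARSI`, `taxane`, `pembrolizumab`.
#' @param cutoff_date Data cutoff; defaults to the day after the latest
#'   event in `claims`.
#' @param gap_days,window_days Thresholds for [infer_vital_status()] and
#'   [annotate_castration_state()].
#' @return Data frame of survival records: `patient_id`, `index_date`,
#'   `time_days`, `event`, `class`, `treatment_category`,
#'   `castration_state`, plus strata columns carried over from `samples`.
#' @export
build_survival_records <- function(samples, claims, category = "any",
                                   cutoff_date = NULL,
                                   gap_days = 100, window_days = 90) {
  stopifnot(all(c("patient_id", "class") %in% names(samples)))
  claims$date <- as.Date(claims$date)
  if (is.null(cutoff_date)) cutoff_date <- max(claims$date) + 1L
  cutoff_date <- as.Date(cutoff_date)

  # vectorized vital status: last claim / last contact per patient
  is_claim <- claims$kind %in% c("claim", "treatment_start")
  last_claim <- tapply(as.numeric(claims$date[is_claim]),
                       claims$patient_id[is_claim], max)
  last_any <- tapply(as.numeric(claims$date), claims$patient_id, max)
  gap <- as.numeric(cutoff_date) - last_claim
  dead <- gap > gap_days
  terminal <- ifelse(dead, last_claim, last_any[names(last_claim)])

  trt <- claims[claims$kind == "treatment_start", , drop = FALSE]
  if (category != "any") {
    trt_cat <- trt[trt$drug_category == category, , drop = FALSE]
  } else {
    trt_cat <- trt
  }
  if (nrow(trt_cat) == 0L) {
    return(cbind(samples[0, , drop = FALSE],
                 data.frame(index_date = as.Date(character()),
                            time_days = numeric(), event = integer(),
                            treatment_category = character(),
                            castration_state = character())))
  }
  index <- tapply(as.numeric(trt_cat$date), trt_cat$patient_id, min)

  # castration state of the indexing treatment, via each patient's first ADT
  adt <- trt[trt$drug_category == "first_line_ADT", , drop = FALSE]
  adt0 <- tapply(as.numeric(adt$date), adt$patient_id, min)

  ids <- intersect(samples$patient_id, names(index))
  idx <- index[ids]
  a0 <- adt0[ids]
  cast <- ifelse(is.na(a0), "unknown",
                 ifelse(idx - a0 <= window_days,
                        "hormone_sensitive", "castration_resistant"))
  term <- terminal[ids]
  ev <- as.integer(dead[ids])

  rec <- samples[match(ids, samples$patient_id), , drop = FALSE]
  rec$index_date <- as.Date(idx, origin = "1970-01-01")
  rec$time_days <- term - idx
  rec$event <- ev
  rec$treatment_category <- category
  rec$castration_state <- unname(cast)

  drop <- is.na(rec$time_days) | rec$time_days <= 0
  if (any(drop)) {
    warning(sprintf("dropped %d record(s) with non-positive follow-up time",
                    sum(drop)))
    rec <- rec[!drop, , drop = FALSE]
  }
  rownames(rec) <- NULL
  rec
}

#' Fit a two-arm Cox model for one class versus wild type
#'
#' Single binary covariate Cox proportional-hazards fit (Efron tie
#' handling) of one alteration class against `WT`, with a log-rank p value
#' and a 95% Wald confidence interval on the log hazard ratio. Arms with
#' fewer than two events are reported as non-convergent with a missing HR.
#'
#' @param records Survival records from [build_survival_records()].
#' @param class_label Alteration class to contrast with `WT`.
#' @param wt_label Reference label (default `"WT"`).
#' @param min_events Minimum events per arm for a fit (default 2).
#' @return One-row data frame: `comparison`, `n_class`, `n_wt`,
#'   `events_class`, `events_wt`, `hr`, `ci_low`, `ci_high`, `p_logrank`,
#'   `converged`.
#' @export
fit_class_vs_wt <- function(records, class_label, wt_label = "WT",
                            min_events = 2L) {
  sub <- records[records$class %in% c(class_label, wt_label), , drop = FALSE]
  x <- as.integer(sub$class == class_label)
  n_class <- sum(x == 1L); n_wt <- sum(x == 0L)
  ev_class <- sum(sub$event[x == 1L]); ev_wt <- sum(sub$event[x == 0L])
  out <- data.frame(
    comparison = sprintf("%s_vs_%s", class_label, wt_label),
    n_class = n_class, n_wt = n_wt,
    events_class = ev_class, events_wt = ev_wt,
    hr = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
    p_logrank = NA_real_, converged = FALSE,
    stringsAsFactors = FALSE
  )
  if (n_class == 0L || n_wt == 0L || ev_class < min_events || ev_wt < min_events) {
    return(out)
  }
  fit <- coxph(Surv(sub$time_days, sub$event) ~ x, ties = "efron")
  beta <- unname(fit$coefficients[1])
  se <- sqrt(unname(fit$var[1, 1]))
  sd <- survdiff(Surv(sub$time_days, sub$event) ~ x)
  out$hr <- exp(beta)
  out$ci_low <- exp(beta - 1.96 * se)
  out$ci_high <- exp(beta + 1.96 * se)
  out$p_logrank <- pchisq(sd$chisq, df = 1, lower.tail = FALSE)
  out$converged <- is.finite(beta) && is.finite(se)
  out
}

#' Forest table of class-versus-WT hazard ratios
#'
#' @param records Survival records.
#' @param classes Classes to contrast (default: all non-WT classes present).
#' @param ... Passed to [fit_class_vs_wt()].
#' @return Data frame with one row per comparison.
#' @export
forest_table <- function(records, classes = NULL, ...) {
  if (is.null(classes)) {
    classes <- intersect(setdiff(FOXA1_CLASSES, "WT"), unique(records$class))
  }
  if (length(classes) == 0L) {
    return(data.frame(comparison = character(), n_class = integer(),
                      n_wt = integer(), events_class = integer(),
                      events_wt = integer(), hr = numeric(),
                      ci_low = numeric(), ci_high = numeric(),
                      p_logrank = numeric(), converged = logical(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(classes, function(cl) fit_class_vs_wt(records, cl, ...)))
}

#' Kaplan-Meier coordinates for one class-versus-WT contrast
#'
#' @param records Survival records.
#' @param class_label Alteration class; both its curve and the WT curve are
#'   returned.
#' @param wt_label Reference label.
#' @return Data frame with columns `arm`, `time`, `n_risk`, `n_event`,
#'   `surv`.
#' @export
km_coordinates <- function(records, class_label, wt_label = "WT") {
  sub <- records[records$class %in% c(class_label, wt_label), , drop = FALSE]
  arm <- factor(sub$class, levels = c(wt_label, class_label))
  fit <- survfit(Surv(sub$time_days, sub$event) ~ arm)
  arms <- rep(sub("^arm=", "", names(fit$strata)), fit$strata)
  data.frame(arm = arms, time = fit$time, n_risk = fit$n.risk,
             n_event = fit$n.event, surv = fit$surv,
             stringsAsFactors = FALSE)
}
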