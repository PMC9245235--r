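# Alert engine: crosses the prescription and the patient profile against the
# knowledge base.  The engine only reports -- it never removes a drug from
# the prescription; overrides are explicit user actions that keep the
# original alert on record.

ALERT_TYPES <- c("nu_interaction", "contraindication", "duplication",
                 "overdose", "underdose", "food_relation", "observation",
                 "min_interval_needed")

# Default severity by alert class; configurable per-rule severities could be
# added in the KB but the defaults below are the package convention.
ALERT_SEVERITY <- c(
  nu_interaction = "blocking", contraindication = "blocking",
  duplication = "warning", overdose = "warning", underdose = "warning",
  food_relation = "info", observation = "info", min_interval_needed = "info"
)

new_alert <- function(alert_type, items_involved, message,
                      severity = ALERT_SEVERITY[[alert_type]],
                      overridden = FALSE, justification = NA_character_) {
  stopifnot(alert_type %in% ALERT_TYPES)
  structure(list(
    id = NA_character_,  # assigned by review_prescription after ordering
    alert_type = alert_type,
    severity = severity,
    items_involved = as.integer(items_involved),
    message = message,
    overridden = overridden,
    justification = justification
  ), class = "alert")
}

# Unordered pair match against a rule.
rule_matches_pair <- function(rule, pa, pb) {
  any(rule$principle_a == pa & rule$principle_b == pb) ||
    any(rule$principle_a == pb & rule$principle_b == pa)
}

# All (i, j, rule) triples where principles of items i < j match a rule of
# the given type. Double loop over item pairs: prescriptions are short.
match_pair_rules <- function(prescription, kb, type) {
  rules <- Filter(function(r) r$rule_type == type, kb$interactions)
  out <- list()
  n <- length(prescription)
  if (n < 2L || length(rules) == 0L) return(out)
  pr <- lapply(prescription, resolve_principles, kb = kb)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      for (r in rules) {
        hit <- FALSE
        for (pa in pr[[i]]) {
          for (pb in pr[[j]]) {
            if (rule_matches_pair(r, pa, pb)) hit <- TRUE
          }
        }
        if (hit) out <- c(out, list(list(i = i, j = j, rule = r)))
      }
    }
  }
  out
}

#' Detect contraindicated concomitant use (no-use interaction rules)
#'
#' Emits one blocking alert per unordered active-principle pair, across
#' distinct prescription items, that matches a no-use (NU) interaction rule.
#'
#' @param prescription list of prescription items.
#' @param kb a `knowledge_base`.
#' @return list of alerts (empty when nothing matches).
#' @export
check_nu_pairs <- function(prescription, kb) {
  lapply(match_pair_rules(prescription, kb, "NU"), function(m) {
    msg <- if (nzchar(m$rule$message)) m$rule$message else
      sprintf("%s and %s must not be used concomitantly",
              m$rule$principle_a, m$rule$principle_b)
    new_alert("nu_interaction", c(m$i, m$j),
              sprintf("[%s + %s] %s", prescription[[m$i]]$drug,
                      prescription[[m$j]]$drug, msg))
  })
}

# S-rule pairs surface as informational alerts; the scheduler consumes the
# same rules as hard minimum-interval constraints.
check_min_intervals <- function(prescription, kb) {
  lapply(match_pair_rules(prescription, kb, "S"), function(m) {
    new_alert("min_interval_needed", c(m$i, m$j),
              sprintf("[%s + %s] keep at least %d min between administrations%s",
                      prescription[[m$i]]$drug, prescription[[m$j]]$drug,
                      m$rule$min_interval,
                      if (nzchar(m$rule$message)) paste0(": ", m$rule$message) else ""))
  })
}

#' Detect drugs contraindicated by the patient's conditions
#'
#' One blocking alert per (item, condition) pair where the condition appears
#' in the drug's contraindicated conditions.  An item carrying a
#' `clinical_override_note` (risk explicitly accepted by clinical decision)
#' yields its alert pre-overridden with that note as justification -- the
#' alert is still emitted and retained.
#'
#' @param case a `patient_case`.
#' @param kb a `knowledge_base`.
#' @return list of alerts.
#' @export
check_contraindications <- function(case, kb) {
  codes <- condition_codes(case)
  out <- list()
  for (i in seq_along(case$prescription)) {
    it <- case$prescription[[i]]
    d <- kb_drug(kb, it$drug)
    for (cond in intersect(d$contraindicated_conditions, codes)) {
      ov <- !is.na(it$clinical_override_note)
      out <- c(out, list(new_alert(
        "contraindication", i,
        sprintf("[%s] contraindicated for condition '%s'", it$drug, cond),
        overridden = ov,
        justification = if (ov) it$clinical_override_note else NA_character_
      )))
    }
  }
  out
}

#' Detect therapeutic duplication
#'
#' Two-tier rule: a shared active principle across two distinct items is a
#' duplication warning; two items whose ATC codes share the 5-character
#' prefix (same chemical subgroup) but share no principle raise a
#' class-level warning.
#'
#' @inheritParams check_nu_pairs
#' @return list of alerts.
#' @export
check_duplication <- function(prescription, kb) {
  out <- list()
  n <- length(prescription)
  if (n < 2L) return(out)
  pr <- lapply(prescription, resolve_principles, kb = kb)
  atc <- vapply(prescription, function(it) kb_drug(kb, it$drug)$atc_code, "")
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      shared <- intersect(pr[[i]], pr[[j]])
      if (length(shared)) {
        out <- c(out, list(new_alert(
          "duplication", c(i, j),
          sprintf("[%s + %s] duplicated active principle: %s",
                  prescription[[i]]$drug, prescription[[j]]$drug,
                  paste(shared, collapse = ", ")))))
      } else if (!is.na(atc[i]) && !is.na(atc[j]) &&
                 substr(atc[i], 1L, 5L) == substr(atc[j], 1L, 5L)) {
        out <- c(out, list(new_alert(
          "duplication", c(i, j),
          sprintf("[%s + %s] same ATC chemical subgroup %s",
                  prescription[[i]]$drug, prescription[[j]]$drug,
                  substr(atc[i], 1L, 5L)),
          severity = "warning")))
      }
    }
  }
  out
}

#' Check doses against the knowledge-base limits
#'
#' Flags overdose when the total daily dose per kg exceeds the drug's
#' maximum (or a single dose exceeds the absolute single-dose cap), and
#' underdose when the daily dose per kg falls below the minimum.  Doses
#' exactly at a limit are compliant (strict inequality, relative tolerance
#' `1e-9` to absorb float noise).  A per-kg limit with no recorded patient
#' weight yields an explicit "cannot evaluate" info alert, never silence.
#'
#' @param case a `patient_case`.
#' @param kb a `knowledge_base`.
#' @return list of alerts.
#' @export
check_dose <- function(case, kb) {
  tol <- 1e-9
  out <- list()
  for (i in seq_along(case$prescription)) {
    it <- case$prescription[[i]]
    d <- kb_drug(kb, it$drug)
    daily <- it$dose_amount * it$doses_per_day
    per_kg_limits <- !is.na(d$max_daily_dose_per_kg) || !is.na(d$min_daily_dose_per_kg)
    if (per_kg_limits && (is.na(case$weight) || case$weight <= 0)) {
      out <- c(out, list(new_alert(
        "observation", i,
        sprintf("[%s] per-kg dose limit exists but patient weight is missing: cannot evaluate dose",
                it$drug),
        severity = "info")))
      next
    }
    if (!is.na(d$max_daily_dose_per_kg)) {
      per_kg <- daily / case$weight
      if (per_kg > d$max_daily_dose_per_kg * (1 + tol)) {
        out <- c(out, list(new_alert(
          "overdose", i,
          sprintf("[%s] %.1f/kg/day exceeds maximum %.1f/kg/day",
                  it$drug, per_kg, d$max_daily_dose_per_kg))))
      }
    }
    if (!is.na(d$max_single_dose) && it$dose_amount > d$max_single_dose * (1 + tol)) {
      out <- c(out, list(new_alert(
        "overdose", i,
        sprintf("[%s] single dose %.1f exceeds maximum single dose %.1f",
                it$drug, it$dose_amount, d$max_single_dose))))
    }
    if (!is.na(d$min_daily_dose_per_kg)) {
      per_kg <- daily / case$weight
      if (per_kg < d$min_daily_dose_per_kg * (1 - tol)) {
        out <- c(out, list(new_alert(
          "underdose", i,
          sprintf("[%s] %.1f/kg/day below minimum %.1f/kg/day",
                  it$drug, per_kg, d$min_daily_dose_per_kg))))
      }
    }
  }
  out
}

#' Surface food relations and administration observations
#'
#' One info alert per drug whose food relation is not `none` (the scheduler
#' consumes the same relation as a meal-anchored timing constraint), and one
#' per free-text administration observation (e.g. a posture instruction).
#'
#' @inheritParams check_nu_pairs
#' @return list of alerts.
#' @export
check_food_and_observations <- function(prescription, kb) {
  out <- list()
  for (i in seq_along(prescription)) {
    d <- kb_drug(kb, prescription[[i]]$drug)
    if (d$food_relation == "empty_stomach") {
      out <- c(out, list(new_alert(
        "food_relation", i,
        sprintf("[%s] take on an empty stomach (at least %d min before a meal)",
                d$product_name, d$food_lead_min))))
    } else if (d$food_relation == "with_food") {
      out <- c(out, list(new_alert(
        "food_relation", i,
        sprintf("[%s] take with food (within %d min before to %d min after a meal)",
                d$product_name, d$food_lead_min, d$food_lag_min))))
    }
    for (obs in d$administration_observations) {
      out <- c(out, list(new_alert("observation", i,
                                   sprintf("[%s] %s", d$product_name, obs))))
    }
  }
  out
}

#' Run every check and aggregate into an alert report
#'
#' Concatenates the no-use, contraindication, duplication, dose, minimum-
#' interval and food/observation checks, stably ordered (blocking alerts
#' first, then warnings, then info; within a severity by first involved item
#' then emission order) and assigns sequential alert ids.  Idempotent:
#' identical inputs give identical reports.
#'
#' @param case a `patient_case`.
#' @param kb a `knowledge_base`.
#' @return an `alert_report` (fields `case_id`, `alerts`,
#'   `has_unresolved_blocking`).
#' @examples
#' kb <- load_knowledge_base(pharmsched_fixture("kb.json"))
#' rep <- review_prescription(load_case(pharmsched_fixture("case01.json")), kb)
#' rep$has_unresolved_blocking
#' @export
review_prescription <- function(case, kb) {
  alerts <- c(
    check_nu_pairs(case$prescription, kb),
    check_contraindications(case, kb),
    check_duplication(case$prescription, kb),
    check_dose(case, kb),
    check_min_intervals(case$prescription, kb),
    check_food_and_observations(case$prescription, kb)
  )
  sev_rank <- c(blocking = 1L, warning = 2L, info = 3L)
  if (length(alerts)) {
    ord <- order(sev_rank[vapply(alerts, function(a) a$severity, "")],
                 vapply(alerts, function(a) min(a$items_involved), 1L),
                 seq_along(alerts))
    alerts <- alerts[ord]
    for (k in seq_along(alerts)) alerts[[k]]$id <- sprintf("A%d", k)
  }
  report <- structure(list(case_id = case$case_id, alerts = alerts,
                           has_unresolved_blocking = FALSE),
                      class = "alert_report")
  recompute_blocking(report)
}

recompute_blocking <- function(report) {
  report$has_unresolved_blocking <- any(vapply(
    report$alerts, function(a) a$severity == "blocking" && !a$overridden, TRUE))
  report
}

#' Override an alert after expert analysis
#'
#' Marks the alert as overridden with a justification; the alert's content
#' is retained (never deleted) and the report's blocking flag is recomputed.
#'
#' @param report an `alert_report`.
#' @param alert_id id of the alert to override (e.g. `"A1"`).
#' @param justification free-text justification.
#' @return the updated `alert_report`.
#' @export
apply_override <- function(report, alert_id, justification) {
  ids <- vapply(report$alerts, function(a) a$id, "")
  k <- match(alert_id, ids)
  if (is.na(k)) stop("unknown alert id '", alert_id, "'", call. = FALSE)
  report$alerts[[k]]$overridden <- TRUE
  report$alerts[[k]]$justification <- justification
  recompute_blocking(report)
}

alert_report_to_list <- function(report) {
  list(case_id = report$case_id,
       has_unresolved_blocking = report$has_unresolved_blocking,
       alerts = lapply(report$alerts, function(a) {
         o <- list(id = a$id, alert_type = a$alert_type, severity = a$severity,
                   items_involved = as.list(a$items_involved), message = a$message,
                   overridden = a$overridden)
         if (!is.na(a$justification)) o$justification <- a$justification
         o
       }))
}

#' @export
print.alert_report <- function(x, ...) {
  cat(sprintf("Alert report for %s: %d alert(s)%s\n", x$case_id, length(x$alerts),
              if (x$has_unresolved_blocking) " [UNRESOLVED BLOCKING]" else ""))
  for (a in x$alerts) {
    cat(sprintf("  %-4s %-20s %-8s %s%s\n", a$id, a$alert_type, a$severity,
                a$message, if (a$overridden) " (overridden)" else ""))
  }
  invisible(x)
}

alert_types_present <- function(report) {
  unique(vapply(report$alerts, function(a) a$alert_type, ""))
}
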