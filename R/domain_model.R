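# Domain model: drug knowledge base, patient case, daily routine.
#
# The knowledge base is a JSON document with two arrays, `drugs` and
# `interactions`, plus an optional `food_tokens` vector; a patient case is a
# JSON document with `patient`, `routine` and `prescription` blocks.  Both
# schemas are documented in the package vignette and exercised by the shipped
# fixtures under inst/extdata/fixtures/.

CONDITION_CODES <- c(
  "pregnancy", "lactation", "severe_hepatic_disease", "renal_impairment",
  "peptic_ulcer", "asthma", "glaucoma", "epilepsy", "diabetes",
  "heart_failure", "hypertension"
)

FOOD_RELATIONS <- c("empty_stomach", "with_food", "none")
RULE_TYPES <- c("NU", "S", "O")

#' Canonicalize an active-principle or product name
#'
#' Upper-cases, strips accents (Latin-ASCII transliteration), collapses
#' whitespace and removes trademark glyphs, so that Portuguese/English brand
#' and generic spellings compare equal.
#'
#' @param x character vector of names.
#' @return canonical character vector.
#' @examples
#' canonical_name("Digoxina ")          # "DIGOXINA"
#' canonical_name("Mylanta Plus®") # "MYLANTA PLUS"
#' @export
canonical_name <- function(x) {
  x <- gsub("[®™]", "", x)
  x <- iconv(x, from = "UTF-8", to = "ASCII//TRANSLIT")
  x <- toupper(x)
  x <- gsub("['`^~\"]", "", x)  # transliteration leftovers of accents
  x <- gsub("\\s+", " ", trimws(x))
  x
}

new_drug_record <- function(product_name, active_principles, atc_code = NA_character_,
                            max_daily_dose_per_kg = NA_real_, max_single_dose = NA_real_,
                            min_daily_dose_per_kg = NA_real_,
                            food_relation = "none", food_lead_min = 0L, food_lag_min = 0L,
                            administration_observations = character(),
                            contraindicated_conditions = character(),
                            indication = NA_character_) {
  if (length(active_principles) == 0L || any(!nzchar(active_principles))) {
    stop("drug '", product_name, "': active_principles must be non-empty", call. = FALSE)
  }
  for (lim in list(max_daily_dose_per_kg, max_single_dose, min_daily_dose_per_kg)) {
    if (!is.na(lim) && lim <= 0) {
      stop("drug '", product_name, "': dose limits must be strictly positive", call. = FALSE)
    }
  }
  if (!is.na(min_daily_dose_per_kg) && !is.na(max_daily_dose_per_kg) &&
      min_daily_dose_per_kg > max_daily_dose_per_kg) {
    stop("drug '", product_name, "': min daily dose exceeds max daily dose", call. = FALSE)
  }
  if (!food_relation %in% FOOD_RELATIONS) {
    stop("drug '", product_name, "': unknown food_relation '", food_relation, "'", call. = FALSE)
  }
  if (!is.na(atc_code) && nzchar(atc_code) && !grepl("^[A-V][0-9]{2}[A-Z]{2}[0-9]{2}$", atc_code)) {
    stop("drug '", product_name, "': malformed ATC code '", atc_code, "'", call. = FALSE)
  }
  structure(list(
    product_name = canonical_name(product_name),
    atc_code = atc_code,
    active_principles = sort(unique(canonical_name(active_principles))),
    max_daily_dose_per_kg = max_daily_dose_per_kg,
    max_single_dose = max_single_dose,
    min_daily_dose_per_kg = min_daily_dose_per_kg,
    food_relation = food_relation,
    food_lead_min = as.integer(food_lead_min),
    food_lag_min = as.integer(food_lag_min),
    administration_observations = as.character(administration_observations),
    contraindicated_conditions = as.character(contraindicated_conditions),
    indication = indication
  ), class = "drug_record")
}

new_interaction_rule <- function(principle_a, principle_b, rule_type,
                                 min_interval = NA_integer_, message = "") {
  if (!rule_type %in% RULE_TYPES) stop("unknown rule_type '", rule_type, "'", call. = FALSE)
  a <- canonical_name(principle_a)
  b <- canonical_name(principle_b)
  if (rule_type == "NU" && !is.na(min_interval)) {
    stop("NU rule (", a, ", ", b, ") must not carry min_interval", call. = FALSE)
  }
  if (rule_type == "S" && (is.na(min_interval) || min_interval <= 0)) {
    stop("S rule (", a, ", ", b, ") requires min_interval > 0", call. = FALSE)
  }
  structure(list(
    principle_a = a, principle_b = b, rule_type = rule_type,
    min_interval = if (is.na(min_interval)) NA_integer_ else as.integer(min_interval),
    message = message
  ), class = "interaction_rule")
}

#' Construct a daily routine
#'
#' Times are `"HH:MM"` strings or minutes since midnight; the sleep interval
#' runs from `sleep_time` to `wake_time` and may wrap midnight (night-shift
#' patients sleep during the day).  Busy intervals (work, commitments) may
#' also wrap.
#'
#' @param wake_time,sleep_time clock times.
#' @param busy_intervals list of `c(start, end)` clock-time pairs.
#' @param meal_times named list/vector of clock times (names are meal labels,
#'   e.g. `breakfast`).
#' @return a `routine` object.
#' @examples
#' routine("07:00", "22:00",
#'         busy_intervals = list(c("08:00", "12:00"), c("13:00", "18:00")),
#'         meal_times = c(breakfast = "07:30", lunch = "12:30", dinner = "19:00"))
#' @export
routine <- function(wake_time, sleep_time, busy_intervals = list(), meal_times = c()) {
  wk <- parse_clock(wake_time)
  sl <- parse_clock(sleep_time)
  if (wk == sl) stop("wake_time equals sleep_time: sleep interval undefined", call. = FALSE)
  busy <- lapply(busy_intervals, function(iv) c(parse_clock(iv[[1L]]), parse_clock(iv[[2L]])))
  meals <- if (length(meal_times)) {
    stats::setNames(parse_clock(unlist(meal_times)),
                    if (is.null(names(meal_times))) paste0("meal", seq_along(meal_times))
                    else names(meal_times))
  } else integer()
  structure(list(wake_time = wk, sleep_time = sl,
                 busy_intervals = busy, meal_times = meals),
            class = "routine")
}

#' Waking windows of a routine
#'
#' Returns the complement of the sleep interval as an ordered list of
#' non-overlapping, non-wrapping half-open `[start, end)` intervals in
#' minutes since midnight (a sleep interval crossing midnight yields one
#' window; daytime sleep yields two, split at 00:00).
#'
#' @param r a [routine()] object.
#' @return list of `c(start, end)` integer pairs; their durations sum to
#'   24h minus the sleep duration.
#' @examples
#' awake_windows(routine("07:00", "22:00"))          # 07:00-22:00
#' awake_windows(routine("14:30", "07:30"))          # night worker: two windows
#' @export
awake_windows <- function(r) {
  stopifnot(inherits(r, "routine"))
  sleep <- split_interval(r$sleep_time, r$wake_time)
  if (length(sleep) == 0L) stop("sleep interval covers the full day", call. = FALSE)
  complement_intervals(sleep)
}

# Sleep interval(s), normalized (split at midnight).
sleep_windows <- function(r) split_interval(r$sleep_time, r$wake_time)

new_prescription_item <- function(drug, dose_amount, doses_per_day = NA_integer_,
                                  interval_hours = NA_real_, fixed_times = NULL,
                                  clinical_override_note = NA_character_) {
  if (is.na(doses_per_day) == is.na(interval_hours)) {
    stop("item '", drug, "': specify exactly one of doses_per_day / interval_hours",
         call. = FALSE)
  }
  if (!is.na(interval_hours)) {
    doses_per_day <- max(1L, as.integer(floor(24 / interval_hours)))
  }
  if (doses_per_day < 1L) stop("item '", drug, "': doses_per_day must be >= 1", call. = FALSE)
  structure(list(
    drug = canonical_name(drug),
    dose_amount = dose_amount,
    doses_per_day = as.integer(doses_per_day),
    interval_hours = interval_hours,
    fixed_times = if (is.null(fixed_times) || length(fixed_times) == 0L) NULL
                  else parse_clock(unlist(fixed_times)),
    clinical_override_note = clinical_override_note
  ), class = "prescription_item")
}

new_patient_case <- function(case_id, age, weight = NA_real_, sex = "unspecified",
                             conditions = list(), routine, prescription) {
  stopifnot(inherits(routine, "routine"))
  conds <- lapply(conditions, function(cc) {
    if (is.character(cc)) cc <- list(code = cc)
    if (is.null(cc$code)) stop("condition without code in case '", case_id, "'", call. = FALSE)
    cc
  })
  codes <- vapply(conds, function(cc) cc$code, "")
  has_weeks <- vapply(conds, function(cc) !is.null(cc$pregnancy_weeks), TRUE)
  if (any(has_weeks & codes != "pregnancy")) {
    stop("pregnancy_weeks only allowed on the pregnancy condition", call. = FALSE)
  }
  if (!sex %in% c("F", "M", "unspecified")) stop("sex must be F, M or unspecified", call. = FALSE)
  structure(list(case_id = case_id, age = age, weight = weight, sex = sex,
                 conditions = conds, routine = routine,
                 prescription = prescription),
            class = "patient_case")
}

condition_codes <- function(case) {
  vapply(case$conditions, function(cc) cc$code, "")
}

# ---- knowledge base ---------------------------------------------------------

#' Load and validate a drug knowledge base
#'
#' Reads a JSON knowledge base (arrays `drugs` and `interactions`, optional
#' `food_tokens`), validates every record, and checks referential integrity:
#' each principle named by an interaction rule must resolve to at least one
#' drug's active principle or to a declared food token.
#'
#' @param path path to a `kb.json` file.
#' @return a `knowledge_base` object (lists `drugs`, `interactions`,
#'   `food_tokens`), with drugs indexed by canonical product name.
#' @examples
#' kb <- load_knowledge_base(pharmsched_fixture("kb.json"))
#' length(kb$drugs)
#' @export
load_knowledge_base <- function(path) {
  if (!file.exists(path)) stop("knowledge base file not found: ", path, call. = FALSE)
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  kb_from_list(raw, context = path)
}

kb_from_list <- function(raw, context = "<kb>") {
  drugs <- lapply(raw$drugs %||% list(), function(d) {
    tryCatch(
      new_drug_record(
        product_name = d$product_name,
        active_principles = unlist(d$active_principles),
        atc_code = d$atc_code %||% NA_character_,
        max_daily_dose_per_kg = d$max_daily_dose_per_kg %||% NA_real_,
        max_single_dose = d$max_single_dose %||% NA_real_,
        min_daily_dose_per_kg = d$min_daily_dose_per_kg %||% NA_real_,
        food_relation = d$food_relation %||% "none",
        food_lead_min = d$food_lead_min %||% 0L,
        food_lag_min = d$food_lag_min %||% 0L,
        administration_observations = unlist(d$administration_observations %||% list()),
        contraindicated_conditions = unlist(d$contraindicated_conditions %||% list()),
        indication = d$indication %||% NA_character_
      ),
      error = function(e) stop("invalid drug record in ", context, ": ",
                               conditionMessage(e), call. = FALSE)
    )
  })
  names(drugs) <- vapply(drugs, function(d) d$product_name, "")
  if (anyDuplicated(names(drugs))) {
    stop("duplicate product names in ", context, ": ",
         paste(unique(names(drugs)[duplicated(names(drugs))]), collapse = ", "),
         call. = FALSE)
  }
  rules <- lapply(raw$interactions %||% list(), function(r) {
    tryCatch(
      new_interaction_rule(r$principle_a, r$principle_b, r$rule_type,
                           r$min_interval %||% NA_integer_, r$message %||% ""),
      error = function(e) stop("invalid interaction rule in ", context, ": ",
                               conditionMessage(e), call. = FALSE)
    )
  })
  food_tokens <- canonical_name(unlist(raw$food_tokens %||% list("FOOD", "MEAL")))
  known <- unique(c(unlist(lapply(drugs, function(d) d$active_principles)), food_tokens))
  for (r in rules) {
    for (p in c(r$principle_a, r$principle_b)) {
      if (!p %in% known) {
        stop("interaction rule in ", context, " references unknown principle '", p,
             "' (not an active principle of any drug nor a food token)", call. = FALSE)
      }
    }
  }
  structure(list(drugs = drugs, interactions = rules, food_tokens = food_tokens),
            class = "knowledge_base")
}

#' Import the drug table from CSV
#'
#' CSV columns: `product_name`, `active_principles` (semicolon-separated),
#' `atc_code`, `max_daily_dose_per_kg`, `max_single_dose`,
#' `min_daily_dose_per_kg`, `food_relation`, `food_lead_min`, `food_lag_min`,
#' `administration_observations` (semicolon-separated),
#' `contraindicated_conditions` (semicolon-separated), `indication`.
#' Missing optional columns are allowed.  Interaction rules cannot be
#' expressed in CSV; combine with a JSON KB if rules are needed.
#'
#' @param path CSV file path.
#' @return a `knowledge_base` with the drugs and no interaction rules.
#' @export
load_drug_table_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("product_name", "active_principles") %in% names(df))) {
    stop("drug CSV must have product_name and active_principles columns", call. = FALSE)
  }
  col <- function(nm, default) if (nm %in% names(df)) df[[nm]] else rep(default, nrow(df))
  split_multi <- function(x) if (is.na(x) || !nzchar(x)) character() else strsplit(x, ";")[[1L]]
  blank_to <- function(x, default) ifelse(is.na(x) | !nzchar(as.character(x)), default, x)
  drugs <- lapply(seq_len(nrow(df)), function(i) {
    list(product_name = df$product_name[i],
         active_principles = as.list(split_multi(df$active_principles[i])),
         atc_code = col("atc_code", NA_character_)[i],
         max_daily_dose_per_kg = col("max_daily_dose_per_kg", NA_real_)[i],
         max_single_dose = col("max_single_dose", NA_real_)[i],
         min_daily_dose_per_kg = col("min_daily_dose_per_kg", NA_real_)[i],
         food_relation = blank_to(col("food_relation", "none")[i], "none"),
         food_lead_min = as.integer(blank_to(col("food_lead_min", 0L)[i], 0L)),
         food_lag_min = as.integer(blank_to(col("food_lag_min", 0L)[i], 0L)),
         administration_observations = as.list(split_multi(col("administration_observations", "")[i])),
         contraindicated_conditions = as.list(split_multi(col("contraindicated_conditions", "")[i])),
         indication = col("indication", NA_character_)[i])
  })
  kb_from_list(list(drugs = drugs, interactions = list(), food_tokens = list("FOOD", "MEAL")),
               context = path)
}

#' Resolve a prescription item to its active principles
#'
#' All comparisons between prescription items (interactions, duplication)
#' happen at the active-principle level, never at the product-name level, so
#' combination products contribute every constituent principle.
#'
#' @param item a prescription item (or a product name).
#' @param kb a `knowledge_base`.
#' @return character vector of canonical principle names.
#' @export
resolve_principles <- function(item, kb) {
  name <- if (inherits(item, "prescription_item")) item$drug else canonical_name(item)
  d <- kb$drugs[[name]]
  if (is.null(d)) stop("drug '", name, "' not found in knowledge base", call. = FALSE)
  d$active_principles
}

kb_drug <- function(kb, name) {
  d <- kb$drugs[[canonical_name(name)]]
  if (is.null(d)) stop("drug '", name, "' not found in knowledge base", call. = FALSE)
  d
}

# ---- case files -------------------------------------------------------------

#' Load a patient case file
#'
#' @param path path to a `case.json` file (blocks `patient`, `routine`,
#'   `prescription`, and optionally `planted` ground-truth metadata).
#' @return a `patient_case`; any `planted` block is attached as attribute
#'   `"planted"`.
#' @export
load_case <- function(path) {
  if (!file.exists(path)) stop("case file not found: ", path, call. = FALSE)
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  case_from_list(raw)
}

case_from_list <- function(raw) {
  p <- raw$patient
  r <- raw$routine
  rt <- routine(
    wake_time = r$wake_time, sleep_time = r$sleep_time,
    busy_intervals = lapply(r$busy_intervals %||% list(), unlist),
    meal_times = if (length(r$meal_times %||% list())) {
      stats::setNames(
        vapply(r$meal_times, function(m) m$time, ""),
        vapply(r$meal_times, function(m) m$label, "")
      )
    } else c()
  )
  items <- lapply(raw$prescription %||% list(), function(it) {
    new_prescription_item(
      drug = it$drug, dose_amount = it$dose_amount,
      doses_per_day = it$doses_per_day %||% NA_integer_,
      interval_hours = it$interval_hours %||% NA_real_,
      fixed_times = it$fixed_times,
      clinical_override_note = it$clinical_override_note %||% NA_character_
    )
  })
  case <- new_patient_case(
    case_id = raw$case_id, age = p$age, weight = p$weight %||% NA_real_,
    sex = p$sex %||% "unspecified",
    conditions = p$conditions %||% list(),
    routine = rt, prescription = items
  )
  if (!is.null(raw$planted)) attr(case, "planted") <- raw$planted
  case
}

# ---- serialization ----------------------------------------------------------

kb_to_list <- function(kb) {
  list(
    drugs = lapply(unname(kb$drugs), function(d) {
      out <- list(product_name = d$product_name,
                  active_principles = as.list(d$active_principles))
      if (!is.na(d$atc_code)) out$atc_code <- d$atc_code
      for (f in c("max_daily_dose_per_kg", "max_single_dose", "min_daily_dose_per_kg")) {
        if (!is.na(d[[f]])) out[[f]] <- d[[f]]
      }
      if (d$food_relation != "none") {
        out$food_relation <- d$food_relation
        out$food_lead_min <- d$food_lead_min
        out$food_lag_min <- d$food_lag_min
      }
      if (length(d$administration_observations)) {
        out$administration_observations <- as.list(d$administration_observations)
      }
      if (length(d$contraindicated_conditions)) {
        out$contraindicated_conditions <- as.list(d$contraindicated_conditions)
      }
      if (!is.na(d$indication)) out$indication <- d$indication
      out
    }),
    interactions = lapply(kb$interactions, function(r) {
      out <- list(principle_a = r$principle_a, principle_b = r$principle_b,
                  rule_type = r$rule_type)
      if (!is.na(r$min_interval)) out$min_interval <- r$min_interval
      if (nzchar(r$message)) out$message <- r$message
      out
    }),
    food_tokens = as.list(kb$food_tokens)
  )
}

case_to_list <- function(case) {
  r <- case$routine
  out <- list(
    case_id = case$case_id,
    patient = list(age = case$age, weight = case$weight, sex = case$sex,
                   conditions = case$conditions),
    routine = list(
      wake_time = format_clock(r$wake_time),
      sleep_time = format_clock(r$sleep_time),
      busy_intervals = lapply(r$busy_intervals, function(iv) as.list(format_clock(iv))),
      meal_times = if (length(r$meal_times)) {
        lapply(seq_along(r$meal_times), function(i) {
          list(label = names(r$meal_times)[i], time = format_clock(r$meal_times[[i]]))
        })
      } else list()
    ),
    prescription = lapply(case$prescription, function(it) {
      o <- list(drug = it$drug, dose_amount = it$dose_amount)
      if (!is.na(it$interval_hours)) o$interval_hours <- it$interval_hours
      else o$doses_per_day <- it$doses_per_day
      if (!is.null(it$fixed_times)) o$fixed_times <- as.list(format_clock(it$fixed_times))
      if (!is.na(it$clinical_override_note)) o$clinical_override_note <- it$clinical_override_note
      o
    })
  )
  if (!is.null(attr(case, "planted"))) out$planted <- attr(case, "planted")
  out
}

#' Serialize a knowledge base or patient case back to JSON
#'
#' Round-trip safe: `load_knowledge_base(save_json(kb, f))` is semantically
#' identical to `kb` (and likewise for cases).
#'
#' @param x a `knowledge_base` or `patient_case`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_json <- function(x, path) {
  lst <- if (inherits(x, "knowledge_base")) kb_to_list(x)
         else if (inherits(x, "patient_case")) case_to_list(x)
         else stop("cannot serialize object of class ", paste(class(x), collapse = "/"),
                   call. = FALSE)
  jsonlite::write_json(lst, path, auto_unbox = TRUE, pretty = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Path to a shipped fixture file
#'
#' @param file file name under the package's `fixtures/` data directory
#'   (e.g. `"kb.json"`, `"case01.json"`).
#' @return absolute path to the installed fixture.
#' @export
pharmsched_fixture <- function(file) {
  p <- system.file("extdata", "fixtures", file, package = "pharmsched")
  if (!nzchar(p)) stop("fixture not found: ", file, call. = FALSE)
  p
}

`%||%` <- function(a, b) if (is.null(a)) b else a
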