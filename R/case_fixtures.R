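# Executable fixtures: a minimal knowledge base and ten hypothetical
# planted-error cases, plus seeded generators for synthetic cases and
# synthetic paired ratings.
#
# Every dose limit, minimum interval and food lead/lag below is a FIXTURE
# VALUE chosen to make the planted scenario machine-checkable; none of them
# is clinical guidance.

PLANTED_CLASSES <- c("nu_pair", "daytime_routine", "night_routine", "min_interval",
                     "contraindication", "overdose", "food_relation",
                     "sleep_protection", "override_risk", "specific_guidelines")

# Drugs with no interaction rules, food relations, observations,
# contraindications or per-kg limits: the sampling pool for clean synthetic
# cases (all 5-char ATC prefixes distinct, so no class-level duplication).
CLEAN_DRUG_POOL <- c("PARACETAMOL 500 MG", "LOSARTAN 50 MG", "AMLODIPINE 5 MG",
                     "CETIRIZINE 10 MG", "FOLIC ACID 5 MG", "ENALAPRIL 10 MG",
                     "METOPROLOL 50 MG")

fixture_kb_list <- function() {
  drug <- function(name, principles, atc, ...) {
    c(list(product_name = name, active_principles = as.list(principles), atc_code = atc),
      list(...))
  }
  list(
    drugs = list(
      drug("ASPIRIN 500 MG", "ACETYLSALICYLIC ACID", "N02BA01"),
      drug("WARFARIN 2.5 MG", "WARFARIN", "B01AA03"),
      drug("DIGOXIN 0.25 MG", "DIGOXIN", "C01AA05"),
      drug("MYLANTA PLUS", c("ALUMINUM HYDROXIDE", "MAGNESIUM HYDROXIDE", "SIMETHICONE"),
           "A02AD01"),
      drug("ATORVASTATIN CALCIUM 20 MG", "ATORVASTATIN", "C10AA05",
           contraindicated_conditions = list("severe_hepatic_disease")),
      drug("SIMVASTATIN 20 MG", "SIMVASTATIN", "C10AA01",
           contraindicated_conditions = list("severe_hepatic_disease")),
      drug("AZITHROMYCIN SUSPENSION 200 MG", "AZITHROMYCIN", "J01FA10",
           max_daily_dose_per_kg = 10, min_daily_dose_per_kg = 5),
      drug("OMEPRAZOLE 20 MG", "OMEPRAZOLE", "A02BC01",
           food_relation = "empty_stomach", food_lead_min = 30),
      drug("AMOXICILLIN 250 MG", "AMOXICILLIN", "J01CA04",
           max_daily_dose_per_kg = 90),
      drug("CARBAMAZEPINE 200 MG", "CARBAMAZEPINE", "N03AF01",
           contraindicated_conditions = list("pregnancy")),
      drug("ALENDRONATE SODIUM 70 MG", "ALENDRONIC ACID", "M05BA04",
           food_relation = "empty_stomach", food_lead_min = 30,
           administration_observations = list(
             "Take upon waking with a full glass of water",
             "Remain standing for at least 20 min after taking")),
      drug("LEVOTHYROXINE 50 MCG", "LEVOTHYROXINE SODIUM", "H03AA01",
           food_relation = "empty_stomach", food_lead_min = 30,
           administration_observations = list(
             "Take at least 30 min before the first meal of the day")),
      drug("PARACETAMOL 500 MG", "PARACETAMOL", "N02BE01"),
      drug("TYLENOL 750 MG", "PARACETAMOL", "N02BE01"),
      drug("METFORMIN 500 MG", "METFORMIN", "A10BA02",
           food_relation = "with_food", food_lead_min = 15, food_lag_min = 60),
      drug("LOSARTAN 50 MG", "LOSARTAN POTASSIUM", "C09CA01"),
      drug("AMLODIPINE 5 MG", "AMLODIPINE", "C08CA01"),
      drug("CETIRIZINE 10 MG", "CETIRIZINE", "R06AE07"),
      drug("FOLIC ACID 5 MG", "FOLIC ACID", "B03BB01"),
      drug("ENALAPRIL 10 MG", "ENALAPRIL MALEATE", "C09AA02"),
      drug("METOPROLOL 50 MG", "METOPROLOL TARTRATE", "C07AB02")
    ),
    interactions = list(
      list(principle_a = "ACETYLSALICYLIC ACID", principle_b = "WARFARIN",
           rule_type = "NU", message = "concomitant use increases bleeding risk"),
      list(principle_a = "DIGOXIN", principle_b = "ALUMINUM HYDROXIDE",
           rule_type = "S", min_interval = 120L,
           message = "antacids reduce digoxin absorption"),
      list(principle_a = "ALENDRONIC ACID", principle_b = "LEVOTHYROXINE SODIUM",
           rule_type = "S", min_interval = 30L,
           message = "separate administration to preserve absorption")
    ),
    food_tokens = list("FOOD", "MEAL")
  )
}

#' The fixture knowledge base
#'
#' A ~20-product knowledge base containing exactly what the ten built-in
#' hypothetical cases and the synthetic generators need; it is not a
#' clinical formulary and its thresholds are fixture values.
#'
#' @return a `knowledge_base`.
#' @export
fixture_kb <- function() kb_from_list(fixture_kb_list(), context = "<fixture kb>")

default_routine_list <- function() {
  list(wake_time = "07:00", sleep_time = "22:00", busy_intervals = list(),
       meal_times = list(list(label = "breakfast", time = "07:30"),
                         list(label = "lunch", time = "12:30"),
                         list(label = "dinner", time = "19:00")))
}

child_routine_list <- function() {
  list(wake_time = "07:00", sleep_time = "20:00", busy_intervals = list(),
       meal_times = list(list(label = "breakfast", time = "07:30"),
                         list(label = "lunch", time = "12:00"),
                         list(label = "dinner", time = "18:30")))
}

builtin_case_lists <- function() {
  mk <- function(id, class, expected_types, age, weight, sex, conditions, routine,
                 prescription, feasible = TRUE) {
    list(case_id = id,
         patient = list(age = age, weight = weight, sex = sex, conditions = conditions),
         routine = routine, prescription = prescription,
         planted = list(error_class = class,
                        expected_alert_types = as.list(expected_types),
                        expected_feasible = feasible))
  }
  item <- function(drug, dose, ...) c(list(drug = drug, dose_amount = dose), list(...))
  list(
    mk("case01", "nu_pair", "nu_interaction", 58, 72, "M", list(),
       default_routine_list(),
       list(item("ASPIRIN 500 MG", 500, doses_per_day = 2L),
            item("WARFARIN 2.5 MG", 2.5, doses_per_day = 1L))),
    mk("case02", "daytime_routine", character(), 35, 70, "F",
       list(),
       list(wake_time = "07:00", sleep_time = "22:00",
            busy_intervals = list(list("08:00", "12:00"), list("13:00", "18:00")),
            meal_times = list(list(label = "breakfast", time = "07:30"),
                              list(label = "lunch", time = "12:30"),
                              list(label = "dinner", time = "19:00"))),
       list(item("PARACETAMOL 500 MG", 500, doses_per_day = 3L),
            item("LOSARTAN 50 MG", 50, doses_per_day = 1L),
            item("AMLODIPINE 5 MG", 5, doses_per_day = 1L))),
    mk("case03", "night_routine", character(), 42, 80, "M", list(),
       list(wake_time = "14:30", sleep_time = "07:30",
            busy_intervals = list(list("22:00", "06:00")),
            meal_times = list(list(label = "breakfast", time = "15:00"),
                              list(label = "dinner", time = "21:00"),
                              list(label = "supper", time = "06:30"))),
       list(item("LOSARTAN 50 MG", 50, doses_per_day = 1L),
            item("PARACETAMOL 500 MG", 500, doses_per_day = 3L))),
    mk("case04", "min_interval", "min_interval_needed", 67, 65, "F", list(),
       list(wake_time = "07:00", sleep_time = "23:00", busy_intervals = list(),
            meal_times = list(list(label = "breakfast", time = "07:30"),
                              list(label = "lunch", time = "12:30"),
                              list(label = "dinner", time = "19:00"))),
       list(item("DIGOXIN 0.25 MG", 0.25, doses_per_day = 1L),
            item("MYLANTA PLUS", 10, doses_per_day = 3L))),
    mk("case05", "contraindication", "contraindication", 61, 78, "M",
       list(list(code = "severe_hepatic_disease")),
       default_routine_list(),
       list(item("ATORVASTATIN CALCIUM 20 MG", 20, doses_per_day = 1L),
            item("PARACETAMOL 500 MG", 500, doses_per_day = 2L))),
    mk("case06", "overdose", "overdose", 2, 13, "M", list(),
       child_routine_list(),
       list(item("AZITHROMYCIN SUSPENSION 200 MG", 200, doses_per_day = 1L))),
    mk("case07", "food_relation", "food_relation", 45, 68, "F", list(),
       default_routine_list(),
       list(item("OMEPRAZOLE 20 MG", 20, doses_per_day = 1L),
            item("CETIRIZINE 10 MG", 10, doses_per_day = 1L))),
    mk("case08", "sleep_protection", character(), 6, 20, "F", list(),
       child_routine_list(),
       list(item("AMOXICILLIN 250 MG", 250, interval_hours = 8))),
    mk("case09", "override_risk", "contraindication", 28, 64, "F",
       list(list(code = "pregnancy", pregnancy_weeks = 12)),
       default_routine_list(),
       list(item("CARBAMAZEPINE 200 MG", 200, doses_per_day = 2L,
                 clinical_override_note = "epilepsy crises: risk accepted by clinical decision"))),
    mk("case10", "specific_guidelines", "observation", 66, 59, "F", list(),
       default_routine_list(),
       list(item("ALENDRONATE SODIUM 70 MG", 70, doses_per_day = 1L),
            item("LEVOTHYROXINE 50 MCG", 50, doses_per_day = 1L)))
  )
}

#' The ten built-in hypothetical cases
#'
#' Each case plants exactly one inconsistency class (or a routine situation
#' demanding a specific scheduling behaviour) and carries machine-checkable
#' ground truth in its `planted` attribute: the error class, the alert types
#' the review must emit, and whether the scheduler must find a feasible
#' schedule.
#'
#' @return list of 10 `patient_case` objects, ids `case01`..`case10`.
#' @examples
#' length(builtin_cases())
#' attr(builtin_cases()[[1]], "planted")$error_class
#' @export
builtin_cases <- function() {
  lapply(builtin_case_lists(), case_from_list)
}

#' Generate a synthetic patient case with a planted inconsistency
#'
#' Reproducible from the seed.  With `error_class = "none"` only drugs free
#' of any knowledge-base rule are sampled, so the review yields zero alerts
#' by construction; otherwise the clean base is augmented with exactly one
#' inconsistency of the requested class.
#'
#' @param error_class one of the planted classes (see the ten built-in
#'   cases) or `"none"`.
#' @param seed integer seed.
#' @param kb knowledge base (defaults to [fixture_kb()]).
#' @return a `patient_case` with `planted` ground-truth attribute.
#' @export
generate_case <- function(error_class, seed, kb = fixture_kb()) {
  if (!error_class %in% c(PLANTED_CLASSES, "none")) {
    stop("unknown error class '", error_class, "'", call. = FALSE)
  }
  run_seeded(seed, {
    wake <- 360L + 15L * sample.int(8L, 1L)            # 06:15 .. 08:00
    sleep <- 1260L + 15L * sample.int(8L, 1L)          # 21:15 .. 23:00
    rt <- list(wake_time = format_clock(wake), sleep_time = format_clock(sleep),
               busy_intervals = list(),
               meal_times = list(list(label = "breakfast", time = format_clock(wake + 30L)),
                                 list(label = "lunch", time = "12:30"),
                                 list(label = "dinner", time = "19:00")))
    n_clean <- sample(3:min(8L, length(CLEAN_DRUG_POOL)), 1L)
    pool <- sample(CLEAN_DRUG_POOL, n_clean)
    strength <- function(nm) kb_drug(kb, nm)$product_name  # validated lookup
    items <- lapply(pool, function(nm) {
      strength(nm)
      list(drug = nm, dose_amount = as.numeric(sub("^.* (\\d+(\\.\\d+)?) M.*$", "\\1", nm)),
           doses_per_day = sample.int(3L, 1L))
    })
    age <- sample(25:75, 1L)
    weight <- round(stats::runif(1L, 55, 95), 1)
    sex <- sample(c("F", "M"), 1L)
    conditions <- list()
    expected <- character()
    feasible <- TRUE

    add_item <- function(drug, dose, ...) {
      items[[length(items) + 1L]] <<- c(list(drug = drug, dose_amount = dose), list(...))
    }
    if (error_class == "nu_pair") {
      add_item("ASPIRIN 500 MG", 500, doses_per_day = 2L)
      add_item("WARFARIN 2.5 MG", 2.5, doses_per_day = 1L)
      expected <- "nu_interaction"
    } else if (error_class == "daytime_routine") {
      rt$busy_intervals <- list(list("08:00", "12:00"), list("13:00", "18:00"))
    } else if (error_class == "night_routine") {
      rt$wake_time <- "14:30"; rt$sleep_time <- "07:30"
      rt$busy_intervals <- list(list("22:00", "06:00"))
      rt$meal_times <- list(list(label = "breakfast", time = "15:00"),
                            list(label = "dinner", time = "21:00"),
                            list(label = "supper", time = "06:30"))
    } else if (error_class == "min_interval") {
      add_item("DIGOXIN 0.25 MG", 0.25, doses_per_day = 1L)
      add_item("MYLANTA PLUS", 10, doses_per_day = 3L)
      expected <- "min_interval_needed"
    } else if (error_class == "contraindication") {
      conditions <- list(list(code = "severe_hepatic_disease"))
      add_item("ATORVASTATIN CALCIUM 20 MG", 20, doses_per_day = 1L)
      expected <- "contraindication"
    } else if (error_class == "overdose") {
      age <- 2; weight <- 13
      items <- list(list(drug = "PARACETAMOL 500 MG", dose_amount = 250,
                         doses_per_day = 2L))
      add_item("AZITHROMYCIN SUSPENSION 200 MG", 200, doses_per_day = 1L)
      expected <- "overdose"
    } else if (error_class == "food_relation") {
      add_item("OMEPRAZOLE 20 MG", 20, doses_per_day = 1L)
      expected <- "food_relation"
    } else if (error_class == "sleep_protection") {
      age <- 6; weight <- 20
      rt$sleep_time <- "20:00"; rt$wake_time <- "07:00"
      items <- list(list(drug = "AMOXICILLIN 250 MG", dose_amount = 250,
                         interval_hours = 8))
    } else if (error_class == "override_risk") {
      sex <- "F"; age <- sample(20:40, 1L)
      conditions <- list(list(code = "pregnancy", pregnancy_weeks = sample(6:30, 1L)))
      add_item("CARBAMAZEPINE 200 MG", 200, doses_per_day = 2L,
               clinical_override_note = "risk accepted by clinical decision")
      expected <- "contraindication"
    } else if (error_class == "specific_guidelines") {
      add_item("ALENDRONATE SODIUM 70 MG", 70, doses_per_day = 1L)
      expected <- "observation"
    }
    case_from_list(list(
      case_id = sprintf("synthetic-%s-%d", error_class, seed),
      patient = list(age = age, weight = weight, sex = sex, conditions = conditions),
      routine = rt, prescription = items,
      planted = list(error_class = error_class,
                     expected_alert_types = as.list(expected),
                     expected_feasible = feasible)
    ))
  })
}

#' Generate paired ordinal ratings with a target chance-corrected agreement
#'
#' Mixture construction: rater A draws from the category marginals; with
#' probability `p` rater B copies A's label, otherwise B draws independently
#' from the same marginals.  Under this construction the expected weighted
#' kappa equals `p` exactly, for every disagreement-weight scheme, so the
#' calibration is `p = target`.
#'
#' @param n_units number of rated units.
#' @param marginals category probabilities (sum to 1).
#' @param target target kappa in `[0, 1]`.
#' @param seed integer seed.
#' @return list with rating vectors `a` and `b`.
#' @export
generate_ratings <- function(n_units, marginals = c(0.5, 0.3, 0.2), target = 0.5, seed = 1L) {
  if (abs(sum(marginals) - 1) > 1e-9) stop("marginals must sum to 1", call. = FALSE)
  if (target < 0 || target > 1) {
    stop("target kappa ", target, " unreachable by the mixture construction (need [0, 1])",
         call. = FALSE)
  }
  k <- length(marginals)
  run_seeded(seed, {
    a <- sample.int(k, n_units, replace = TRUE, prob = marginals)
    copy <- stats::runif(n_units) < target
    b <- ifelse(copy, a, sample.int(k, n_units, replace = TRUE, prob = marginals))
    list(a = a, b = b)
  })
}

#' Write the fixture KB and the ten built-in cases as JSON files
#'
#' @param dir output directory (created if needed).
#' @return the written file paths, invisibly.
#' @export
write_fixture_files <- function(dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, "kb.json")
  save_json(fixture_kb(), paths)
  for (case in builtin_cases()) {
    p <- file.path(dir, paste0(case$case_id, ".json"))
    save_json(case, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
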