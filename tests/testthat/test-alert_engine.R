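kb_fix <- fixture_kb()

test_that("NU pairs: one blocking alert per matching principle pair", {
  case <- load_case(pharmsched_fixture("case01.json"))
  alerts <- check_nu_pairs(case$prescription, kb_fix)
  expect_length(alerts, 1)
  expect_equal(alerts[[1]]$alert_type, "nu_interaction")
  expect_equal(alerts[[1]]$severity, "blocking")
  expect_equal(alerts[[1]]$items_involved, c(1L, 2L))

  single <- make_case(prescription = list(rx("ASPIRIN 500 MG", 500, doses_per_day = 1)))
  expect_length(check_nu_pairs(single$prescription, kb_fix), 0)
})

test_that("NU pair scan equals a brute-force double loop over item pairs", {
  kb <- make_kb(
    drugs = list(kb_drug_spec("D1", "P1"), kb_drug_spec("D2", "P2"),
                 kb_drug_spec("D3", "P3"), kb_drug_spec("D4", c("P1", "P4")),
                 kb_drug_spec("D5", "P5")),
    interactions = list(
      list(principle_a = "P1", principle_b = "P2", rule_type = "NU"),
      list(principle_a = "P1", principle_b = "P3", rule_type = "NU"))
  )
  # three items where items 1-2 and 1-3 each match an NU rule -> 2 alerts
  case <- make_case(prescription = list(rx("D1", 1, doses_per_day = 1),
                                        rx("D2", 1, doses_per_day = 1),
                                        rx("D3", 1, doses_per_day = 1)))
  expect_length(check_nu_pairs(case$prescription, kb), 2)

  # randomized prescriptions vs an independent double-loop oracle
  set.seed(77)
  pool <- c("D1", "D2", "D3", "D4", "D5")
  for (trial in 1:25) {
    drugs <- sample(pool, sample(2:5, 1), replace = FALSE)
    case <- make_case(prescription = lapply(drugs, function(d) rx(d, 1, doses_per_day = 1)))
    got <- length(check_nu_pairs(case$prescription, kb))
    pr <- lapply(case$prescription, resolve_principles, kb = kb)
    want <- 0
    nu <- list(c("P1", "P2"), c("P1", "P3"))
    for (i in seq_along(pr)) for (j in seq_along(pr)) {
      if (i < j) for (rule in nu) {
        hit <- (rule[1] %in% pr[[i]] && rule[2] %in% pr[[j]]) ||
               (rule[2] %in% pr[[i]] && rule[1] %in% pr[[j]])
        if (hit) want <- want + 1
      }
    }
    expect_equal(got, want)
  }
})

test_that("contraindications respect conditions and clinical overrides", {
  cirrhosis <- load_case(pharmsched_fixture("case05.json"))
  alerts <- check_contraindications(cirrhosis, kb_fix)
  expect_length(alerts, 1)
  expect_equal(alerts[[1]]$severity, "blocking")
  expect_false(alerts[[1]]$overridden)

  pregnant <- load_case(pharmsched_fixture("case09.json"))
  alerts <- check_contraindications(pregnant, kb_fix)
  expect_length(alerts, 1)
  expect_true(alerts[[1]]$overridden)
  expect_match(alerts[[1]]$justification, "clinical decision")
  # the pre-overridden alert never blocks the pipeline
  expect_false(review_prescription(pregnant, kb_fix)$has_unresolved_blocking)

  clean <- make_case(prescription = list(rx("ATORVASTATIN CALCIUM 20 MG", 20,
                                            doses_per_day = 1)))
  expect_length(check_contraindications(clean, kb_fix), 0)
})

test_that("duplication: shared principle, and ATC subgroup as a warning tier", {
  same_principle <- make_case(prescription = list(
    rx("PARACETAMOL 500 MG", 500, doses_per_day = 2),
    rx("TYLENOL 750 MG", 750, doses_per_day = 1)))
  alerts <- check_duplication(same_principle$prescription, kb_fix)
  expect_length(alerts, 1)
  expect_match(alerts[[1]]$message, "PARACETAMOL")

  distinct <- make_case(prescription = list(
    rx("LOSARTAN 50 MG", 50, doses_per_day = 1),
    rx("AMLODIPINE 5 MG", 5, doses_per_day = 1),
    rx("CETIRIZINE 10 MG", 10, doses_per_day = 1)))
  expect_length(check_duplication(distinct$prescription, kb_fix), 0)

  statins <- make_case(prescription = list(
    rx("ATORVASTATIN CALCIUM 20 MG", 20, doses_per_day = 1),
    rx("SIMVASTATIN 20 MG", 20, doses_per_day = 1)))
  alerts <- check_duplication(statins$prescription, kb_fix)
  expect_length(alerts, 1)
  expect_equal(alerts[[1]]$severity, "warning")
  expect_match(alerts[[1]]$message, "C10AA")
})

test_that("dose checks: per-kg overdose, boundary compliance, missing limits and weight", {
  over <- load_case(pharmsched_fixture("case06.json"))   # 13 kg, 200 mg once = 15.4/kg/day
  alerts <- check_dose(over, kb_fix)
  expect_length(alerts, 1)
  expect_equal(alerts[[1]]$alert_type, "overdose")

  # exactly at the limit: 13 kg * 10 mg/kg = 130 mg -> compliant
  at_limit <- make_case(weight = 13, prescription = list(
    rx("AZITHROMYCIN SUSPENSION 200 MG", 130, doses_per_day = 1)))
  expect_length(check_dose(at_limit, kb_fix), 0)

  # below the fixture minimum -> underdose
  under <- make_case(weight = 13, prescription = list(
    rx("AZITHROMYCIN SUSPENSION 200 MG", 30, doses_per_day = 1)))
  alerts <- check_dose(under, kb_fix)
  expect_length(alerts, 1)
  expect_equal(alerts[[1]]$alert_type, "underdose")

  no_limits <- make_case(prescription = list(rx("LOSARTAN 50 MG", 5000, doses_per_day = 3)))
  expect_length(check_dose(no_limits, kb_fix), 0)

  # per-kg limit but unknown weight: explicit cannot-evaluate, not silence
  noweight <- make_case(weight = NA, prescription = list(
    rx("AZITHROMYCIN SUSPENSION 200 MG", 200, doses_per_day = 1)))
  alerts <- check_dose(noweight, kb_fix)
  expect_length(alerts, 1)
  expect_match(alerts[[1]]$message, "cannot evaluate")
})

test_that("food relations and observations surface as info alerts", {
  omz <- make_case(prescription = list(rx("OMEPRAZOLE 20 MG", 20, doses_per_day = 1)))
  alerts <- check_food_and_observations(omz$prescription, kb_fix)
  expect_length(alerts, 1)
  expect_equal(alerts[[1]]$alert_type, "food_relation")
  expect_match(alerts[[1]]$message, "empty stomach")

  ale <- make_case(prescription = list(rx("ALENDRONATE SODIUM 70 MG", 70, doses_per_day = 1)))
  alerts <- check_food_and_observations(ale$prescription, kb_fix)
  types <- vapply(alerts, function(a) a$alert_type, "")
  expect_true("observation" %in% types)
  expect_match(alerts[[which(grepl("standing", vapply(alerts, function(a) a$message, "")))]]$message,
               "at least 20 min")

  plain <- make_case(prescription = list(rx("LOSARTAN 50 MG", 50, doses_per_day = 1)))
  expect_length(check_food_and_observations(plain$prescription, kb_fix), 0)
})

test_that("review aggregates all checks, stably ordered and deterministic", {
  # plant overdose + contraindication together: both classes present
  case <- make_case(weight = 13,
                    conditions = list(list(code = "severe_hepatic_disease")),
                    prescription = list(
                      rx("AZITHROMYCIN SUSPENSION 200 MG", 200, doses_per_day = 1),
                      rx("ATORVASTATIN CALCIUM 20 MG", 20, doses_per_day = 1)))
  report <- review_prescription(case, kb_fix)
  expect_setequal(alert_types_of(report), c("overdose", "contraindication"))
  sev <- vapply(report$alerts, function(a) a$severity, "")
  expect_true(!is.unsorted(match(sev, c("blocking", "warning", "info"))))
  expect_equal(vapply(report$alerts, function(a) a$id, ""),
               paste0("A", seq_along(report$alerts)))

  clean <- make_case(prescription = list(rx("LOSARTAN 50 MG", 50, doses_per_day = 1)))
  expect_length(review_prescription(clean, kb_fix)$alerts, 0)
  expect_false(review_prescription(clean, kb_fix)$has_unresolved_blocking)

  # byte-for-byte determinism after serialization
  j1 <- jsonlite::toJSON(pharmsched:::alert_report_to_list(report), auto_unbox = TRUE)
  j2 <- jsonlite::toJSON(pharmsched:::alert_report_to_list(review_prescription(case, kb_fix)),
                         auto_unbox = TRUE)
  expect_identical(as.character(j1), as.character(j2))
})

test_that("overrides keep the alert, recompute the gate, and reject unknown ids", {
  case <- load_case(pharmsched_fixture("case01.json"))
  report <- review_prescription(case, kb_fix)
  expect_true(report$has_unresolved_blocking)
  report2 <- apply_override(report, "A1", "risk acceptable for this patient")
  expect_false(report2$has_unresolved_blocking)
  expect_true(report2$alerts[[1]]$overridden)
  expect_equal(report2$alerts[[1]]$message, report$alerts[[1]]$message)
  expect_error(apply_override(report, "A99", "x"), "unknown alert id")

  # two blocking alerts: overriding one is not enough
  two <- make_case(conditions = list(list(code = "severe_hepatic_disease")),
                   prescription = list(
                     rx("ASPIRIN 500 MG", 500, doses_per_day = 1),
                     rx("WARFARIN 2.5 MG", 2.5, doses_per_day = 1),
                     rx("ATORVASTATIN CALCIUM 20 MG", 20, doses_per_day = 1)))
  rep2 <- review_prescription(two, kb_fix)
  expect_equal(sum(vapply(rep2$alerts, function(a) a$severity == "blocking", TRUE)), 2)
  rep2 <- apply_override(rep2, rep2$alerts[[1]]$id, "first handled")
  expect_true(rep2$has_unresolved_blocking)

  # overriding an info alert only flips its flag
  omz <- make_case(prescription = list(rx("OMEPRAZOLE 20 MG", 20, doses_per_day = 1)))
  rep3 <- review_prescription(omz, kb_fix)
  rep3b <- apply_override(rep3, "A1", "noted")
  expect_false(rep3b$has_unresolved_blocking)
  expect_true(rep3b$alerts[[1]]$overridden)
})

test_that("clean synthetic prescriptions trigger zero alerts (soundness)", {
  for (seed in 1:25) {
    case <- generate_case("none", seed)
    expect_length(review_prescription(case, kb_fix)$alerts, 0)
  }
})
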