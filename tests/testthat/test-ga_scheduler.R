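kb_fix <- fixture_kb()

clean_report <- function(case, kb) {
  report <- review_prescription(case, kb)
  for (a in report$alerts) {
    if (a$severity == "blocking" && !a$overridden) {
      report <- apply_override(report, a$id, "test override")
    }
  }
  report
}

test_that("constraint compilation maps rules, routine and prescription to typed constraints", {
  case <- load_case(pharmsched_fixture("case04.json"))
  cs <- build_constraints(case, kb_fix, review_prescription(case, kb_fix))
  expect_length(cs$pairwise, 1)
  expect_equal(cs$pairwise[[1]]$min_interval, 120L)
  expect_match(cs$pairwise[[1]]$provenance, "DIGOXIN")
  expect_equal(cs$n_genes, 4L)  # 1 digoxin + 3 antacid doses

  omz <- make_case(prescription = list(rx("OMEPRAZOLE 20 MG", 20, doses_per_day = 1)))
  cs2 <- build_constraints(omz, kb_fix, review_prescription(omz, kb_fix))
  expect_length(cs2$food, 1)
  expect_equal(cs2$food[[1]]$type, "empty_stomach")
  expect_equal(cs2$food[[1]]$lead, 30L)

  plain <- make_case(prescription = list(rx("LOSARTAN 50 MG", 50, doses_per_day = 2)))
  cs3 <- build_constraints(plain, kb_fix, review_prescription(plain, kb_fix))
  expect_length(cs3$pairwise, 0)
  expect_length(cs3$food, 0)
  expect_length(cs3$spacing, 1)

  # the alert gate: unresolved blocking alerts refuse scheduling by name
  nu <- load_case(pharmsched_fixture("case01.json"))
  expect_error(build_constraints(nu, kb_fix, review_prescription(nu, kb_fix)),
               "unresolved blocking")
})

test_that("fitness is zero iff clean, scores shortfalls in minutes, and is linear in weights", {
  kb <- spaced_pair_kb(120L)
  case <- make_case(prescription = list(rx("DRUG A", 1, doses_per_day = 1),
                                        rx("DRUG B", 1, doses_per_day = 1)))
  cs <- build_constraints(case, kb, review_prescription(case, kb))
  w <- default_penalty_weights()
  w[] <- 1  # unit weights isolate raw magnitudes

  # 08:00 and 12:00: every constraint met
  ok <- fitness(parse_clock(c("08:00", "12:00")) / 30, cs, w)
  expect_equal(ok$total, 0)

  # 60 min apart under a 120 min requirement, weight 1/min -> penalty 60
  short <- fitness(parse_clock(c("08:00", "09:00")) / 30, cs, w)
  expect_equal(unname(short$breakdown["pairwise"]), 60)
  expect_equal(short$total, 60)

  # homogeneity: doubling every weight exactly doubles the total
  w2 <- w * 2
  expect_equal(fitness(parse_clock(c("08:00", "09:00")) / 30, cs, w2)$total,
               2 * short$total)
  expect_error(fitness(c(1, 2, 3), cs, w), "length")
})

test_that("sleep depth, spacing tolerance and food anchors score as documented", {
  case <- make_case(prescription = list(rx("PARACETAMOL 500 MG", 500, doses_per_day = 2)))
  cs <- build_constraints(case, kb_fix, review_prescription(case, kb_fix))
  w <- default_penalty_weights(); w[] <- 1
  # both doses awake, 12h apart: clean
  expect_equal(fitness(parse_clock(c("08:00", "20:00")) / 30, cs, w)$total, 0)
  # a dose at 23:00 sits 60 min deep in the 22:00-07:00 sleep window
  f <- fitness(parse_clock(c("08:00", "23:00")) / 30, cs, w)
  expect_gt(unname(f$breakdown["sleep"]), 0)
  # spacing: 10h apart = 120 min off the 12h target, 60 beyond tolerance
  f2 <- fitness(parse_clock(c("08:00", "18:00")) / 30, cs, w)
  expect_equal(unname(f2$breakdown["spacing"]), 2 * (120 - 60))  # both cyclic gaps deviate

  omz <- make_case(prescription = list(rx("OMEPRAZOLE 20 MG", 20, doses_per_day = 1)))
  cso <- build_constraints(omz, kb_fix, review_prescription(omz, kb_fix))
  # 07:00 is exactly 30 min before breakfast: allowed
  expect_equal(fitness(parse_clock("07:00") / 30, cso, w)$total, 0)
  # 08:00 is 30 min after breakfast, inside the empty-stomach halo
  expect_gt(fitness(parse_clock("08:00") / 30, cso, w)$total, 0)
})

test_that("the GA solves unconstrained and fixture instances and is reproducible", {
  single <- make_case(prescription = list(rx("LOSARTAN 50 MG", 50, doses_per_day = 1)))
  cs <- build_constraints(single, kb_fix, review_prescription(single, kb_fix))
  res <- evolve(cs, ga_config(random_seed = 1))
  expect_equal(res$fitness, 0)
  expect_true(res$feasible)
  t <- res$schedule[[1]]$times_min
  expect_true(t >= parse_clock("07:00") && t < parse_clock("22:00"))

  case4 <- load_case(pharmsched_fixture("case04.json"))
  cs4 <- build_constraints(case4, kb_fix, review_prescription(case4, kb_fix))
  res4 <- evolve(cs4, ga_config(random_seed = 42))
  expect_equal(res4$fitness, 0)
  digoxin <- res4$schedule[[1]]$times_min
  for (tb in res4$schedule[[2]]$times_min) {
    gap <- min(abs(digoxin - tb), 1440 - abs(digoxin - tb))
    expect_gte(gap, 120)
  }

  # identical (constraints, config, seed) -> identical result
  res4b <- evolve(cs4, ga_config(random_seed = 42))
  expect_identical(res4$chromosome, res4b$chromosome)
  expect_identical(res4$best_history, res4b$best_history)
})

test_that("infeasible instances return the best effort with violations listed", {
  kb <- spaced_pair_kb(120L)
  case <- make_case(prescription = list(
    rx("DRUG A", 1, doses_per_day = 1, fixed_times = list("09:00")),
    rx("DRUG B", 1, doses_per_day = 1, fixed_times = list("09:00"))))
  cs <- build_constraints(case, kb, review_prescription(case, kb))
  res <- evolve(cs, ga_config(random_seed = 3))
  expect_false(res$feasible)
  expect_gt(res$fitness, 0)
  classes <- vapply(res$violations, function(v) v$class, "")
  expect_true("pairwise" %in% classes || "pin" %in% classes)
  mags <- vapply(res$violations, function(v) v$magnitude, 0)
  expect_true(all(mags > 0))
})

test_that("exhaustive search matches hand-computed optima and guards its space", {
  kb <- spaced_pair_kb(120L)
  one <- make_case(prescription = list(rx("DRUG C", 1, doses_per_day = 1)))
  cs1 <- build_constraints(one, kb, review_prescription(one, kb))
  expect_equal(brute_force_schedule(cs1)$optimum, 0)

  two <- make_case(prescription = list(rx("DRUG A", 1, doses_per_day = 1),
                                       rx("DRUG B", 1, doses_per_day = 1)))
  cs2 <- build_constraints(two, kb, review_prescription(two, kb))
  bf <- brute_force_schedule(cs2)
  expect_equal(bf$optimum, 0)
  gap <- abs(diff(bf$chromosome * 30))
  expect_gte(min(gap, 1440 - gap), 120)

  # over-constrained toy: both doses pinned 60 min apart under a 120 min rule;
  # minimal hand-computed penalty = 60 min shortfall * pairwise weight
  pinned <- make_case(prescription = list(
    rx("DRUG A", 1, doses_per_day = 1, fixed_times = list("09:00")),
    rx("DRUG B", 1, doses_per_day = 1, fixed_times = list("10:00"))))
  cs3 <- build_constraints(pinned, kb, review_prescription(pinned, kb))
  bf3 <- brute_force_schedule(cs3)
  w <- default_penalty_weights()
  # moving either dose off its pin trades 1 min of pin penalty per min of
  # shortfall at equal weight; enumeration must find the joint minimum 60*w
  expect_equal(bf3$optimum, 60 * w[["pairwise"]])

  big <- make_case(prescription = list(rx("DRUG A", 1, doses_per_day = 3),
                                       rx("DRUG B", 1, doses_per_day = 3)))
  cs_big <- build_constraints(big, kb, review_prescription(big, kb))
  expect_error(brute_force_schedule(cs_big), "too large")
})

test_that("best-so-far fitness never increases and feasibility is independently confirmed", {
  set.seed(5)
  for (trial in 1:10) {
    kb <- spaced_pair_kb(sample(c(60L, 120L, 180L), 1))
    n_b <- sample(1:2, 1)
    case <- make_case(prescription = list(
      rx("DRUG A", 1, doses_per_day = sample(1:2, 1)),
      rx("DRUG B", 1, doses_per_day = n_b)))
    cs <- build_constraints(case, kb, review_prescription(case, kb))
    res <- evolve(cs, ga_config(random_seed = 1000 + trial,
                                population_size = 60L, generations = 80L))
    expect_true(all(diff(res$best_history) <= 0))
    if (res$feasible) {
      expect_length(verify_hard_constraints(res, cs), 0)
    } else {
      expect_gt(length(verify_hard_constraints(res, cs)), 0)
    }
    # result times lie on the slot grid
    for (s in res$schedule) expect_true(all(s$times_min %% 30 == 0))
  }
})

test_that("user interventions become soft preference rules that shape reruns", {
  case <- make_case(prescription = list(rx("PARACETAMOL 500 MG", 500, doses_per_day = 2),
                                        rx("LOSARTAN 50 MG", 50, doses_per_day = 1),
                                        rx("AMLODIPINE 5 MG", 5, doses_per_day = 1)))
  report <- review_prescription(case, kb_fix)
  cs <- build_constraints(case, kb_fix, report)
  res <- evolve(cs, ga_config(random_seed = 9))

  store <- record_intervention(res, list(drug = "LOSARTAN 50 MG", action = "isolate",
                                         separation_min = 90), preference_store())
  expect_length(store$rules, 1)
  expect_equal(store$rules[[1]]$kind, "administer_alone")

  # empty edit leaves the store unchanged
  expect_length(record_intervention(res, list(), store)$rules, 1)
  expect_error(record_intervention(res, list(drug = "GHOST", action = "isolate",
                                             separation_min = 10), store),
               "not in the schedule")

  cs2 <- build_constraints(case, kb_fix, report, prefs = store)
  expect_length(cs2$preference, 1)
  res2 <- evolve(cs2, ga_config(random_seed = 9))
  los <- res2$schedule[[2]]$times_min
  others <- unlist(lapply(res2$schedule[c(1, 3)], function(s) s$times_min))
  gaps <- vapply(others, function(t) min(abs(t - los), 1440 - abs(t - los)), 0)
  expect_true(all(gaps >= 90))

  # persistence round-trip and precedence: newest wins among tied weights
  path <- tempfile(fileext = ".json")
  store <- record_intervention(res, list(drug = "LOSARTAN 50 MG", action = "isolate",
                                         separation_min = 150), store)
  write_preferences(store, path)
  store2 <- read_preferences(path)
  expect_length(store2$rules, 2)  # append-only: both remain stored
  cs3 <- build_constraints(case, kb_fix, report, prefs = store2)
  expect_equal(cs3$preference[[1]]$separation, 150L)
})

test_that("preference rules are soft: they can never defeat a hard constraint", {
  kb <- spaced_pair_kb(600L)
  case <- make_case(prescription = list(rx("DRUG A", 1, doses_per_day = 1),
                                        rx("DRUG B", 1, doses_per_day = 1)))
  report <- review_prescription(case, kb)
  store <- preference_store()
  store$rules[[1]] <- list(scope = "DRUG A", kind = "administer_alone",
                           separation = 1440L, weight = 50, origin = "test")
  cs <- build_constraints(case, kb, report, prefs = store)
  res <- evolve(cs, ga_config(random_seed = 4))
  # the impossible 24h-isolation preference is violated, the hard S rule is not
  expect_true(res$feasible)
  expect_length(verify_hard_constraints(res, cs), 0)
})
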