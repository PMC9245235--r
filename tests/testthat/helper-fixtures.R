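# Shared helpers: build ad-hoc knowledge bases and cases through the public
# JSON schema (tempfile round-trip), so tests exercise the documented file
# formats as well as the in-memory API.

write_kb <- function(drugs = list(), interactions = list(), food_tokens = list("FOOD")) {
  path <- tempfile(fileext = ".json")
  jsonlite::write_json(list(drugs = drugs, interactions = interactions,
                            food_tokens = food_tokens),
                       path, auto_unbox = TRUE, na = "null")
  path
}

make_kb <- function(...) load_knowledge_base(write_kb(...))

kb_drug_spec <- function(name, principles, ...) {
  c(list(product_name = name, active_principles = as.list(principles)), list(...))
}

write_case <- function(case_id = "t1", age = 40, weight = 70, sex = "M",
                       conditions = list(), routine = NULL, prescription = list(),
                       planted = NULL) {
  if (is.null(routine)) {
    routine <- list(wake_time = "07:00", sleep_time = "22:00",
                    busy_intervals = list(),
                    meal_times = list(list(label = "breakfast", time = "07:30"),
                                      list(label = "lunch", time = "12:30"),
                                      list(label = "dinner", time = "19:00")))
  }
  obj <- list(case_id = case_id,
              patient = list(age = age, weight = weight, sex = sex,
                             conditions = conditions),
              routine = routine, prescription = prescription)
  if (!is.null(planted)) obj$planted <- planted
  path <- tempfile(fileext = ".json")
  jsonlite::write_json(obj, path, auto_unbox = TRUE, na = "null")
  path
}

make_case <- function(...) load_case(write_case(...))

rx <- function(drug, dose, ...) c(list(drug = drug, dose_amount = dose), list(...))

# Two-drug KB with one S rule: the scheduling workhorse for small instances.
spaced_pair_kb <- function(min_interval = 120L) {
  make_kb(drugs = list(kb_drug_spec("DRUG A", "PRINCIPLE A"),
                       kb_drug_spec("DRUG B", "PRINCIPLE B"),
                       kb_drug_spec("DRUG C", "PRINCIPLE C")),
          interactions = list(list(principle_a = "PRINCIPLE A",
                                   principle_b = "PRINCIPLE B",
                                   rule_type = "S", min_interval = min_interval)))
}

review_of <- function(case, kb) review_prescription(case, kb)

alert_types_of <- function(report) {
  vapply(report$alerts, function(a) a$alert_type, "")
}
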