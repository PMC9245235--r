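# Genetic-algorithm dose scheduler.
#
# A candidate schedule (chromosome) is an integer vector of slot indices on a
# discretized 24h grid, one gene per (item, dose).  Fitness is a weighted
# linear penalty sum over violation classes; hard classes (sleep window,
# pairwise minimum intervals, fixed-time pins) carry weights >= 1e3 times the
# soft classes (busy intervals, food anchors, intra-item spacing deviation,
# learned preferences) so that any hard violation dominates any soft total.
# A schedule is feasible iff every hard-class component is exactly zero.

PEN_CLASSES <- c("sleep", "pairwise", "pin", "spacing", "busy", "food", "preference")
HARD_CLASSES <- c("sleep", "pairwise", "pin")

#' Default penalty weights per violation class
#'
#' Magnitudes are minutes (interval shortfall, depth inside a forbidden
#' window, spacing deviation beyond tolerance, distance to a food window)
#' except `preference`, which counts violated soft preference rules times
#' each rule's own weight.
#'
#' @return named numeric vector over the violation classes.
#' @export
default_penalty_weights <- function() {
  c(sleep = 1000, pairwise = 1000, pin = 1000,
    spacing = 1, busy = 1, food = 5, preference = 1)
}

#' Genetic-algorithm configuration
#'
#' @param slot_minutes grid granularity in minutes (default 30: 48 slots/day).
#' @param population_size,generations GA budget.
#' @param crossover_rate probability a selected pair undergoes uniform
#'   crossover.
#' @param mutation_rate per-gene probability of resampling a random slot;
#'   `NULL` means `1/chromosome_length`.
#' @param elitism_count individuals copied unchanged each generation.
#' @param tournament_size selection tournament size.
#' @param random_seed integer seed; mandatory for reproducible runs.
#' @param weights penalty weights, see [default_penalty_weights()].
#' @param early_stop stop as soon as a zero-penalty individual is found.
#' @return a `ga_config` object.
#' @export
ga_config <- function(slot_minutes = 30L, population_size = 200L, generations = 300L,
                      crossover_rate = 0.9, mutation_rate = NULL, elitism_count = 2L,
                      tournament_size = 3L, random_seed = NULL,
                      weights = default_penalty_weights(), early_stop = TRUE) {
  if (is.null(random_seed)) stop("random_seed is mandatory for reproducible runs", call. = FALSE)
  if (crossover_rate < 0 || crossover_rate > 1) stop("crossover_rate must be in [0,1]", call. = FALSE)
  if (!is.null(mutation_rate) && (mutation_rate < 0 || mutation_rate > 1)) {
    stop("mutation_rate must be in [0,1]", call. = FALSE)
  }
  if (elitism_count >= population_size) stop("elitism_count must be < population_size", call. = FALSE)
  if (1440 %% slot_minutes != 0) stop("slot_minutes must divide 1440", call. = FALSE)
  missing_w <- setdiff(PEN_CLASSES, names(weights))
  if (length(missing_w)) stop("weights missing classes: ", paste(missing_w, collapse = ", "),
                              call. = FALSE)
  structure(list(slot_minutes = as.integer(slot_minutes),
                 population_size = as.integer(population_size),
                 generations = as.integer(generations),
                 crossover_rate = crossover_rate, mutation_rate = mutation_rate,
                 elitism_count = as.integer(elitism_count),
                 tournament_size = as.integer(tournament_size),
                 random_seed = as.integer(random_seed),
                 weights = weights[PEN_CLASSES], early_stop = early_stop),
            class = "ga_config")
}

# ---- constraint compilation -------------------------------------------------

#' Compile scheduling constraints from a case, the KB and a clean alert report
#'
#' Refuses to build while unresolved blocking alerts remain (the alert gate
#' precedes scheduling).  Every constraint carries a provenance string naming
#' the KB rule, routine element or prescription field it derives from.
#'
#' S-rules whose principles both appear become pairwise minimum-interval
#' constraints (hard); the sleep interval is a hard forbidden window; fixed
#' times are hard pins; food relations anchor doses to meal times and busy
#' intervals are penalized softly; learned preference rules are appended as
#' soft constraints only.
#'
#' @param case a `patient_case`.
#' @param kb a `knowledge_base`.
#' @param alert_report the case's [review_prescription()] report.
#' @param prefs optional `preference_store` of learned rules.
#' @param slot_minutes grid granularity (must match the GA config).
#' @return a `constraint_set`.
#' @export
build_constraints <- function(case, kb, alert_report, prefs = NULL, slot_minutes = 30L) {
  if (alert_report$has_unresolved_blocking) {
    bad <- Filter(function(a) a$severity == "blocking" && !a$overridden, alert_report$alerts)
    stop("cannot schedule: unresolved blocking alert(s): ",
         paste(vapply(bad, function(a) paste0(a$id, " ", a$message), ""), collapse = "; "),
         call. = FALSE)
  }
  items <- case$prescription
  if (length(items) == 0L) stop("prescription has no items", call. = FALSE)
  rt <- case$routine

  gene_item <- integer(0)
  for (i in seq_along(items)) gene_item <- c(gene_item, rep(i, items[[i]]$doses_per_day))
  if (length(gene_item) == 0L) stop("prescription has zero doses", call. = FALSE)
  item_genes <- lapply(seq_along(items), function(i) which(gene_item == i))

  spacing <- list()
  pins <- list()
  food <- list()
  for (i in seq_along(items)) {
    it <- items[[i]]
    d <- kb_drug(kb, it$drug)
    if (it$doses_per_day >= 2L) {
      target <- if (!is.na(it$interval_hours)) it$interval_hours * 60 else 1440 / it$doses_per_day
      spacing[[length(spacing) + 1L]] <- list(
        item = i, target = target, tol = 60,
        provenance = sprintf("prescription item %d (%s): %s", i, it$drug,
                             if (!is.na(it$interval_hours))
                               sprintf("every %g h", it$interval_hours)
                             else sprintf("%d doses/day", it$doses_per_day)))
    }
    if (!is.null(it$fixed_times)) {
      if (length(it$fixed_times) != it$doses_per_day) {
        stop("item ", i, " (", it$drug, "): fixed_times length must equal doses_per_day",
             call. = FALSE)
      }
      pins[[length(pins) + 1L]] <- list(
        item = i, times = sort(it$fixed_times),
        provenance = sprintf("prescription item %d (%s): mandated times %s", i, it$drug,
                             paste(format_clock(sort(it$fixed_times)), collapse = ", ")))
    }
    if (d$food_relation != "none" && length(rt$meal_times)) {
      lead <- d$food_lead_min
      lag <- if (d$food_relation == "empty_stomach" && d$food_lag_min == 0L) 120L else d$food_lag_min
      food[[length(food) + 1L]] <- list(
        item = i, type = d$food_relation, lead = lead, lag = lag,
        meals = unname(rt$meal_times),
        provenance = sprintf("KB food relation for %s: %s (lead %d min, lag %d min)",
                             d$product_name, d$food_relation, lead, lag))
    }
  }

  # S rules -> pairwise minimum intervals between every dose pair of the
  # matching items.
  pairwise <- lapply(match_pair_rules(items, kb, "S"), function(m) {
    list(item_a = m$i, item_b = m$j, min_interval = m$rule$min_interval,
         provenance = sprintf("KB S rule (%s, %s): >= %d min",
                              m$rule$principle_a, m$rule$principle_b, m$rule$min_interval))
  })

  preference <- list()
  for (pr in effective_preferences(prefs)) {
    scope <- canonical_name(pr$scope)
    hit <- which(vapply(items, function(it) {
      it$drug == scope || scope %in% resolve_principles(it, kb)
    }, TRUE))
    for (i in hit) {
      preference[[length(preference) + 1L]] <- list(
        item = i, kind = pr$kind, separation = pr$separation, weight = pr$weight,
        provenance = sprintf("learned preference %s: %s %s (sep %d min, weight %g)",
                             pr$origin %||% "?", pr$kind, pr$scope, pr$separation, pr$weight))
    }
  }

  structure(list(
    slot_minutes = as.integer(slot_minutes),
    n_slots = as.integer(1440 %/% slot_minutes),
    n_genes = length(gene_item),
    gene_item = gene_item,
    item_genes = item_genes,
    item_drugs = vapply(items, function(it) it$drug, ""),
    awake = awake_windows(rt),
    sleep = sleep_windows(rt),
    busy = unlist(lapply(rt$busy_intervals, function(iv) split_interval(iv[1L], iv[2L])),
                  recursive = FALSE),
    spacing = spacing, pins = pins, food = food, pairwise = pairwise,
    preference = preference
  ), class = "constraint_set")
}

# Awake slot indices (used to seed the population; mutation may roam the
# whole grid so the search space equals the full slot grid).
awake_slots <- function(cs) {
  t <- (seq_len(cs$n_slots) - 1L) * cs$slot_minutes
  which(in_intervals(t, cs$awake)) - 1L
}

# Row-wise sort of an n x k matrix, vectorized by comparator networks for
# k <= 4 (the common case) and apply() beyond.
rowsort <- function(M) {
  k <- ncol(M)
  if (k == 1L) return(M)
  if (k == 2L) {
    return(cbind(pmin(M[, 1L], M[, 2L]), pmax(M[, 1L], M[, 2L])))
  }
  if (k == 3L) {
    lo <- pmin(M[, 1L], M[, 2L], M[, 3L])
    hi <- pmax(M[, 1L], M[, 2L], M[, 3L])
    return(cbind(lo, M[, 1L] + M[, 2L] + M[, 3L] - lo - hi, hi))
  }
  if (k == 4L) {
    a <- pmin(M[, 1L], M[, 2L]); b <- pmax(M[, 1L], M[, 2L])
    c_ <- pmin(M[, 3L], M[, 4L]); d <- pmax(M[, 3L], M[, 4L])
    lo <- pmin(a, c_); m1 <- pmax(a, c_)
    hi <- pmax(b, d); m2 <- pmin(b, d)
    return(cbind(lo, pmin(m1, m2), pmax(m1, m2), hi))
  }
  t(apply(M, 1L, sort))
}

# Raw (unweighted) penalty components per candidate row.  M is an n x L
# matrix of slot indices; returns an n x length(PEN_CLASSES) matrix of
# violation magnitudes.
penalty_components <- function(M, cs) {
  if (is.null(dim(M))) M <- matrix(M, nrow = 1L)
  n <- nrow(M)
  T <- M * cs$slot_minutes
  comp <- matrix(0, n, length(PEN_CLASSES), dimnames = list(NULL, PEN_CLASSES))

  for (g in seq_len(cs$n_genes)) {
    if (length(cs$sleep)) comp[, "sleep"] <- comp[, "sleep"] + forbidden_depth(T[, g], cs$sleep)
    if (length(cs$busy)) comp[, "busy"] <- comp[, "busy"] + forbidden_depth(T[, g], cs$busy)
  }

  for (pw in cs$pairwise) {
    for (a in cs$item_genes[[pw$item_a]]) {
      for (b in cs$item_genes[[pw$item_b]]) {
        comp[, "pairwise"] <- comp[, "pairwise"] +
          pmax(0, pw$min_interval - circular_gap(T[, a], T[, b]))
      }
    }
  }

  sorted_items <- list()
  sorted_for <- function(i) {
    key <- as.character(i)
    if (is.null(sorted_items[[key]])) {
      sorted_items[[key]] <<- rowsort(T[, cs$item_genes[[i]], drop = FALSE])
    }
    sorted_items[[key]]
  }

  for (sp in cs$spacing) {
    S <- sorted_for(sp$item)
    k <- ncol(S)
    gaps <- cbind(S[, -1L, drop = FALSE] - S[, -k, drop = FALSE],
                  MINUTES_PER_DAY - (S[, k] - S[, 1L]))  # cyclic wrap gap
    dev <- abs(gaps - sp$target) - sp$tol
    dev[dev < 0] <- 0
    comp[, "spacing"] <- comp[, "spacing"] + rowSums(dev)
  }

  for (pn in cs$pins) {
    S <- sorted_for(pn$item)
    for (k in seq_along(pn$times)) {
      comp[, "pin"] <- comp[, "pin"] + circular_gap(S[, k], pn$times[k])
    }
  }

  for (fd in cs$food) {
    for (g in cs$item_genes[[fd$item]]) {
      t <- T[, g]
      if (fd$type == "empty_stomach") {
        # each meal spreads a forbidden halo (meal - lead, meal + lag):
        # exactly `lead` min before the meal (or `lag` after) is compliant
        depth <- rep(0, n)
        for (m in fd$meals) {
          ivs <- split_interval((m - fd$lead + 1L) %% MINUTES_PER_DAY,
                                (m + fd$lag) %% MINUTES_PER_DAY)
          depth <- pmax(depth, forbidden_depth(t, ivs))
        }
        comp[, "food"] <- comp[, "food"] + depth
      } else {  # with_food: distance to the nearest meal window
        dist <- rep(Inf, n)
        for (m in fd$meals) {
          lo <- (m - fd$lead) %% MINUTES_PER_DAY
          hi <- (m + fd$lag) %% MINUTES_PER_DAY
          inside <- in_intervals(t, split_interval(lo, hi))
          dmeal <- pmin(circular_gap(t, lo), circular_gap(t, hi))
          dmeal[inside] <- 0
          dist <- pmin(dist, dmeal)
        }
        comp[, "food"] <- comp[, "food"] + dist
      }
    }
  }

  for (pf in cs$preference) {
    if (pf$kind != "administer_alone") next
    others <- setdiff(seq_len(cs$n_genes), cs$item_genes[[pf$item]])
    for (a in cs$item_genes[[pf$item]]) {
      for (b in others) {
        comp[, "preference"] <- comp[, "preference"] +
          pf$weight * (circular_gap(T[, a], T[, b]) < pf$separation)
      }
    }
  }

  comp
}

#' Penalty fitness of a candidate schedule
#'
#' Total penalty is the weighted sum over violation classes of the raw
#' violation magnitudes; zero iff the schedule violates nothing.  The
#' breakdown reports each class's weighted contribution.
#'
#' @param chromosome integer vector of slot indices (one per dose).
#' @param constraints a `constraint_set` from [build_constraints()].
#' @param weights penalty weights (see [default_penalty_weights()]).
#' @return list with `total` and named `breakdown`.
#' @export
fitness <- function(chromosome, constraints, weights = default_penalty_weights()) {
  if (length(chromosome) != constraints$n_genes) {
    stop("chromosome length ", length(chromosome), " != number of doses ",
         constraints$n_genes, call. = FALSE)
  }
  comp <- penalty_components(matrix(chromosome, nrow = 1L), constraints)
  bd <- comp[1L, ] * weights[PEN_CLASSES]
  list(total = sum(bd), breakdown = bd)
}

fitness_totals <- function(M, cs, weights) {
  drop(penalty_components(M, cs) %*% weights[PEN_CLASSES])
}

# ---- GA ---------------------------------------------------------------------

# TRUE if integer vector a is lexicographically smaller than b.
lex_less <- function(a, b) {
  d <- a != b
  if (!any(d)) return(FALSE)
  k <- which(d)[1L]
  a[k] < b[k]
}

run_seeded <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Evolve a medication schedule
#'
#' Seeded, reproducible genetic algorithm: tournament selection, uniform
#' crossover, per-gene mutation resampling a random slot, elitism, and an
#' elitist hall of fame so the returned individual is the best ever seen
#' (ties broken by the lexicographically smallest slot vector).  Stops early
#' when a zero-penalty individual appears.  Always returns a result, even
#' when infeasible, with the violations listed.
#'
#' @param constraints a `constraint_set`.
#' @param config a [ga_config()].
#' @return a `schedule_result`: `schedule` (per item, sorted clock times),
#'   `fitness`, `breakdown`, `violations`, `feasible`, `generations_run`,
#'   `best_history`, `seed`.
#' @examples
#' kb <- load_knowledge_base(pharmsched_fixture("kb.json"))
#' case <- load_case(pharmsched_fixture("case04.json"))
#' cs <- build_constraints(case, kb, review_prescription(case, kb))
#' res <- evolve(cs, ga_config(random_seed = 42))
#' res$feasible
#' @export
evolve <- function(constraints, config) {
  stopifnot(inherits(constraints, "constraint_set"), inherits(config, "ga_config"))
  if (constraints$slot_minutes != config$slot_minutes) {
    stop("constraint_set and ga_config disagree on slot_minutes", call. = FALSE)
  }
  L <- constraints$n_genes
  w <- config$weights
  mut <- config$mutation_rate %||% (1 / L)
  pop_n <- config$population_size
  seed_pool <- awake_slots(constraints)
  if (length(seed_pool) == 0L) seed_pool <- seq_len(constraints$n_slots) - 1L

  run_seeded(config$random_seed, {
    pop <- matrix(sample(seed_pool, pop_n * L, replace = TRUE), pop_n, L)
    fit <- fitness_totals(pop, constraints, w)

    best_vec <- NULL
    best_fit <- Inf
    note_best <- function(M, f) {
      for (i in order(f)[seq_len(min(4L, length(f)))]) {
        if (f[i] < best_fit || (f[i] == best_fit && lex_less(M[i, ], best_vec))) {
          best_fit <<- f[i]
          best_vec <<- M[i, ]
        }
      }
    }
    note_best(pop, fit)
    history <- best_fit
    gens <- 0L

    for (gen in seq_len(config$generations)) {
      if (config$early_stop && best_fit == 0) break
      # tournament selection of pop_n parents
      idx <- matrix(sample.int(pop_n, pop_n * config$tournament_size, replace = TRUE),
                    pop_n, config$tournament_size)
      winners <- apply(idx, 1L, function(r) r[which.min(fit[r])])
      parents <- pop[winners, , drop = FALSE]
      # uniform crossover on consecutive pairs
      children <- parents
      for (p in seq(1L, pop_n - 1L, by = 2L)) {
        if (stats::runif(1) < config$crossover_rate) {
          mask <- stats::runif(L) < 0.5
          a <- parents[p, ]; b <- parents[p + 1L, ]
          children[p, mask] <- b[mask]
          children[p + 1L, mask] <- a[mask]
        }
      }
      # per-gene mutation: resample a random slot anywhere on the grid
      mmask <- matrix(stats::runif(pop_n * L) < mut, pop_n, L)
      if (any(mmask)) {
        children[mmask] <- sample.int(constraints$n_slots, sum(mmask), replace = TRUE) - 1L
      }
      # elitism: best of the current generation survive unchanged
      if (config$elitism_count > 0L) {
        elite <- order(fit)[seq_len(config$elitism_count)]
        children[seq_len(config$elitism_count), ] <- pop[elite, , drop = FALSE]
      }
      pop <- children
      fit <- fitness_totals(pop, constraints, w)
      note_best(pop, fit)
      history <- c(history, best_fit)
      gens <- gen
    }

    bd <- fitness(best_vec, constraints, w)
    times <- best_vec * constraints$slot_minutes
    schedule <- lapply(seq_along(constraints$item_genes), function(i) {
      tt <- sort(times[constraints$item_genes[[i]]])
      list(item = i, drug = constraints$item_drugs[i],
           times_min = tt, times = format_clock(tt))
    })
    feasible <- all(bd$breakdown[HARD_CLASSES] == 0)
    structure(list(
      schedule = schedule, chromosome = best_vec,
      fitness = bd$total, breakdown = bd$breakdown,
      violations = describe_violations(best_vec, constraints, w),
      feasible = feasible, generations_run = gens,
      best_history = history, seed = config$random_seed,
      slot_minutes = constraints$slot_minutes
    ), class = "schedule_result")
  })
}

#' Exhaustive schedule optimizer (test oracle)
#'
#' Enumerates the full slot grid and returns the exact minimum of the same
#' fitness function, with one lexicographically-smallest optimal assignment.
#' Refuses search spaces above `1e7` combinations.
#'
#' @param constraints a `constraint_set`.
#' @param weights penalty weights.
#' @return list with `optimum` (minimal total penalty) and `chromosome`.
#' @export
brute_force_schedule <- function(constraints, weights = default_penalty_weights()) {
  L <- constraints$n_genes
  ns <- constraints$n_slots
  total <- ns^L
  if (total > 1e7) {
    stop(sprintf("search space too large for exhaustive enumeration: %d^%d = %.3g combinations",
                 ns, L, total), call. = FALSE)
  }
  best <- Inf
  best_vec <- NULL
  chunk <- 200000L
  # gene 1 is the most significant digit, so increasing index enumerates
  # chromosomes in lexicographic order and the first minimum is lex-smallest
  for (start in seq(0, total - 1, by = chunk)) {
    idx <- start:min(start + chunk - 1, total - 1)
    M <- matrix(0L, length(idx), L)
    rem <- idx
    for (g in L:1) {
      M[, g] <- as.integer(rem %% ns)
      rem <- rem %/% ns
    }
    f <- fitness_totals(M, constraints, weights)
    i <- which.min(f)
    if (f[i] < best) {
      best <- f[i]
      best_vec <- M[i, ]
    }
  }
  list(optimum = best, chromosome = best_vec)
}

# Human-readable violation list for a candidate (all classes, with
# magnitudes); shares the penalty definitions but reports per constraint.
describe_violations <- function(chromosome, cs, weights = default_penalty_weights()) {
  T <- chromosome * cs$slot_minutes
  out <- list()
  add <- function(class, magnitude, description) {
    out[[length(out) + 1L]] <<- list(class = class, magnitude = magnitude,
                                     description = description)
  }
  for (g in seq_len(cs$n_genes)) {
    d <- forbidden_depth(T[g], cs$sleep)
    if (d > 0) add("sleep", d, sprintf("dose of %s at %s falls inside the sleep window",
                                       cs$item_drugs[cs$gene_item[g]], format_clock(T[g])))
    d <- forbidden_depth(T[g], cs$busy)
    if (d > 0) add("busy", d, sprintf("dose of %s at %s falls inside a busy interval",
                                      cs$item_drugs[cs$gene_item[g]], format_clock(T[g])))
  }
  for (pw in cs$pairwise) {
    for (a in cs$item_genes[[pw$item_a]]) {
      for (b in cs$item_genes[[pw$item_b]]) {
        short <- pw$min_interval - circular_gap(T[a], T[b])
        if (short > 0) add("pairwise", short,
                           sprintf("%s at %s and %s at %s only %d min apart (need %d) [%s]",
                                   cs$item_drugs[pw$item_a], format_clock(T[a]),
                                   cs$item_drugs[pw$item_b], format_clock(T[b]),
                                   circular_gap(T[a], T[b]), pw$min_interval, pw$provenance))
      }
    }
  }
  comp_row <- penalty_components(matrix(chromosome, 1L), cs)[1L, ]
  for (cls in c("pin", "spacing", "food", "preference")) {
    if (comp_row[cls] > 0) {
      prov <- switch(cls,
        pin = paste(vapply(cs$pins, function(p) p$provenance, ""), collapse = "; "),
        spacing = paste(vapply(cs$spacing, function(s) s$provenance, ""), collapse = "; "),
        food = paste(vapply(cs$food, function(f) f$provenance, ""), collapse = "; "),
        preference = paste(vapply(cs$preference, function(p) p$provenance, ""), collapse = "; "))
      add(cls, comp_row[cls], sprintf("%s violation (magnitude %g) [%s]", cls, comp_row[cls], prov))
    }
  }
  out
}

#' Independently re-check the hard constraints of a schedule result
#'
#' Deliberately separate from the fitness code path: walks the returned
#' clock times and verifies directly that no dose lies inside the sleep
#' window, every pairwise minimum interval holds on the 24h circle, and
#' every pinned time is met exactly.
#'
#' @param result a `schedule_result`.
#' @param constraints the `constraint_set` it was produced from.
#' @return character vector of violation descriptions (empty when clean).
#' @export
verify_hard_constraints <- function(result, constraints) {
  probs <- character()
  times_of <- function(i) result$schedule[[i]]$times_min
  # sleep: a dose must not lie in [sleep_start, wake) on the wrapped clock
  for (i in seq_along(result$schedule)) {
    for (t in times_of(i)) {
      for (iv in constraints$sleep) {
        if (t >= iv[1L] && t < iv[2L]) {
          probs <- c(probs, sprintf("item %d dose at %s inside sleep", i, format_clock(t)))
        }
      }
    }
  }
  for (pw in constraints$pairwise) {
    for (ta in times_of(pw$item_a)) {
      for (tb in times_of(pw$item_b)) {
        d <- abs(ta - tb)
        gap <- min(d, 1440 - d)
        if (gap < pw$min_interval) {
          probs <- c(probs, sprintf("items %d/%d gap %d < %d min",
                                    pw$item_a, pw$item_b, gap, pw$min_interval))
        }
      }
    }
  }
  for (pn in constraints$pins) {
    tt <- times_of(pn$item)
    if (!identical(sort(tt), as.integer(sort(pn$times)))) {
      probs <- c(probs, sprintf("item %d times differ from pinned times", pn$item))
    }
  }
  probs
}

#' @export
print.schedule_result <- function(x, ...) {
  cat(sprintf("Schedule (fitness %g, %s, %d generation(s), seed %d)\n",
              x$fitness, if (x$feasible) "feasible" else "INFEASIBLE",
              x$generations_run, x$seed))
  for (s in x$schedule) {
    cat(sprintf("  item %d %-28s %s\n", s$item, s$drug, paste(s$times, collapse = "  ")))
  }
  if (length(x$violations)) {
    cat("Violations:\n")
    for (v in x$violations) cat(sprintf("  [%s] %s\n", v$class, v$description))
  }
  invisible(x)
}

schedule_result_to_list <- function(res) {
  list(
    schedule = lapply(res$schedule, function(s) {
      list(item = s$item, drug = s$drug, times = as.list(s$times))
    }),
    fitness = res$fitness,
    breakdown = as.list(res$breakdown),
    violations = res$violations,
    feasible = res$feasible,
    generations_run = res$generations_run,
    seed = res$seed,
    slot_minutes = res$slot_minutes
  )
}

# ---- learned preferences ----------------------------------------------------

#' Create an empty preference store
#' @return a `preference_store` (append-only list of learned soft rules).
#' @export
preference_store <- function() {
  structure(list(rules = list()), class = "preference_store")
}

#' Learn a preference rule from a user's schedule edit
#'
#' When the user modifies a proposed schedule (e.g. moves every dose of one
#' drug away from all others), the system records the implied habit as a
#' soft preference rule that future [build_constraints()] calls append.
#' The store is append-only and keeps provenance; rules are never hard, so
#' a learned habit can never override a safety constraint.
#'
#' @param result the `schedule_result` the user edited.
#' @param user_edit list with `drug` (name), `action` (currently
#'   `"isolate"`), and `separation_min`; an empty list leaves the store
#'   unchanged.
#' @param store a `preference_store`.
#' @return the updated store.
#' @export
record_intervention <- function(result, user_edit, store = preference_store()) {
  if (length(user_edit) == 0L) return(store)
  drugs <- vapply(result$schedule, function(s) s$drug, "")
  drug <- canonical_name(user_edit$drug)
  if (!drug %in% drugs) {
    stop("edit references drug '", user_edit$drug, "' not in the schedule", call. = FALSE)
  }
  if (!identical(user_edit$action, "isolate")) {
    stop("unknown edit action '", user_edit$action, "'", call. = FALSE)
  }
  store$rules[[length(store$rules) + 1L]] <- list(
    scope = drug, kind = "administer_alone",
    separation = as.integer(user_edit$separation_min),
    weight = user_edit$weight %||% 1,
    origin = sprintf("intervention-%d", length(store$rules) + 1L)
  )
  store
}

# Effective rules after precedence: for each (scope, kind) the rule with the
# highest weight applies; ties go to the newest (both remain stored).
effective_preferences <- function(store) {
  if (is.null(store) || length(store$rules) == 0L) return(list())
  key <- vapply(store$rules, function(r) paste(r$scope, r$kind), "")
  out <- list()
  for (k in unique(key)) {
    cand <- store$rules[key == k]
    wts <- vapply(cand, function(r) r$weight, 1)
    out[[length(out) + 1L]] <- cand[[max(which(wts == max(wts)))]]
  }
  out
}

#' Read / write a preference store as JSON
#' @param path file path.
#' @return [read_preferences()]: a `preference_store`;
#'   [write_preferences()]: `path` invisibly.
#' @export
read_preferences <- function(path) {
  if (!file.exists(path)) return(preference_store())
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  structure(list(rules = raw$rules %||% list()), class = "preference_store")
}

#' @rdname read_preferences
#' @param store a `preference_store`.
#' @export
write_preferences <- function(store, path) {
  jsonlite::write_json(list(rules = store$rules), path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
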