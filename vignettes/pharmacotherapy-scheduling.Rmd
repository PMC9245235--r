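---
title: "Methods: alert screening and GA-based medication scheduling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: alert screening and GA-based medication scheduling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pharmsched)
```

## The problem

Pharmacotherapy review inspects everything a patient takes, looking for
drug-related problems — contraindications, interacting drugs used
concomitantly, therapeutic duplication, doses outside the safe range — and
then *schedules* the surviving prescription: assigns a clock time to every
dose so that interacting drugs are kept apart, food-dependent drugs meet
their meals correctly, and nothing lands in the middle of the patient's
sleep or, if avoidable, their working hours. Doing this by hand is slow and
error-prone; `pharmsched` automates both halves and ships the validation
instruments used to compare automated reviews with expert ones.

## The knowledge model

The drug knowledge base holds one record per medicinal product (canonical
active principles, optional 7-character ATC code, optional dose limits,
food relation, free-text administration observations, contraindicated
conditions) plus typed interaction rules over *principles*, never product
names:

* **NU (no-use)** — contraindicated concomitant use; no interval, the pair
  simply must not co-occur. Emitted as *blocking* alerts.
* **S (scheduling)** — a minimum time span in minutes that must separate
  administrations of the two principles. Surfaced as info alerts and
  consumed by the scheduler as hard pairwise constraints.
* **O (observations)** — administration instructions (posture, water,
  relation to meals) that are surfaced verbatim.

All principle names are canonicalized (upper-case, accent-stripped,
trademark glyphs removed) because real formularies mix Portuguese/English
brand and generic spellings. Clock times are integer minutes since
midnight; every interval is half-open `[start, end)` and intervals that
cross midnight are split at 00:00, which makes night-shift routines (sleep
07:30–14:30, work 22:00–06:00) exact rather than special-cased.

Duplication is two-tier by design: a shared active principle across two
items is the unambiguous case, and two items sharing a 5-character ATC
prefix (same chemical subgroup) raise a weaker class-level warning. Dose
checks use strict inequality with a `1e-9` relative tolerance — a dose
exactly at the limit is compliant — and a per-kg limit with no recorded
weight produces an explicit "cannot evaluate" alert rather than silence.
The engine never removes a drug: blocking alerts gate the scheduler until a
user overrides them with a justification, and an overridden alert is kept
on record forever.

## The scheduling model

The day is discretized into `1440 / slot_minutes` slots (default 30 min, 48
slots — clinically meaningful resolution that also keeps the exhaustive test
oracle tractable). A candidate schedule is an integer vector with one gene
per (item, dose). Fitness is a weighted linear penalty

$$F(x) \;=\; \sum_{c} w_c \sum_{v \in c} m_v(x),$$

where each violation's magnitude $m_v$ is measured in minutes: shortfall
below a pairwise minimum interval, depth inside a forbidden window
(sleep, the empty-stomach halo around meals), absolute deviation of
intra-item spacing beyond a 60-min tolerance, distance to the nearest
with-food window, and — for learned preferences only — a count times the
rule's own weight. Hard classes (sleep window, pairwise S-intervals,
fixed-time pins) carry weight 1000/min, at least $10^3$ times the soft
classes (busy intervals 1, spacing 1, food 5, preferences 1), so one minute
of hard violation always dominates any realistic soft total; a schedule is
*feasible* iff every hard component is exactly zero. Busy (work) intervals
are soft on purpose: a working patient can still take a tablet at work,
whereas sleep is protected as hard.

Intra-item spacing targets `interval_hours × 60` when the prescription is
interval-style, else `1440 / doses_per_day`, and gaps are measured
cyclically (last dose to next morning's first), so the optimizer is never
rewarded for clustering doses at the end of the day. For a child's q8h
antibiotic under a long sleep window, the hard sleep constraint stays hard
and the soft spacing tolerance absorbs the compression.

The optimizer is a plain generational GA: tournament selection (k = 3),
uniform crossover (rate 0.9), per-gene mutation `1/L` resampling a uniform
slot, elitism 2, population 200, up to 300 generations, early stop on a
zero-penalty individual, all behind a mandatory seed. The initial
population is sampled from the awake slots (a seeding heuristic); mutation
roams the full grid, so the reachable space equals the full slot grid and
the GA can in principle attain any exhaustive optimum, including infeasible
instances' best compromises. An elitist hall of fame makes the best-so-far
fitness non-increasing by construction, and ties between equal-fitness
individuals are broken toward the lexicographically smallest slot vector so
that a (constraints, config, seed) triple maps to exactly one result. When
no feasible schedule exists the best individual is still returned, flagged
infeasible, with every violation listed and quantified — the contract is
"show the best solution found", not "fail".

Two independent checks guard the implementation: `brute_force_schedule()`
enumerates the full grid (guarded at $10^7$ combinations) and minimizes the
same fitness exactly, and `verify_hard_constraints()` re-checks the
returned clock times against sleep, S-intervals and pins through direct
interval arithmetic that shares no code with the fitness function.

Learned preferences close the loop: when a user edits a proposed schedule
to isolate a drug, `record_intervention()` appends an `administer_alone`
rule (scope, separation, weight, provenance) to an append-only store;
among conflicting rules for the same scope the highest weight wins and ties
go to the newest. Preference rules are always soft — a user habit can bias
the search but can never defeat a safety constraint.

## Fixtures and the synthetic generator

Ten hypothetical cases (`case01`–`case10`) plant, one each: a no-use pair
(aspirin + warfarin), an active daytime routine, a night-shift routine, a
minimum-interval pair (digoxin + an aluminium-hydroxide antacid), a
contraindication (cirrhosis + atorvastatin), a pediatric per-kg overdose
(13 kg, azithromycin), an empty-stomach food relation (omeprazole), a
sleep-protection q8h antibiotic in a child, a risk explicitly accepted by
clinical decision (carbamazepine in pregnancy, shipped pre-overridden), and
drugs needing specific administration guidelines (alendronate +
levothyroxine). Every numeric threshold in the fixture KB (the
10 mg/kg/day azithromycin cap, the 120-min digoxin–antacid interval, the
30-min empty-stomach leads) is a **fixture value** chosen to make the
scenario machine-checkable, not clinical guidance. Each case carries its
ground truth (planted class, expected alert types, expected feasibility),
so detection and schedule adequacy are computable properties, not
judgments. For the three routine-situation cases, which plant no alert at
all, "identified" means the review raises no spurious blocking alert *and*
the scheduler returns a feasible schedule confirmed by the independent
checker — the planted situation there is a scheduling demand.

The synthetic generator reproduces the same construction at scale: clean
cases sample 3–8 drugs from a pool with no KB rules, limits, food relations
or observations (zero alerts by construction), and planted cases add
exactly one inconsistency of the requested class. All randomness flows
through one seed per call; the same (class, seed) always yields the same
case. What the generator does *not* emulate: multi-drug cascades of
interactions, incomplete or contradictory knowledge bases, adherence
behaviour, or multi-day regimens — so green tests here demonstrate engine
correctness against planted ground truth, not clinical completeness on
real-world prescriptions.

## Review assessment and agreement

`score_iarf()` scores the 10-item review instrument: codes 1/2/3 sum
(optimal all-"No" review = 10), code 9 ("I do not know") is excluded from
the sum and reported as `n_unknown` — the instrument's source only defines
the optimal sum, so exclusion-plus-flag was chosen over treating unknowns
as any numeric value, and the print method warns that such assessments are
incomplete. Item 10 maps to the overall adequate / partially adequate /
inadequate classification.

`weighted_kappa()` implements
$\kappa = 1 - \sum w_{ij} O_{ij} / \sum w_{ij} E_{ij}$ over the 3-level
ordinal classification with an explicit, mandatory weight scheme: linear
disagreement weights $|i-j|/(k-1)$ are the sensible default for 3-level
ordinal ratings and what the command-line `kappa` subcommand defaults to,
quadratic weights are provided, and identity weights reduce exactly to
unweighted Cohen's kappa (cross-checked in the tests against an independent
implementation). Degenerate marginals raise an explicit undefined-kappa
error, never a silent 0. The confidence interval uses the non-null
asymptotic variance of Fleiss, Cohen & Everitt (1969), clipped to
$[-1, 1]$; because agreement studies are often tiny (ten cases is typical),
a seeded nonparametric bootstrap over rated units is offered as an
alternative, and the method used is always recorded in the output.
Interpretation bands follow the usual ladder (0.21–0.40 "reasonable",
0.41–0.60 "moderate", ...), applied after rounding to the bands' two-decimal
print precision so boundary values land in the band whose printed range
contains them.

The synthetic rating generator uses a mixture: rater A draws from the
category marginals; with probability $p$ rater B copies A, else draws
independently. Since the diagonal carries zero disagreement weight and B's
marginal equals A's, the expected weighted kappa equals $p$ exactly under
*every* weight scheme, which makes the calibration trivial and exact and
gives the CI-coverage simulation a known true value.

## Problem sizes and numerical choices

The test suite runs the ten fixtures through the full pipeline (GA at
default settings, seed 42), checks GA-vs-exhaustive equivalence on 100
seeded instances kept to ≤3 genes on the 48-slot grid (the exhaustive
oracle's comfort zone), simulates CI coverage with 500 replicates of
n = 1000 ratings, and screens 200 clean and 200-per-class planted synthetic
cases. These sizes were chosen so the whole suite documents the properties
at convincing scale while remaining quick to run routinely.

Degenerate inputs are handled explicitly: an empty prescription or a
sleep interval covering the whole day refuse with errors; a zero-length
awake window cannot arise (wake ≠ sleep is enforced); chromosomes of the
wrong length, unknown alert ids, unknown drugs and malformed KB records all
fail fast with named errors rather than propagating silently.

## Known limitations

One prototypical 24-hour day (no calendars, no tapering regimens); single
scalarized objective rather than Pareto multi-objective search; the KB is
user-supplied or fixture — no external formulary lookups; severity grading
of alerts is a package convention (blocking/warning/info), not an
evidence-graded scale; and the kappa tooling compares rater *pairs* only —
multi-rater designs need a different statistic.
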