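---
title: "Methods: pathway mining and stochastic multi-resource scheduling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pathway mining and stochastic multi-resource scheduling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

An outpatient clinic serves a cohort of scheduled patients. Each patient
follows a *care pathway*: an ordered sequence of activities (intake, imaging,
provider consult, technician work, discharge), each requiring one or more
units of a typed, capacitated resource (a technician, a provider), each with
a random service duration. careflow addresses two coupled questions:

1. **Mining** — given room-level co-location logs from a real-time location
   system (RTLS), what are the dominant pathways and the per-activity
   duration distributions?
2. **Scheduling** — given those pathways and a resource pool, which unit
   should serve each activity and in what order, so that the *expected total
   patient waiting time* is minimized?

## The two-stage stochastic program

Activities `A` are split into initial activities `A0` (released at the
scheduled arrival time `t_a`) and subsequent ones `A1` (released when the
predecessor `pre(a)` completes). The requirement matrix `V[a, g]` counts the
type-`g` units activity `a` needs; unit `j` has capacity `k_j`, the number
of activities it can serve simultaneously.

**First stage** (before durations are observed): binary assignment `x[a, j]`;
for every ordered pair of activities sharing a required type, sequencing
indicators `s1[a, a']` ("`a` does not start before `a'`") and `s2[a, a']`
("`a` starts before `a'` ends"); and concurrency indicators `q[a, a', j]`
lower-bounded by `s1 + s2 + x[a,j] + x[a',j] - 3`. Capacity is enforced only
at activity starts — `sum_{a'} q[a, a', j] <= k_j - 1` — which suffices
because concurrency on a unit can only increase when some activity starts.
This is what makes the formulation free of time and rank indices.

**Second stage** (per duration realization): continuous start times `b_a`
minimizing total waiting
`sum_{A0} (b_a - t_a) + sum_{A1} (b_a - b_pre - d_pre)`, subject to release,
precedence, and big-M linkages that force `b` to respect the first-stage
sequencing (with a one-minute strictness constant, so with integer durations
"strictly earlier" means "at least one minute earlier").

The expectation over durations is replaced by a **sample average
approximation (SAA)**: `N` i.i.d. duration scenarios, first-stage constraints
once, second-stage constraints replicated per scenario, objective the
scenario average. For fixed `N` this is a single MILP; `solve_saa()` builds
it sparsely in R and solves it through HiGHS branch-and-cut (via
`scipy.optimize.milp`), so every solution carries a gap certificate. The
deterministic counterpart is exactly the `N = 1` model
(`solve_deterministic()`).

After the solver returns, start times are recomputed per scenario as the
*least element* of the fixed-sequence difference-constraint system. The MILP
can leave arbitrary slack on starts that do not affect the objective;
replaying the first stage with a longest-path fixpoint yields the unique
earliest schedule, with the same objective value, and integral starts for
integral data. The same machinery powers `evaluate_first_stage()`: with the
binaries fixed, each scenario's second-stage problem is a system of
difference constraints with a monotone objective, so its exact LP optimum is
available in closed form without a solver call.

### Infeasible `s2 = 1` pairs at evaluation

A planned "starts before `a'` ends" constraint can become inconsistent when a
fresh scenario shrinks `d_{a'}` (the plan expected an overlap that the short
realization cannot provide). Dropping that constraint only lets the activity
start later than planned, which cannot increase concurrency on any unit, so
the relaxation is capacity-safe. Operationally: if the fixpoint detects a
positive cycle, the least solution of the system *without* `s2 = 1`
constraints is computed (always consistent — all other constraints are
duration-monotone), the `s2 = 1` constraints it violates are dropped, and
the scenario is flagged `relaxed` in the output. Scenarios are never
resampled, keeping all evaluations comparable.

### Big-M and numerical choices

* `M = max_a t_a + sum_a d_a^max + 1`, recomputed per instance and scenario
  set: the smallest easily-provable constant under which every relaxed big-M
  constraint is vacuous. Tests verify that doubling `M` leaves optima
  unchanged.
* MIP relative gap `1e-4`, per-model time limit 3600 s (configurable).
* Durations are integers (minutes): log-normal draws are rounded to the
  nearest minute and clamped to at least 1; mean-value durations are rounded
  means, clamped the same way. Timestamps are floored to whole minutes
  before mining.
* Pair variables are instantiated for both ordered directions of every pair
  sharing a required type. The constraints are asymmetric; the mild
  redundancy is accepted for fidelity.
* Objective comparisons in tests use exact equality on integral optima
  (tolerance `1e-6`).

## Monte Carlo optimization and its bounds

`run_mco()` grows the SAA sample size until the solution is statistically
near-optimal. Per iteration, for each of `K` replicates: draw `N + N'`
scenarios; solve the SAA on the first `N` (value `v^k_N`); evaluate the
resulting fixed first stage on the last `N'` (value `v^k_{N'}`). The
replicate averages are the classical statistical lower bound (`v̄_N`, the
mean SAA optimum is optimistic in expectation) and upper bound (`v̄_{N'}`,
any fixed feasible first stage is pessimistic). The approximate optimality
index `AOI = |v̄_{N'} - v̄_N| / v̄_{N'}` stops the loop at tolerance ε.

Defaults: `N0 = 100`, `N' = 500`, and — where the method's description
leaves them open — `K = 10`, `ε = 0.05` (matching the 5% optimality-gap
reporting convention), and geometric growth `N ← 2N`, which reaches an
adequate `N` in few expensive iterations. The retained first stage is the
final iteration's best replicate by simulation value. Replicates derive
their seeds from the master seed through a documented affine hash
(`child_seed()`), so every reported number is recomputable from
`(configuration, seed)`.

## Value of the stochastic solution

`compute_vss()` fixes the mean-value model's first stage and evaluates it on
the *same* retained simulation scenario sets as the stochastic solution.
The report uses `VSS = v̄^base_{N'} - v̄_{N'}` (positive when modelling
uncertainty helps) and the ratio `VSS / v̄^base_{N'}` as the fractional
waiting-time reduction; the literal difference estimator with the opposite
sign is also carried in the report for reference.

Two empirical observations from the test suite, at the reduced scales it
exercises (2-6 patients, `N0` 20-100):

* The SAA bound sandwich and the AOI tolerance behave as the theory
  predicts (terminal AOI ≤ 0.05 on the 4-patient reference instance).
* The stochastic and mean-value first stages frequently *coincide* for
  small symmetric cohorts, making VSS exactly zero there; an engineered
  crossing-flow example with a heavy-tailed service time demonstrates a
  strictly positive VSS. Large-cohort behaviour (20 patients at 10-minute
  intervals) is outside a single-CPU open-source-solver budget and is not
  asserted by the tests.

## Pathway mining

Co-location activities are maximal time segments in which the patient's room
and the multiset of co-located resource *types* are both constant; a room
change or a change in the type multiset starts a new activity. Two
deliberate identities: a swap between two units of the same type does not
split an activity (pathways are type-level), and two same-type units present
simultaneously form a multiset label (`"Provider+Provider"`), which
downstream becomes a two-unit requirement. Co-location is evaluated on
half-open minute intervals; zero-length intersections are not activities,
and a configurable minimum overlap (default 1 minute) filters spurious
contacts. Visits are grouped by exact sequence equality; the `top_k` groups
are retained with proportions renormalized over the retained set (the
pathway sampling weights), and per-position duration moments are fitted by
log-normal moment inversion:
`σ² = log(1 + v/m²)`, `μ = log m - σ²/2` — a bijection on
`{m > 0, v ≥ 0}` verified to round-trip to `1e-9` relative error.

Cleaning: rows with inverted intervals or missing identifiers are dropped
and counted. Patients with no co-located time are flagged and excluded from
grouping rather than imputed.

## What the synthetic generator emulates — and what it does not

`generate_synthetic_rtls()` emits schema-faithful patient and resource logs:
fixed-interval arrivals, pathway types drawn by the table proportions,
integer-minute log-normal service durations, one room per activity with the
required resource present for exactly the activity span. It is designed so
the mining pipeline is *identifiable*: extraction plus grouping provably
recovers the generating pathways, which the tests verify at corpus sizes up
to 100,000 visits (proportions within three binomial standard errors).

It deliberately does not emulate: room contention or room reuse across
concurrent visits (each visit gets its own rooms; rooms are not capacitated
assets in the scheduling model), clinic congestion (visits are back-to-back
co-location, not queueing — waiting is the *scheduler's* output, not the
generator's), positioning noise, missing or duplicated RTLS reads beyond
the simple invalid-row patterns the cleaner counts, or stochastic arrivals
and no-shows (arrivals are deterministic equal-interval). Passing
round-trip tests therefore validates the mining logic, not robustness to
real-world RTLS measurement artifacts.

## Validation strategy

* **Dual route**: the big-M MILP (HiGHS) is cross-checked against
  `brute_force_optimum()`, an independent pure-R branch-and-bound over
  placement orders and unit choices with greedy earliest-start replay —
  exact for tiny instances — on fifty seeded instances.
* **Independent audit**: `check_schedule()` re-verifies every
  solver-produced schedule from only `(x, b, d)` — assignment counts,
  release, precedence, and capacity at every activity start — never
  trusting the sequencing or concurrency indicators.
* **Statistical properties**: bound sandwich, AOI reproduction from the
  trace, VSS non-negativity within two standard errors, determinism of
  every seeded path.

Problem sizes in the test suite are the package's chosen reference scales:
tiny oracle instances (2-3 patients, chains ≤ 3), a 4-patient bound-sandwich
instance (`N0 = 20`, `N' = 100`, `K = 5`), 6-patient congestion checks, and
100,000-visit mining corpora.

## Known limitations

* Sequencing is wholly first-stage: all pairwise orderings are fixed before
  durations realize, so recourse is limited to shifting start times. This
  is the model's design, but it narrows the measurable gap between the
  stochastic and mean-value solutions at small scale.
* A consequence worth knowing: the sequencing linkages hold for *every*
  ordered pair sharing a required type, whether or not the pair is
  co-assigned, and the indicators are shared across scenarios. With two or
  more distinct scenarios even an uncapacitated instance therefore incurs
  waiting whenever scenarios disagree about a pair's temporal relation; the
  analytic zero-wait guarantee for ample-capacity pools holds for the
  deterministic (`N = 1`) model only.
* With the heavy-tailed clinic durations (variance up to ~230 min² on
  ~12-minute means), the replicate optimization values `v^k_N` at small
  `N0` have standard deviations of tens of minutes, so the AOI carries
  noise of roughly ±0.07 at `K = 5`, `N' = 100`; whether a given run stops
  at the 5% tolerance in its first iterations is seed-sensitive at that
  scale. Larger `K` and `N'` (evaluation is cheap) stabilize it.
* MILP solve time grows steeply with cohort size; about 8 patients with
  `N = 100` scenarios is the practical single-CPU limit at the default gap.
* The mining stage assumes logs are trustworthy after simple validity
  filtering; no indoor-positioning signal processing is attempted.
* Only log-normal duration models are fitted, by moment matching (no
  distribution-family search).
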