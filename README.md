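# careflow

Care pathway mining and stochastic multi-resource scheduling for outpatient
clinics.

careflow is for operations analysts and health-services researchers who have
(or can emulate) room-level co-location logs from a Real-Time Location
System (RTLS) and want to turn them into resource allocation and sequencing
decisions. It covers the full chain:

* **Mine** dominant care pathways from patient/resource co-location logs:
  maximal segments with a constant room and co-located resource-type
  multiset are the atomic activities; visits with exactly equal activity
  sequences form pathway groups; per-activity durations get log-normal
  models by moment inversion.
* **Schedule** a cohort over a capacitated, heterogeneous resource pool by
  solving a two-stage stochastic mixed-integer linear program.
* **Quantify** solution quality with statistical optimality bounds and the
  value of the stochastic solution (VSS) against a mean-value baseline.

## The model

First-stage binaries choose the assignment `x[a,j]` of activities to
resource units and the pairwise sequencing of activities sharing a type:
`s1[a,a'] = 1` iff `a` does not start before `a'`, `s2[a,a'] = 1` iff `a`
starts before `a'` ends, with concurrency indicators `q[a,a',j]` and the
start-time capacity rule `sum_{a'} q[a,a',j] <= k_j - 1`. Second-stage
continuous start times `b_a` adapt to each duration realization and
minimize total waiting

```
sum_{a in A0} (b_a - t_a)  +  sum_{a in A1} (b_a - b_pre(a) - d_pre(a))
```

subject to release, precedence and big-M sequencing linkages. There are no
time or rank indices; capacity only needs checking at activity starts. The
expectation over random durations is handled by Sample Average
Approximation (SAA), and a Monte Carlo Optimization loop grows the sample
size `N` until the Approximate Optimality Index

```
AOI = |v̄_N' − v̄_N| / v̄_N'
```

(the relative gap between the statistical lower bound `v̄_N`, averaged SAA
optima, and upper bound `v̄_N'`, averaged fixed-first-stage simulations)
falls below a tolerance (default 5%).

MILPs are solved through HiGHS branch-and-cut (`scipy.optimize.milp`),
reached via the `python` on the PATH; everything else is pure R. An
exhaustive oracle and an independent schedule checker validate the solver
route in the test suite.

## Worked example

```r
library(careflow)

profiles <- ortho_pathway_profiles()   # mined dominant pathways + moments
print(profiles)
#> careflow pathway profiles: 5 pathways
#>   path 0 (38.03%): [Intake, Radiology Tech, Provider, Ortho Tech, Discharge]
#>   path 1 (24.55%): [Intake, Provider, Ortho Tech, Discharge]
#>   path 2 (13.93%): [Intake, Ortho Tech, Discharge]
#>   path 3 (13.78%): [Intake, Radiology Tech, Ortho Tech, Discharge]
#>   path 4 (9.71%): [Intake, Radiology Tech, Provider, Discharge]

cohort <- sample_cohort(profiles, n_patients = 4, arrival_interval = 10, seed = 11)
inst <- build_instance(cohort, profiles, default_ortho_pool(4))
print(inst)
#> careflow instance: 4 patients, 19 activities (4 initial), 5 resource units, horizon 240 min

mco <- run_mco(inst, mco_config(N0 = 20, n_prime = 100, K = 5,
                                epsilon = 0.05, max_iter = 4, seed = 5))
print(mco)
#> careflow MCO: 1 iteration(s), converged
#>   N = 20: v_bar_N = 33.710, v_bar_N' = 32.818, AOI = 0.0272
```

Reading: with 4 patients arriving every 10 minutes and one capacity-1 unit
each of Radiology Tech, Provider and Ortho Tech, the expected total waiting
time of the cohort is about 33 minutes; the SAA lower bound (33.7) and the
fresh-scenario upper bound (32.8) agree to within 2.7%, inside the 5%
tolerance, so `N = 20` scenarios already suffice at this scale.
`compute_vss(inst, mco)` then compares against the mean-value baseline on
the same retained scenarios, and `schedule_table()` / `write_gantt()`
export the planned schedule.

A command-line interface wraps the same pipeline (`mine`, `synth-rtls`,
`build-instance`, `sample`, `solve`, `evaluate`, `mco`, `experiment`); see
`system.file("cli", "careflow", package = "careflow")` and `careflow --help`.
Every command writes a JSON run manifest sufficient to replay it.

Because real RTLS logs are proprietary, `generate_synthetic_rtls()` emits
schema-faithful synthetic logs from any pathway profile set, and the test
suite verifies that mining recovers the generating pathways exactly
(proportions within binomial sampling error at 100,000 visits).

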