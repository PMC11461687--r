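test_that("the optimality index follows its definition and edge cases", {
  expect_equal(compute_aoi(96, 100), 0.04)
  expect_equal(compute_aoi(100, 100), 0)
  expect_equal(compute_aoi(0, 0), 0)
  expect_error(compute_aoi(3, 0), "undefined")
  expect_error(compute_aoi(3, -1), "non-negative")
})

test_that("MCO configuration enforces its ranges", {
  expect_error(mco_config(N0 = 0), "positive")
  expect_error(mco_config(N0 = 50, n_prime = 20), "n_prime")
  expect_error(mco_config(epsilon = 1.5), "\\(0, 1\\)")
  expect_error(mco_config(K = 0), "positive")
  cfg <- mco_config()
  expect_equal(cfg$N0, 100L)
  expect_equal(cfg$n_prime, 500L)
  expect_equal(cfg$K, 10L)
  expect_equal(cfg$epsilon, 0.05)
})

test_that("zero-variance durations terminate MCO at the first iteration with AOI 0", {
  prof <- toy_profile(c("Intake", "Provider"), means = c(2, 5))
  cohort <- data.table::data.table(patient_id = c("A", "B"), path_id = 0L,
                                   scheduled_time = c(0, 0))
  inst <- build_instance(cohort, prof,
                         resource_pool(c("Intake", "Intake", "Provider"),
                                       c(1, 1, 1)))
  mco <- run_mco(inst, mco_config(N0 = 2, n_prime = 4, K = 3, seed = 1))
  expect_true(mco$converged)
  expect_length(mco$iterations, 1)
  expect_equal(mco$aoi, 0)
  it <- mco$iterations[[1]]
  expect_equal(it$v_k_N, it$v_k_n_prime)
  expect_equal(it$v_bar_N, 5) # the deterministic bottleneck cost
  ## stored AOI column reproduces from the stored bounds
  expect_equal(it$aoi, compute_aoi(it$v_bar_N, it$v_bar_n_prime))
})

test_that("MCO trace is reproducible from its seed", {
  inst <- ortho_instance(2, 10, seed = 4)
  cfg <- mco_config(N0 = 3, n_prime = 6, K = 2, seed = 42, max_iter = 2)
  m1 <- run_mco(inst, cfg)
  m2 <- run_mco(inst, cfg)
  expect_equal(m1$v_bar_N, m2$v_bar_N)
  expect_equal(m1$v_bar_n_prime, m2$v_bar_n_prime)
  expect_equal(m1$aoi, m2$aoi)
  for (it in m1$iterations)
    expect_equal(it$aoi, compute_aoi(it$v_bar_N, it$v_bar_n_prime))
})

test_that("zero-variance VSS is exactly zero", {
  prof <- toy_profile(c("Intake", "Provider"), means = c(2, 5))
  cohort <- data.table::data.table(patient_id = c("A", "B"), path_id = 0L,
                                   scheduled_time = c(0, 0))
  inst <- build_instance(cohort, prof,
                         resource_pool(c("Intake", "Intake", "Provider"),
                                       c(1, 1, 1)))
  mco <- run_mco(inst, mco_config(N0 = 2, n_prime = 4, K = 2, seed = 3))
  vss <- compute_vss(inst, mco)
  expect_equal(vss$vss, 0)
  expect_equal(vss$ratio, 0)
  expect_equal(vss$difference_estimator, 0)
})

test_that("an engineered risky-first flow shop gives positive VSS", {
  ## two crossing chains on machines A (capacity 1) and B (capacity 1):
  ## patient P runs A then B with deterministic service; patient Q runs B
  ## then A, and Q's B service is heavy-tailed (mean 4 min, variance 400).
  ## At the rounded means, serving Q's B first costs 2 waiting minutes and
  ## serving P's B first costs 3, so the mean-value model picks the fragile
  ## order; under the realized distribution the fragile order costs
  ## E|L - 2| (about 3.5 min), so the hedge wins on average.
  prof <- pathway_profiles(
    activity_sequences = list(c("A", "B"), c("B", "A")),
    proportions = c(0.5, 0.5),
    duration_means = list(c(2, 1), c(4, 4)),
    duration_variances = list(c(0, 0), c(400, 0)))
  cohort <- data.table::data.table(patient_id = c("P", "Q"),
                                   path_id = c(0L, 1L),
                                   scheduled_time = c(0, 0))
  inst <- build_instance(cohort, prof, resource_pool(c("A", "B"), c(1, 1)))
  mco <- run_mco(inst,
                 mco_config(N0 = 1500, n_prime = 6000, K = 3, epsilon = 0.05,
                            max_iter = 1, seed = 8))
  vss <- compute_vss(inst, mco)
  expect_gt(vss$vss, 0)
  ## and in general VSS cannot be materially negative
  expect_gte(vss$vss, -2 * vss$se)
})

test_that("the experiment grid records one seeded row per cell", {
  prof <- ortho_pathway_profiles()
  grid <- list(n_patients = c(1, 2), interval = 10)
  res <- run_experiment_grid(prof, grid,
                             cfg = mco_config(N0 = 2, n_prime = 4, K = 2,
                                              max_iter = 1),
                             seed = 6)
  expect_equal(nrow(res), 2)
  expect_true(all(is.na(res$error)))
  ## a single patient has nothing to wait for
  one <- res[res$n_patients == 1, ]
  expect_equal(one$vss, 0)
  expect_equal(one$aoi, 0)
  ## re-running the grid reproduces it
  res2 <- run_experiment_grid(prof, grid,
                              cfg = mco_config(N0 = 2, n_prime = 4, K = 2,
                                               max_iter = 1),
                              seed = 6)
  expect_equal(res$vss, res2$vss)
  expect_equal(res$aoi, res2$aoi)
})
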