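test_that("cohorts arrive at fixed intervals with profile-weighted pathways", {
  prof <- ortho_pathway_profiles()
  one <- sample_cohort(prof, 1, 10, seed = 1)
  expect_equal(nrow(one), 1)
  expect_equal(one$scheduled_time, 0L)

  six <- sample_cohort(prof, 6, 10, seed = 1)
  expect_equal(six$scheduled_time, seq(0L, 50L, by = 10L)) # 6 arrivals/hour

  expect_identical(sample_cohort(prof, 20, 15, seed = 9),
                   sample_cohort(prof, 20, 15, seed = 9))

  ## pathway frequencies within 3 binomial SEs of the sampling weights
  n <- 50000
  big <- sample_cohort(prof, n, 10, seed = 4)
  for (p in prof) {
    phat <- mean(big$path_id == p$path_id)
    se <- sqrt(p$proportion * (1 - p$proportion) / n)
    expect_lt(abs(phat - p$proportion), 3 * se + 1e-9)
  }
})

test_that("cohort sampling validates its inputs", {
  prof <- ortho_pathway_profiles()
  expect_error(sample_cohort(prof, 0, 10), "positive")
  expect_error(sample_cohort(prof, 3, 0), "positive")
  bad <- prof
  bad[[1]]$proportion <- 0.9 * bad[[1]]$proportion
  expect_error(sample_cohort(bad, 3, 10), "sum to 1")
})

test_that("instances expand cohorts into per-patient precedence chains", {
  prof <- toy_profile(c("Intake", "Provider"), means = c(2, 5))
  cohort <- data.table::data.table(patient_id = c("A", "B"), path_id = 0L,
                                   scheduled_time = c(0, 10))
  pool <- resource_pool(c("Intake", "Provider"), c(2, 1))
  inst <- build_instance(cohort, prof, pool)
  acts <- inst$activities
  expect_equal(nrow(acts), 4)
  expect_equal(sum(acts$is_initial), 2)
  ## two 2-chains: each subsequent activity points at its patient's previous
  expect_equal(acts$pre, c(NA, 1L, NA, 3L))
  expect_equal(acts$scheduled_time[acts$is_initial], c(0, 10))

  ## the five-step clinic pathway builds a 5-chain in table order
  ortho <- ortho_pathway_profiles()
  c0 <- data.table::data.table(patient_id = "A", path_id = 0L,
                               scheduled_time = 0)
  i0 <- build_instance(c0, ortho, default_ortho_pool(1))
  expect_equal(i0$activities$types,
               c("Intake", "Radiology Tech", "Provider", "Ortho Tech",
                 "Discharge"))
  expect_equal(i0$activities$pre, c(NA, 1L, 2L, 3L, 4L))
})

test_that("requirements exceeding the pool are rejected at build time", {
  prof <- toy_profile(c("Intake", "Provider+Provider"), means = c(2, 5))
  cohort <- data.table::data.table(patient_id = "A", path_id = 0L,
                                   scheduled_time = 0)
  expect_error(
    build_instance(cohort, prof, resource_pool(c("Intake", "Provider"),
                                               c(1, 1))),
    "needs 2 unit")
  ## two provider units make the same profile buildable
  inst <- build_instance(cohort, prof,
                         resource_pool(c("Intake", "Provider", "Provider"),
                                       c(1, 1, 1)))
  expect_equal(unname(inst$V[2, "Provider"]), 2L)
  ## unknown type label names the label and path
  prof2 <- toy_profile(c("Intake", "MRI"), path_id = 7L)
  expect_error(
    build_instance(data.table::data.table(patient_id = "A", path_id = 7L,
                                          scheduled_time = 0),
                   prof2, resource_pool("Intake", 1)),
    "MRI")
})

test_that("scenario sampling is reproducible, integral and moment-faithful", {
  inst <- ortho_instance(3, 10, seed = 2)
  A <- nrow(inst$activities)
  D1 <- sample_scenarios(inst, 50, seed = 7)
  D2 <- sample_scenarios(inst, 50, seed = 7)
  expect_identical(unclass(D1), unclass(D2))
  expect_true(all(D1 >= 1))
  expect_true(all(D1 == round(D1)))
  expect_equal(dim(D1), c(50L, A))

  ## zero variance degenerates to the rounded means in every scenario
  flat <- toy_profile(c("Intake", "Provider"), means = c(2.4, 5.6))
  cflat <- data.table::data.table(patient_id = "A", path_id = 0L,
                                  scheduled_time = 0)
  iflat <- build_instance(cflat, flat, resource_pool(c("Intake", "Provider"),
                                                     c(1, 1)))
  Df <- sample_scenarios(iflat, 5, seed = 1)
  expect_true(all(Df[, 1] == 2) && all(Df[, 2] == 6))

  ## pre-rounding sampler reproduces the heavy-tailed technician moments
  par <- lognormal_from_moments(11.62, 185.52)
  x <- careflow:::with_seed(12, sample_lognormal(2e5, par))
  se_mean <- sqrt(185.52 / 2e5)
  expect_lt(abs(mean(x) - 11.62), 3 * se_mean)
  expect_equal(stats::var(x), 185.52, tolerance = 0.05)
})

test_that("mean-value durations round and clamp", {
  ortho <- ortho_pathway_profiles()
  c0 <- data.table::data.table(patient_id = "A", path_id = 0L,
                               scheduled_time = 0)
  i0 <- build_instance(c0, ortho, default_ortho_pool(1))
  expect_equal(as.vector(mean_value_durations(i0)), c(5L, 3L, 5L, 12L, 3L))

  tiny <- toy_profile(c("Intake", "Provider"), means = c(0.4, 3))
  it <- build_instance(c0[, .(patient_id, path_id = 0L, scheduled_time)],
                       tiny, resource_pool(c("Intake", "Provider"), c(1, 1)))
  expect_equal(as.vector(mean_value_durations(it)), c(1L, 3L))

  whole <- toy_profile(c("Intake", "Provider"), means = c(4, 7))
  iw <- build_instance(c0[, .(patient_id, path_id = 0L, scheduled_time)],
                       whole, resource_pool(c("Intake", "Provider"), c(1, 1)))
  expect_equal(as.vector(mean_value_durations(iw)), c(4L, 7L))
})

test_that("instances and scenarios round-trip through files", {
  inst <- ortho_instance(3, 10, seed = 8)
  td <- withr::local_tempdir()
  f <- file.path(td, "inst.json")
  write_instance(inst, f)
  back <- read_instance(f)
  expect_equal(as.data.frame(back$activities), as.data.frame(inst$activities))
  expect_equal(as.data.frame(back$pool), as.data.frame(inst$pool))
  expect_equal(back$V, inst$V)

  D <- sample_scenarios(inst, 10, seed = 3)
  fs <- file.path(td, "scen.csv")
  write_scenarios(D, fs)
  back_D <- read_scenarios(fs)
  expect_equal(dim(back_D), dim(D))
  expect_true(all(back_D == unclass(D)))
})
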