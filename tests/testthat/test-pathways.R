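make_patient_events <- function(...) {
  rows <- list(...)
  base <- as.POSIXct("2020-01-06 08:00:00", tz = "UTC")
  data.table::rbindlist(lapply(rows, function(r)
    data.table::data.table(
      patient_id = r$id, room_name = r$room, room_id = r$room,
      visit_start = base + 60 * r$vs, visit_end = base + 60 * r$ve,
      move_start = base + 60 * r$s, move_end = base + 60 * r$e)))
}

make_resource_events <- function(...) {
  rows <- list(...)
  base <- as.POSIXct("2020-01-06 08:00:00", tz = "UTC")
  data.table::rbindlist(lapply(rows, function(r)
    data.table::data.table(
      resource_id = r$id, resource_type = r$type, room_name = r$room,
      room_type = "Exam", start = base + 60 * r$s, end = base + 60 * r$e)))
}

test_that("a full patient-resource overlap yields one activity", {
  pe <- make_patient_events(list(id = "P1", room = "R", vs = 0, ve = 10,
                                 s = 0, e = 10))
  re <- make_resource_events(list(id = "prov1", type = "Provider", room = "R",
                                  s = 0, e = 10))
  obs <- extract_activities(pe, re)
  expect_equal(nrow(obs), 1)
  expect_equal(obs$resource_types, "Provider")
  expect_equal(obs$duration, 10)
  expect_equal(obs$ordinal, 0L)
})

test_that("a change of co-located resource types splits the activity", {
  pe <- make_patient_events(list(id = "P1", room = "R", vs = 0, ve = 10,
                                 s = 0, e = 10))
  re <- make_resource_events(
    list(id = "prov1", type = "Provider", room = "R", s = 0, e = 4),
    list(id = "tech1", type = "Ortho Tech", room = "R", s = 4, e = 10))
  obs <- extract_activities(pe, re)
  expect_equal(obs$resource_types, c("Provider", "Ortho Tech"))
  expect_equal(obs$duration, c(4, 6))
  expect_equal(obs$ordinal, c(0L, 1L))
})

test_that("a room change splits the activity even with the same staff", {
  pe <- make_patient_events(
    list(id = "P1", room = "R1", vs = 0, ve = 10, s = 0, e = 5),
    list(id = "P1", room = "R2", vs = 0, ve = 10, s = 5, e = 10))
  re <- make_resource_events(
    list(id = "prov1", type = "Provider", room = "R1", s = 0, e = 5),
    list(id = "prov1", type = "Provider", room = "R2", s = 5, e = 10))
  obs <- extract_activities(pe, re)
  expect_equal(nrow(obs), 2)
  expect_equal(obs$resource_types, c("Provider", "Provider"))
  expect_equal(obs$room_id, c("R1", "R2"))
})

test_that("a unit swap of the same type does not split; two units at once form a multiset", {
  pe <- make_patient_events(list(id = "P1", room = "R", vs = 0, ve = 12,
                                 s = 0, e = 12))
  re <- make_resource_events(
    list(id = "prov1", type = "Provider", room = "R", s = 0, e = 6),
    list(id = "prov2", type = "Provider", room = "R", s = 6, e = 12))
  obs <- extract_activities(pe, re)
  expect_equal(nrow(obs), 1)      # swap merges
  expect_equal(obs$duration, 12)
  re2 <- make_resource_events(
    list(id = "prov1", type = "Provider", room = "R", s = 0, e = 12),
    list(id = "prov2", type = "Provider", room = "R", s = 4, e = 8))
  obs2 <- extract_activities(pe, re2)
  expect_equal(obs2$resource_types, c("Provider", "Provider+Provider",
                                      "Provider"))
})

test_that("patients without co-location are flagged and excluded", {
  pe <- make_patient_events(
    list(id = "P1", room = "R", vs = 0, ve = 10, s = 0, e = 10),
    list(id = "P2", room = "Other", vs = 0, ve = 10, s = 0, e = 10))
  re <- make_resource_events(list(id = "prov1", type = "Provider", room = "R",
                                  s = 0, e = 10))
  obs <- extract_activities(pe, re)
  expect_equal(unique(obs$patient_id), "P1")
  expect_equal(attr(obs, "no_colocation"), "P2")
})

test_that("segmentation covers exactly the co-located time without overlap", {
  prof <- ortho_pathway_profiles()
  logs <- generate_synthetic_rtls(prof, 40, seed = 77)
  parsed_dir <- withr::local_tempdir()
  obs <- extract_activities(logs$patient_log, logs$resource_log)
  for (pid in unique(obs$patient_id)) {
    o <- obs[obs$patient_id == pid, ]
    o <- o[order(o$start), ]
    expect_true(all(o$end[-nrow(o)] <= o$start[-1]))   # no overlaps
    expect_equal(sum(o$duration), sum(o$end - o$start))
  }
  ## total co-located span equals the patient log span (generator co-locates
  ## every minute of every visit)
  pl <- logs$patient_log
  spans <- as.numeric(difftime(pl$move_end, pl$move_start, units = "mins"))
  expect_equal(sum(obs$duration), sum(spans))
})

test_that("parser enforces schema, reports row-level timestamp errors, counts cleaning", {
  td <- withr::local_tempdir()
  pp <- file.path(td, "p.csv"); rp <- file.path(td, "r.csv")

  ## header-only files parse to empty with zero drops
  writeLines(paste(careflow:::.patient_cols, collapse = ","), pp)
  writeLines(paste(careflow:::.resource_cols, collapse = ","), rp)
  out <- parse_rtls_logs(pp, rp)
  expect_equal(nrow(out$patient_events), 0)
  expect_equal(out$cleaning$patient_inverted_interval, 0)

  ## missing column named
  writeLines("patient_id,visit_start", pp)
  expect_error(parse_rtls_logs(pp, rp), "visit_end")

  ## unparseable timestamp names the row
  writeLines(c(paste(careflow:::.patient_cols, collapse = ","),
               "P1,2020-01-06T08:00:00,2020-01-06T09:00:00,not-a-time,2020-01-06T08:10:00,R,R"),
             pp)
  expect_error(parse_rtls_logs(pp, rp), "row 1")

  ## inverted interval dropped and counted
  writeLines(c(paste(careflow:::.patient_cols, collapse = ","),
               "P1,2020-01-06T08:00:00,2020-01-06T09:00:00,2020-01-06T08:20:00,2020-01-06T08:10:00,R,R",
               "P1,2020-01-06T08:00:00,2020-01-06T09:00:00,2020-01-06T08:00:00,2020-01-06T08:10:00,R,R"),
             pp)
  out <- parse_rtls_logs(pp, rp)
  expect_equal(out$cleaning$patient_inverted_interval, 1)
  expect_equal(nrow(out$patient_events), 1)
})

test_that("synthetic logs round-trip losslessly through write-then-parse", {
  prof <- ortho_pathway_profiles()
  logs <- generate_synthetic_rtls(prof, 25, seed = 5)
  td <- withr::local_tempdir()
  write_rtls_logs(logs, file.path(td, "p.csv"), file.path(td, "r.csv"))
  back <- parse_rtls_logs(file.path(td, "p.csv"), file.path(td, "r.csv"))
  orig_p <- data.table::setorder(data.table::copy(logs$patient_log),
                                 patient_id, move_start)
  expect_equal(as.data.frame(back$patient_events), as.data.frame(orig_p))
  orig_r <- data.table::setorder(data.table::copy(logs$resource_log),
                                 resource_id, start)
  expect_equal(as.data.frame(back$resource_events), as.data.frame(orig_r))
})

test_that("synthetic log generation is byte-deterministic under a seed", {
  prof <- ortho_pathway_profiles()
  td <- withr::local_tempdir()
  for (run in 1:2)
    write_rtls_logs(generate_synthetic_rtls(prof, 30, seed = 123),
                    file.path(td, sprintf("p%d.csv", run)),
                    file.path(td, sprintf("r%d.csv", run)))
  expect_identical(readLines(file.path(td, "p1.csv")),
                   readLines(file.path(td, "p2.csv")))
  expect_identical(readLines(file.path(td, "r1.csv")),
                   readLines(file.path(td, "r2.csv")))
})

test_that("pathway grouping counts, renormalizes and warns as specified", {
  base <- as.POSIXct("2020-01-06 08:00:00", tz = "UTC")
  mk <- function(pid, types, t0 = 0) {
    n <- length(types)
    list(pe = data.table::data.table(
      patient_id = pid, room_name = sprintf("%s-%d", pid, 1:n),
      room_id = sprintf("%s-%d", pid, 1:n),
      visit_start = base, visit_end = base + 3600,
      move_start = base + 60 * (t0 + 5 * (0:(n - 1))),
      move_end = base + 60 * (t0 + 5 * (1:n))),
      re = data.table::data.table(
        resource_id = paste0(types, "_1"), resource_type = types,
        room_name = sprintf("%s-%d", pid, 1:n), room_type = "Exam",
        start = base + 60 * (t0 + 5 * (0:(n - 1))),
        end = base + 60 * (t0 + 5 * (1:n))))
  }
  seqs <- c(rep(list(c("A", "B")), 5), rep(list(c("A", "C")), 3),
            rep(list("B"), 2))
  parts <- Map(mk, sprintf("P%02d", seq_along(seqs)), seqs)
  pe <- data.table::rbindlist(lapply(parts, `[[`, "pe"))
  re <- data.table::rbindlist(lapply(parts, `[[`, "re"))
  obs <- extract_activities(pe, re)

  g <- group_pathways(obs, top_k = 3)
  expect_equal(vapply(g, `[[`, numeric(1), "proportion"), c(0.5, 0.3, 0.2))
  expect_equal(g[[1]]$activity_sequence, c("A", "B"))
  expect_equal(attr(g, "counts"), c(5L, 3L, 2L))

  ## top 2 of 3: renormalized over the retained groups
  g2 <- group_pathways(obs, top_k = 2)
  expect_equal(vapply(g2, `[[`, numeric(1), "proportion"), c(5, 3) / 8)

  expect_warning(g3 <- group_pathways(obs, top_k = 10), "distinct")
  expect_equal(length(g3), 3)

  ## a single repeated visit collapses to one profile with proportion 1
  solo <- extract_activities(
    data.table::rbindlist(lapply(parts[1:3], `[[`, "pe")),
    data.table::rbindlist(lapply(parts[1:3], `[[`, "re")))
  g4 <- group_pathways(solo, top_k = 1)
  expect_equal(length(g4), 1)
  expect_equal(g4[[1]]$proportion, 1.0)
})

test_that("mining recovers the generating pathways from a synthetic corpus", {
  prof <- ortho_pathway_profiles()
  n <- 3000
  logs <- generate_synthetic_rtls(prof, n, seed = 31)
  obs <- extract_activities(logs$patient_log, logs$resource_log)
  mined <- group_pathways(obs, top_k = 5)
  ## exact sequence recovery
  mined_seqs <- lapply(mined, `[[`, "activity_sequence")
  true_seqs <- lapply(prof, `[[`, "activity_sequence")
  for (s in true_seqs)
    expect_true(any(vapply(mined_seqs, identical, TRUE, s)))
  ## proportions within 3 binomial standard errors
  for (k in seq_along(prof)) {
    p0 <- prof[[k]]$proportion
    got <- Filter(function(m) identical(m$activity_sequence,
                                        true_seqs[[k]]), mined)[[1]]
    se <- sqrt(p0 * (1 - p0) / n)
    expect_lt(abs(got$proportion - p0), 3 * se + 1e-9)
  }
  ## duration means recovered within sampling error of the rounded draws
  m0 <- Filter(function(m) identical(m$activity_sequence, true_seqs[[1]]),
               mined)[[1]]
  expect_equal(m0$duration_mean, prof[[1]]$duration_mean, tolerance = 0.2)
})

test_that("profiles round-trip through JSON", {
  prof <- ortho_pathway_profiles()
  td <- withr::local_tempdir()
  f <- file.path(td, "prof.json")
  write_profiles(prof, f, table_path = file.path(td, "prof.csv"))
  back <- read_profiles(f)
  expect_equal(unclass(back), unclass(prof), tolerance = 1e-12)
  tab <- utils::read.csv(file.path(td, "prof.csv"))
  expect_equal(nrow(tab), 5)
})
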