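# Synthetic registry: configuration, generation invariants, CSV round-trip.

test_that("configuration validation names the offending field", {
  expect_error(simulation_config(sex_ratio = 2), "sex_ratio")
  expect_error(simulation_config(completeness_october = 0),
               "completeness_october")
  expect_error(simulation_config(baseline_daily_rate = -1),
               "baseline_daily_rate")
  lev <- exposure_levels()[-1]
  expect_error(simulation_config(true_or = setNames(c(-1, rep(1, 7)), lev)),
               "true_or")
  expect_error(simulation_config(n_persons = 0), "n_persons")
})

test_that("generation is deterministic and dose 2 strictly follows dose 1", {
  cfg <- simulation_config(n_persons = 4000, n_departments = 2,
                           baseline_daily_rate = 5e-5, seed = 7)
  r1 <- generate_registry(cfg)
  r2 <- generate_registry(cfg)
  expect_identical(r1[c("persons", "vaccinations", "hospital_stays", "tests")],
                   r2[c("persons", "vaccinations", "hospital_stays", "tests")])
  r3 <- generate_registry(simulation_config(n_persons = 4000,
                                            n_departments = 2,
                                            baseline_daily_rate = 5e-5,
                                            seed = 8))
  expect_false(identical(r1$hospital_stays, r3$hospital_stays))

  v <- r1$vaccinations
  wide <- merge(v[v$dose_rank == 1, c("person_id", "date")],
                v[v$dose_rank == 2, c("person_id", "date")],
                by = "person_id", suffixes = c("_1", "_2"))
  expect_true(all(wide$date_2 > wide$date_1))
  # dose ranks contiguous: every dose-2 recipient has a dose 1
  expect_true(all(v$person_id[v$dose_rank == 2] %in%
                    v$person_id[v$dose_rank == 1]))
})

test_that("with all effects at 1 the event rate matches the baseline hazard", {
  lev <- exposure_levels()[-1]
  cfg <- simulation_config(
    n_persons = 30000, n_departments = 3, baseline_daily_rate = 4e-5,
    true_or = setNames(rep(1, 8), lev),
    covariate_effects = c(history = 1, infection = 1, least_deprived = 1),
    history_prevalence = 0, infection_rate = 0, dual_diagnosis_prob = c(
      myocarditis = 0, pericarditis = 0),
    completeness_october = 1, other_stay_rate = 0, seed = 21)
  r <- generate_registry(cfg)
  n_days <- as.integer(r$study_end - r$study_start) + 1
  cases <- detect_cases(r, "myocarditis")
  expected <- cfg$n_persons * n_days * cfg$baseline_daily_rate
  expect_lt(abs(nrow(cases) - expected), 3 * sqrt(expected))
})

test_that("final-month admissions are unrecorded at 1 - completeness", {
  cfg <- simulation_config(n_persons = 30000, n_departments = 3,
                           baseline_daily_rate = 1.5e-4,
                           other_stay_rate = 0.01, seed = 31)
  r <- generate_registry(cfg)
  s <- r$hospital_stays
  oct <- s[format(s$admission_date, "%Y-%m") == "2021-10", ]
  expect_gt(nrow(oct), 100)
  frac <- mean(!oct$recorded)
  p <- 1 - cfg$completeness_october
  expect_lt(abs(frac - p), 3 * sqrt(p * (1 - p) / nrow(oct)))
  # no unrecorded stays outside the final month
  other <- s[format(s$admission_date, "%Y-%m") != "2021-10", ]
  expect_true(all(other$recorded))
})

test_that("registry round-trips through CSV byte-identically", {
  r <- generate_registry(simulation_config(n_persons = 1500,
                                           baseline_daily_rate = 1e-4,
                                           seed = 3))
  dir <- withr::local_tempdir()
  write_registry(r, dir)
  r2 <- read_registry(dir)
  for (tbl in c("persons", "vaccinations", "hospital_stays", "tests")) {
    expect_equal(r[[tbl]], r2[[tbl]], info = tbl)
  }
  expect_equal(r$study_start, r2$study_start)
  expect_equal(r$study_end, r2$study_end)
})

test_that("empty registry writes header-only files that read back empty", {
  dir <- withr::local_tempdir()
  write_registry(empty_registry(), dir)
  for (f in c("persons.csv", "vaccinations.csv", "hospital_stays.csv",
              "tests.csv")) {
    expect_true(file.exists(file.path(dir, f)))
    expect_equal(length(readLines(file.path(dir, f))), 1L, info = f)
  }
  r <- read_registry(dir)
  expect_equal(nrow(r$persons), 0L)
  expect_equal(nrow(r$vaccinations), 0L)
})

test_that("schema violations are rejected with a row-numbered parse error", {
  r <- mk_registry(mk_persons(2),
                   vacc = mk_vacc(1, "BNT162b2", 1, "2021-06-01"))
  dir <- withr::local_tempdir()
  write_registry(r, dir)
  # duplicate dose rank
  vpath <- file.path(dir, "vaccinations.csv")
  v <- readLines(vpath)
  writeLines(c(v, "1,\"BNT162b2\",1,2021-06-20"), vpath)
  expect_error(read_registry(dir), "duplicate dose rank.*row")
  # malformed date
  writeLines(c(v[1], "1,\"BNT162b2\",1,June first"), vpath)
  expect_error(read_registry(dir), "malformed date.*row 1")
  # missing column
  writeLines(c("person_id,brand,dose_rank", "1,\"BNT162b2\",1"), vpath)
  expect_error(read_registry(dir), "missing column 'date'")
})
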