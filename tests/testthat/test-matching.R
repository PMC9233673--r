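# Matched control sampling: stratum constraints, without-replacement,
# incidence-density eligibility, determinism.

test_that("a stratum with exactly `ratio` eligible persons is forced", {
  # person 1 is the case; persons 2..11 are the only stratum mates
  r <- mk_registry(mk_persons(11),
                   stays = mk_stays(1, "2021-06-01", "I401"))
  cases <- detect_cases(r, "myocarditis")
  s1 <- build_matched_sets(r, cases, ratio = 10, seed = 1)
  s2 <- build_matched_sets(r, cases, ratio = 10, seed = 999)
  expect_setequal(s1$person_id[s1$role == "control"], 2:11)
  expect_setequal(s2$person_id[s2$role == "control"], 2:11)
  expect_equal(nrow(validate_sets(s1, r)), 0L)
})

test_that("incidence-density rule: future cases may serve as earlier controls", {
  # 12 persons in one stratum; person 2 becomes a case on Aug 1
  stays <- mk_stays(c(1, 2, 3), c("2021-06-01", "2021-08-01", "2021-09-01"),
                    c("I401", "I401", "I401"))
  r <- mk_registry(mk_persons(12), stays = stays)
  cases <- detect_cases(r, "myocarditis")

  # June 1 case: persons 2..12 minus the case = 11 candidates, person 2 still
  # eligible (diagnosed later)
  jun <- cases[cases$index_date == D("2021-06-01"), ]
  set_jun <- build_matched_sets(r, jun, ratio = 10, seed = 4)
  expect_equal(sum(set_jun$role == "control"), 10L)

  # Sept 1 case: persons 1 and 2 are prior cases, leaving only 9 eligible
  sep <- cases[cases$index_date == D("2021-09-01"), ]
  expect_error(build_matched_sets(r, sep, ratio = 10, seed = 4),
               "eligible controls")
  expect_warning(
    short <- build_matched_sets(r, sep, ratio = 10, seed = 4,
                                on_short = "keep"),
    "9 of 10")
  ctl <- short$person_id[short$role == "control"]
  expect_false(any(c(1, 2) %in% ctl))
})

test_that("controls are drawn without replacement and sets validate clean", {
  r <- small_registry()
  cases <- detect_cases(r, "myocarditis")
  sets <- build_matched_sets(r, cases, ratio = 10, seed = 2)
  ctl <- sets$person_id[sets$role == "control"]
  expect_false(anyDuplicated(ctl) > 0)
  expect_equal(sum(sets$role == "control"), 10L * nrow(cases))
  expect_equal(nrow(validate_sets(sets, r)), 0L)

  # determinism: same seed reproduces the draw; another seed changes it
  sets_b <- build_matched_sets(r, cases, ratio = 10, seed = 2)
  expect_identical(sets, sets_b)
  sets_c <- build_matched_sets(r, cases, ratio = 10, seed = 3)
  expect_false(identical(sets$person_id, sets_c$person_id))
})

test_that("validate_sets flags hand-built violations", {
  r <- mk_registry(mk_persons(30, dept = rep(c(1L, 2L), 15)),
                   stays = mk_stays(1, "2021-06-01", "I401"))
  cases <- detect_cases(r, "myocarditis")
  sets <- build_matched_sets(r, cases, ratio = 5, seed = 1)
  # swap one control for a person in another department
  other_dept <- setdiff(r$persons$person_id[r$persons$department == 2],
                        sets$person_id)[1]
  bad <- sets
  bad$person_id[which(bad$role == "control")[1]] <- other_dept
  v <- validate_sets(bad, r)
  expect_true(any(grepl("stratum", v$problem)))

  # duplicate a control within the condition
  dup <- rbind(sets, transform(sets[sets$role == "control", ][1, ],
                               set_id = "myoc_2"))
  v2 <- validate_sets(dup, r)
  expect_true(any(grepl("reused", v2$problem)))
})
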