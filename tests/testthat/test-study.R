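# Study driver: characteristics table, report bundle determinism, subgroup
# markers, sensitivity filters.

test_that("characteristics percentages are count/total x 100 at 1 decimal", {
  r <- small_registry()
  cases <- detect_cases(r, "myocarditis")
  sets <- build_matched_sets(r, cases, ratio = 10, seed = 5)
  tab <- build_analysis_table(r, sets)
  ch <- characteristics_table(tab, r)
  male <- ch[ch$variable == "sex" & ch$level == "Male", ]
  expect_equal(male$cases_pct,
               round(100 * male$cases_n / sum(tab$is_case), 1))
  expect_equal(male$controls_pct,
               round(100 * male$controls_n / sum(!tab$is_case), 1))
  # age brackets partition all members
  ages <- ch[ch$variable == "age_bracket", ]
  expect_equal(sum(ages$cases_n), sum(tab$is_case))
  expect_equal(sum(ages$controls_n), sum(!tab$is_case))
  # empty input: header-only table
  expect_equal(nrow(characteristics_table(tab[0, ], r)), 0L)
})

test_that("the report bundle is deterministic given config and seed", {
  r <- generate_registry(simulation_config(
    n_persons = 8000, n_departments = 2, baseline_daily_rate = 6e-5,
    seed = 17))
  cfg <- study_config(conditions = "myocarditis", ratio = 5, seed = 9)
  b1 <- run_study(r, cfg)
  b2 <- run_study(r, cfg)
  expect_identical(b1$myocarditis$association, b2$myocarditis$association)
  expect_identical(b1$myocarditis$characteristics,
                   b2$myocarditis$characteristics)
  expect_identical(b1$myocarditis$burden, b2$myocarditis$burden)
  # association counts are consistent with the case total
  assoc <- b1$myocarditis$association
  lev <- exposure_levels()
  expect_equal(sum(assoc$cases[assoc$term %in% lev]),
               nrow(b1$myocarditis$cases))
})

test_that("subgroup categories with no exposed case are marked not estimable", {
  # hand-built table: only BNT162b2 dose 2, 1-7d ever occurs among cases
  lev <- exposure_levels()
  mk_tab <- function(sex) {
    n <- 40
    cat <- rep("unexposed", 2 * n)
    cat[seq(1, 2 * n, 2)[1:12]] <- "BNT162b2 dose 2, 1-7d"   # cases, sets 1-12
    cat[seq(2, 2 * n, 2)[20:24]] <- "BNT162b2 dose 2, 1-7d"  # controls, sets 20-24
    data.frame(set_id = paste0(sex, rep(seq_len(n), each = 2)),
               is_case = rep(c(TRUE, FALSE), n),
               category = factor(cat, lev),
               history_carditis_5y = FALSE, infection_30d = FALSE,
               deprived = FALSE, sex = sex, age_years = 20L,
               stringsAsFactors = FALSE)
  }
  tab <- rbind(mk_tab("M"), mk_tab("F"))
  sub <- subgroup_or_table(tab, by_age = FALSE)
  est <- sub[sub$term == "BNT162b2 dose 2, 1-7d", ]
  expect_true(all(is.finite(est$aor)))
  expect_true(all(is.na(est$note)))
  rest <- sub[sub$term == "mRNA-1273 dose 2, 1-7d", ]
  expect_true(all(grepl("not estimable", rest$note)))
  expect_true(all(is.na(rest$aor)))
})

test_that("sensitivity filters drop exactly the intended cases", {
  r <- small_registry()
  cfg <- study_config(conditions = "myocarditis", ratio = 5, seed = 9)
  cases <- detect_cases(r, "myocarditis")
  sens <- run_sensitivity(r, "myocarditis", cfg,
                          which = c("restrict_before",
                                    "exclude_dual_diagnosis"))
  expect_equal(sens$restrict_before$n_cases,
               sum(cases$index_date < cfg$restrict_before))
  expect_equal(sens$exclude_dual_diagnosis$n_cases,
               sum(!cases$has_other_condition_code))
  expect_lt(sens$restrict_before$n_cases, nrow(cases))

  flags <- history_lookup(r, cases$person_id, cases$index_date)
  sens_h <- run_sensitivity(r, "myocarditis", cfg, which = "exclude_history")
  expect_equal(sens_h$exclude_history$n_cases,
               sum(!flags$history_carditis_5y))
})

test_that("burden rows appear only for significantly positive categories", {
  r <- small_registry()
  cases <- detect_cases(r, "myocarditis")
  sets <- build_matched_sets(r, cases, ratio = 10, seed = 5)
  tab <- build_analysis_table(r, sets)
  fit <- multivariable_fit(tab, drop_inestimable = TRUE)
  bt <- burden_table(fit, tab, r)
  if (nrow(bt)) {
    expect_true(all(bt$or_low > 1))
    expect_true(all(bt$attributable <= bt$exposed_cases_corrected))
    expect_true(all(abs(bt$excess_per_100k * bt$doses_per_case - 1e5) < 1e-6))
    expect_true(all(bt$exposed_cases_corrected >= bt$exposed_cases_raw))
  }
  # override reports also non-significant categories with exposed cases
  bt_all <- burden_table(fit, tab, r, require_significant = FALSE)
  expect_gte(nrow(bt_all), nrow(bt))
})
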