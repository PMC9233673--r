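# Exposure-window classification and covariate construction.

test_that("most-recent-dose rule with inclusive window boundaries", {
  idx <- D("2021-08-01")
  v1 <- mk_vacc(1, "BNT162b2", 2, format(idx - 4))
  expect_equal(classify_exposure(v1, idx), "BNT162b2 dose 2, 1-7d")

  # dose 1 ten days back, dose 2 three days back: most recent wins
  v2 <- mk_vacc(c(1, 1), "BNT162b2", c(1, 2),
                c(format(idx - 10), format(idx - 3)))
  expect_equal(classify_exposure(v2, idx), "BNT162b2 dose 2, 1-7d")

  # single dose beyond 21 days is non-exposed
  expect_equal(classify_exposure(mk_vacc(1, "mRNA-1273", 1, format(idx - 25)),
                                 idx), "unexposed")

  # boundary days: 1 and 7 in the first window, 8 and 21 in the second,
  # 0 and 22 unexposed
  for (case in list(list(1, "mRNA-1273 dose 1, 1-7d"),
                    list(7, "mRNA-1273 dose 1, 1-7d"),
                    list(8, "mRNA-1273 dose 1, 8-21d"),
                    list(21, "mRNA-1273 dose 1, 8-21d"),
                    list(0, "unexposed"),
                    list(22, "unexposed"))) {
    expect_equal(
      classify_exposure(mk_vacc(1, "mRNA-1273", 1, format(idx - case[[1]])),
                        idx),
      case[[2]], info = paste("d =", case[[1]]))
  }

  # a dose dated after the index date never counts
  v3 <- mk_vacc(c(1, 1), "BNT162b2", c(1, 2),
                c(format(idx - 5), format(idx + 3)))
  expect_equal(classify_exposure(v3, idx), "BNT162b2 dose 1, 1-7d")
  expect_equal(classify_exposure(mk_vacc(1, "BNT162b2", 1, format(idx + 3)),
                                 idx), "unexposed")
})

test_that("classification is invariant under calendar translation", {
  set.seed(14)
  idx <- D("2021-08-01")
  for (i in 1:25) {
    n_doses <- sample(0:2, 1)
    if (n_doses == 0) {
      v <- mk_vacc()
    } else {
      d1 <- idx - sample(0:60, 1)
      dates <- if (n_doses == 2) c(d1, d1 + sample(14:40, 1)) else d1
      v <- mk_vacc(rep(1, n_doses), sample(c("BNT162b2", "mRNA-1273"), 1),
                   seq_len(n_doses), format(dates))
    }
    base_cat <- classify_exposure(v, idx)
    for (shift in c(-30, 11, 90)) {
      v_s <- v
      if (nrow(v_s)) v_s$date <- v_s$date + shift
      expect_equal(classify_exposure(v_s, idx + shift), base_cat,
                   info = paste("rep", i, "shift", shift))
    }
  }
})

test_that("the nine categories partition synthetic cases exactly", {
  r <- small_registry()
  cases <- detect_cases(r, "myocarditis")
  sets <- build_matched_sets(r, cases, ratio = 10, seed = 5)
  tab <- build_analysis_table(r, sets)
  expect_false(anyNA(tab$category))
  counts <- table(tab$category[tab$is_case])
  expect_equal(length(counts), 9L)
  expect_equal(sum(counts), nrow(cases))
  expect_equal(sum(table(tab$category)), nrow(tab))
})

test_that("deprivation binarizes quintiles 1-2 vs 3-5 and never imputes", {
  r <- mk_registry(mk_persons(5, depr = 1:5))
  idx <- D("2021-08-01")
  expect_false(build_covariates(r, 2, idx)$deprived)  # quintile 2
  expect_true(build_covariates(r, 3, idx)$deprived)   # quintile 3
  cov5 <- build_covariates(r, 5, idx)
  expect_equal(as.character(cov5$category), "unexposed")
  expect_false(cov5$history_carditis_5y)
  expect_false(cov5$infection_30d)
  expect_true(cov5$deprived)

  r$persons$deprivation_quintile[1] <- NA
  expect_error(build_covariates(r, 1, idx), "imputation")
})
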