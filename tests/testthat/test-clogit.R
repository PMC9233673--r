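# Conditional logistic likelihood and Newton-Raphson fit.

test_that("uniform softmax value at beta = 0 and additivity over sets", {
  d <- data.frame(set_id = rep(1, 11), is_case = c(TRUE, rep(FALSE, 10)))
  x <- matrix(rnorm(11), dimnames = list(NULL, "x"))
  ll1 <- conditional_loglik(0, x, d$is_case, d$set_id)
  expect_equal(as.numeric(ll1), -log(11), tolerance = 1e-12)

  d2 <- rbind(d, transform(d, set_id = 2))
  x2 <- rbind(x, x)
  ll2 <- conditional_loglik(0, x2, d2$is_case, d2$set_id)
  expect_equal(as.numeric(ll2), 2 * as.numeric(ll1), tolerance = 1e-12)
})

test_that("value, gradient and Hessian match brute-force enumeration", {
  set.seed(8)
  for (rep in 1:8) {
    rd <- random_clogit_data(n_sets = 15, ratio = 3, k = 3)
    beta <- rnorm(3, sd = 0.5)
    ll <- conditional_loglik(beta, rd$x, rd$d$is_case, rd$d$set_id)
    expect_equal(as.numeric(ll),
                 brute_loglik(beta, rd$x, rd$d$is_case, rd$d$set_id),
                 tolerance = 1e-10)
    g_num <- vapply(1:3, function(j) {
      h <- 1e-6; e <- beta; e[j] <- e[j] + h
      (brute_loglik(e, rd$x, rd$d$is_case, rd$d$set_id) -
         brute_loglik(beta, rd$x, rd$d$is_case, rd$d$set_id)) / h
    }, numeric(1))
    expect_equal(unname(attr(ll, "gradient")), g_num, tolerance = 1e-4)
    hess <- attr(ll, "hessian")
    expect_equal(hess, t(hess), tolerance = 1e-10)
    expect_true(all(eigen(-hess, only.values = TRUE)$values > -1e-8))
  }
})

test_that("likelihood is invariant to control relabeling and set order", {
  set.seed(9)
  rd <- random_clogit_data(n_sets = 20, ratio = 4, k = 2)
  beta <- c(0.4, -0.3)
  base <- as.numeric(conditional_loglik(beta, rd$x, rd$d$is_case, rd$d$set_id))
  # permute rows wholesale (controls relabeled within sets, sets reordered)
  perm <- sample(nrow(rd$d))
  ll_p <- as.numeric(conditional_loglik(beta, rd$x[perm, ],
                                        rd$d$is_case[perm],
                                        rd$d$set_id[perm]))
  expect_equal(ll_p, base, tolerance = 1e-12)
})

test_that("1:1 discordant pairs give the closed-form odds ratio exactly", {
  d <- discordant_sets(n10 = 30, n01 = 10, n_conc = 10)
  fit <- clogit_fit(as.matrix(d["x"]), d$is_case, d$set_id)
  expect_equal(unname(fit$beta), log(3), tolerance = 1e-8)
  expect_equal(fit$or_table$or, 3, tolerance = 1e-8)
  expect_true(fit$converged)
  # Wald CI brackets the estimate; covariance symmetric positive definite
  expect_true(fit$or_table$ci_low < 3 && fit$or_table$ci_high > 3)
  expect_true(all(eigen(fit$cov, only.values = TRUE)$values > 0))
  # score vanishes at the optimum
  ll <- conditional_loglik(fit$beta, as.matrix(d["x"]), d$is_case, d$set_id)
  expect_lt(max(abs(attr(ll, "gradient"))), 1e-8)
})

test_that("degenerate inputs raise structural errors", {
  d <- discordant_sets(5, 5, 3)
  # a set with no case
  bad_case <- d$is_case
  bad_case[1] <- FALSE
  expect_error(clogit_fit(as.matrix(d["x"]), bad_case, d$set_id),
               "exactly one case")
  # all-concordant sets: exposure constant within every set
  conc <- discordant_sets(0, 0, 8)
  expect_error(clogit_fit(as.matrix(conc["x"]), conc$is_case, conc$set_id),
               "within-set variation")
  # complete separation: every case exposed, no control exposed
  sep <- discordant_sets(25, 0, 0)
  expect_error(clogit_fit(as.matrix(sep["x"]), sep$is_case, sep$set_id),
               "separation|converge")
})

test_that("adding a case-exposed discordant set never lowers the estimate", {
  d <- discordant_sets(12, 8, 5)
  fit0 <- clogit_fit(as.matrix(d["x"]), d$is_case, d$set_id)
  d_plus <- rbind(d, data.frame(set_id = max(d$set_id) + 1,
                                is_case = c(TRUE, FALSE), x = c(1, 0)))
  fit1 <- clogit_fit(as.matrix(d_plus["x"]), d_plus$is_case, d_plus$set_id)
  expect_gte(fit1$beta, fit0$beta)
})

test_that("estimates agree with the survival-package oracle", {
  skip_if_not_installed("survival")
  set.seed(10)
  for (rep in 1:5) {
    rd <- random_clogit_data(n_sets = 50, ratio = 3, k = 3)
    fit <- clogit_fit(rd$x, rd$d$is_case, rd$d$set_id)
    df <- cbind(rd$d, as.data.frame(rd$x))
    oracle <- survival::coxph(
      survival::Surv(rep(1, nrow(df)), is_case) ~ x1 + x2 + x3 +
        survival::strata(set_id), data = df, method = "exact")
    expect_equal(unname(fit$beta), unname(coef(oracle)), tolerance = 1e-6)
  }
})

test_that("null data yield odds ratios near 1 in uni- and multivariable fits", {
  set.seed(12)
  d <- simulate_matched_binary(400, ratio = 10, exposure_prev = 0.15,
                               true_or = 1)
  fit <- clogit_fit(as.matrix(d["x"]), d$is_case, d$set_id)
  expect_true(fit$or_table$ci_low < 1 && fit$or_table$ci_high > 1)
})
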