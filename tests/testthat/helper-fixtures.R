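# Hand-built fixtures for the ascertainment / matching / exposure tests.

D <- function(x) as.Date(x)

mk_persons <- function(n, sex = "M", age = 30L, dept = 1L, depr = 1L) {
  data.frame(person_id = seq_len(n), sex = rep_len(sex, n),
             age_years = rep_len(as.integer(age), n),
             department = rep_len(as.integer(dept), n),
             deprivation_quintile = rep_len(as.integer(depr), n),
             stringsAsFactors = FALSE)
}

mk_stays <- function(person_id = integer(), admission = character(),
                     codes = character(), recorded = TRUE, los = 3L) {
  adm <- D(admission)
  data.frame(person_id = as.integer(person_id), admission_date = adm,
             discharge_date = adm + los, icd10_codes = codes,
             recorded = rep_len(recorded, length(person_id)),
             stringsAsFactors = FALSE)
}

mk_vacc <- function(person_id = integer(), brand = character(),
                    dose_rank = integer(), date = character()) {
  data.frame(person_id = as.integer(person_id), brand = brand,
             dose_rank = as.integer(dose_rank), date = D(date),
             stringsAsFactors = FALSE)
}

mk_tests <- function(person_id = integer(), date = character(),
                     result = "positive") {
  data.frame(person_id = as.integer(person_id), date = D(date),
             result = rep_len(result, length(person_id)),
             stringsAsFactors = FALSE)
}

mk_registry <- function(persons, stays = NULL, vacc = NULL, tests = NULL,
                        start = "2021-05-12", end = "2021-10-31") {
  new_registry(persons, vacc %||% mk_vacc(), stays %||% mk_stays(),
               tests %||% mk_tests(), D(start), D(end))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Small generated registry shared by several tests.
small_registry <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- simulation_config(n_persons = 12000, n_departments = 3,
                               baseline_daily_rate = 5e-5, seed = 99)
      cache <<- generate_registry(cfg)
    }
    cache
  }
})

# 1:1 sets with given numbers of case-exposed and control-exposed discordant
# pairs plus concordant padding; the conditional MLE is log(n10/n01).
discordant_sets <- function(n10, n01, n_conc = 10) {
  n <- n10 + n01 + 2 * n_conc
  x_case <- c(rep(1, n10), rep(0, n01), rep(1, n_conc), rep(0, n_conc))
  x_ctl <- c(rep(0, n10), rep(1, n01), rep(1, n_conc), rep(0, n_conc))
  data.frame(set_id = rep(seq_len(n), each = 2),
             is_case = rep(c(TRUE, FALSE), n),
             x = as.numeric(rbind(x_case, x_ctl)))
}

# Random small matched datasets with a few covariates, for oracle checks.
random_clogit_data <- function(n_sets = 40, ratio = 4, k = 3) {
  m <- ratio + 1
  d <- data.frame(set_id = rep(seq_len(n_sets), each = m),
                  is_case = rep(c(TRUE, rep(FALSE, ratio)), n_sets))
  x <- matrix(0, nrow(d), k, dimnames = list(NULL, paste0("x", seq_len(k))))
  x[, 1] <- as.numeric(runif(nrow(d)) < 0.35)
  if (k > 1) for (j in 2:k) x[, j] <- rnorm(nrow(d))
  list(d = d, x = x)
}

# Brute-force conditional log-likelihood: denominator enumerated term by term.
brute_loglik <- function(beta, x, is_case, set_id) {
  sum(vapply(split(seq_along(set_id), set_id), function(ix) {
    eta <- drop(x[ix, , drop = FALSE] %*% beta)
    eta[is_case[ix]] - log(sum(exp(eta)))
  }, numeric(1)))
}
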