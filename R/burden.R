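# Vaccine-attributable burden: attributable cases, excess cases per 100,000
# doses, doses per attributable case, with delta-method confidence intervals.
#
# With the adjusted odds ratio standing in for the relative risk (rare
# events), the attributable fraction among exposed cases is (OR - 1)/OR, so
# A = E_c (OR - 1)/OR attributable cases among E_c exposed cases. On the
# log-OR scale A(beta) = E_c (1 - e^{-beta}), and the delta method gives
# se(A) = E_c e^{-beta} se(beta).

#' Attributable cases among exposed cases
#'
#' @param E_c Exposed case count (may be non-integer after reporting
#'   correction).
#' @param or_hat Odds ratio point estimate (> 0).
#' @return `E_c * (or_hat - 1) / or_hat`, clipped at 0 (with a warning) when
#'   `or_hat < 1`.
#' @export
attributable_cases <- function(E_c, or_hat) {
  if (any(or_hat <= 0)) stopf("or_hat must be > 0")
  if (any(E_c < 0)) stopf("E_c must be >= 0")
  a <- E_c * (or_hat - 1) / or_hat
  if (any(a < 0)) {
    warning("odds ratio < 1: attributable cases clipped at 0", call. = FALSE)
    a <- pmax(a, 0)
  }
  a
}

#' Correct exposed-case counts for reporting completeness
#'
#' Divides each month's exposed-case count by that month's reporting
#' completeness (default: 0.78 for October 2021, 1 otherwise), compensating
#' for hospital stays not yet entered in the discharge database.
#'
#' @param counts_by_month Named numeric vector; names are `"YYYY-MM"` keys.
#' @param completeness_by_month Named numeric vector of completeness in
#'   (0, 1]; months absent from it default to 1.
#' @return Corrected counts, same names.
#' @export
correct_for_completeness <- function(counts_by_month,
                                     completeness_by_month = c("2021-10" = 0.78)) {
  if (any(completeness_by_month <= 0 | completeness_by_month > 1)) {
    stopf("completeness must be in (0, 1]")
  }
  comp <- rep(1, length(counts_by_month))
  hit <- match(names(counts_by_month), names(completeness_by_month))
  comp[!is.na(hit)] <- completeness_by_month[hit[!is.na(hit)]]
  counts_by_month / comp
}

#' Delta-method confidence interval for attributable cases
#'
#' Treats the exposed-case count as fixed and propagates the variance of the
#' log odds ratio through `A(beta) = E_c (1 - exp(-beta))`:
#' `se(A) = E_c exp(-beta) se(beta)`; the 95% interval is `A +/- 1.96 se(A)`
#' with the lower bound clipped at 0.
#'
#' @param E_c Exposed case count.
#' @param beta_hat Log odds ratio estimate.
#' @param se_beta Standard error of `beta_hat` (>= 0).
#' @param level Confidence level.
#' @return List with `A`, `se`, `lower`, `upper`.
#' @export
delta_ci <- function(E_c, beta_hat, se_beta, level = 0.95) {
  if (any(se_beta < 0)) stopf("se_beta must be >= 0")
  if (any(E_c < 0)) stopf("E_c must be >= 0")
  z <- qnorm(1 - (1 - level) / 2)
  a <- E_c * (1 - exp(-beta_hat))
  se <- E_c * exp(-beta_hat) * se_beta
  list(A = a, se = se, lower = pmax(a - z * se, 0), upper = a + z * se)
}

#' Parametric bootstrap confidence interval for attributable cases
#'
#' Optional cross-check of [delta_ci()]: draws `beta* ~ N(beta_hat,
#' se_beta^2)` and takes percentile bounds of `A(beta*)`.
#'
#' @inheritParams delta_ci
#' @param n_draws Number of normal draws.
#' @return List with `A`, `lower`, `upper`.
#' @export
bootstrap_ci <- function(E_c, beta_hat, se_beta, level = 0.95,
                         n_draws = 1e5) {
  b <- rnorm(n_draws, beta_hat, se_beta)
  a <- E_c * (1 - exp(-b))
  qs <- quantile(a, c((1 - level) / 2, 1 - (1 - level) / 2), names = FALSE)
  list(A = E_c * (1 - exp(-beta_hat)), lower = qs[1], upper = qs[2])
}

#' Population burden metrics
#'
#' Converts attributable cases and the administered-dose denominator into
#' excess cases per 100,000 doses and its reciprocal, doses per attributable
#' case. Confidence bounds are monotone transforms of the bounds on `A`
#' (doses-per-case bounds swap, since the transform is decreasing). The
#' identity `excess_per_100k * doses_per_case = 100000` holds exactly before
#' display rounding.
#'
#' @param A Attributable cases (>= 0).
#' @param A_ci Length-2 vector `c(lower, upper)` for `A`.
#' @param doses Administered dose count (> 0).
#' @return List with `excess_per_100k` (+ `_low`/`_high`) and
#'   `doses_per_case` (+ `_low`/`_high`; `Inf` when `A = 0`).
#' @export
burden_metrics <- function(A, A_ci, doses) {
  if (doses <= 0) stopf("doses must be > 0")
  if (A < 0) stopf("A must be >= 0")
  dpc <- function(a) if (a == 0) Inf else doses / a
  list(
    excess_per_100k = A / doses * 1e5,
    excess_per_100k_low = A_ci[1] / doses * 1e5,
    excess_per_100k_high = A_ci[2] / doses * 1e5,
    doses_per_case = dpc(A),
    doses_per_case_low = dpc(A_ci[2]),
    doses_per_case_high = dpc(A_ci[1])
  )
}

#' Display rounding for doses-per-case
#'
#' Report convention: nearest 1,000 at or above 100,000 doses per case,
#' nearest 100 below.
#' @param x Doses-per-case values.
#' @return Rounded values.
#' @export
round_doses_per_case <- function(x) {
  ifelse(is.finite(x) & x >= 1e5, round(x / 1000) * 1000, round(x / 100) * 100)
}

#' Count administered doses in a registry
#'
#' Doses of a brand and rank administered within the study window, optionally
#' restricted to a sex and/or an age bracket of the recipients.
#'
#' @param registry A `registry`.
#' @param brand,dose_rank Brand name and dose rank.
#' @param sex Optional `"M"`/`"F"` filter.
#' @param age_min,age_max Optional completed-age bounds (inclusive).
#' @return Integer dose count.
#' @export
count_doses <- function(registry, brand, dose_rank, sex = NULL,
                        age_min = NULL, age_max = NULL) {
  v <- registry$vaccinations
  v <- v[v$brand == brand & v$dose_rank == dose_rank &
           v$date >= registry$study_start & v$date <= registry$study_end, ,
         drop = FALSE]
  if (!is.null(sex) || !is.null(age_min) || !is.null(age_max)) {
    p <- registry$persons
    idx <- match(v$person_id, p$person_id)
    keep <- rep(TRUE, nrow(v))
    if (!is.null(sex)) keep <- keep & p$sex[idx] == sex
    if (!is.null(age_min)) keep <- keep & p$age_years[idx] >= age_min
    if (!is.null(age_max)) keep <- keep & p$age_years[idx] <= age_max
    v <- v[keep, , drop = FALSE]
  }
  nrow(v)
}

#' Burden table from a fitted association model
#'
#' For each brand x dose with a significantly positive adjusted association
#' in the 1-7 day window (95% CI excluding 1; override with
#' `require_significant = FALSE`), computes the completeness-corrected
#' exposed-case count, attributable cases with delta-method CI, and the two
#' population burden metrics against the administered-dose denominator.
#'
#' @param fit A `clogit_fit` whose terms include the 1-7 day categories.
#' @param tab The analysis table the fit was computed from (case rows are
#'   used for exposed-case counts by calendar month).
#' @param registry The registry (dose denominators).
#' @param sex,age_min,age_max Optional subgroup restriction for the dose
#'   denominator (must match how `tab` was subset).
#' @param completeness_by_month Passed to [correct_for_completeness()].
#' @param require_significant Only report categories whose adjusted OR CI
#'   excludes 1 (default), mirroring the report convention.
#' @return Data frame, one row per reported brand x dose: counts, OR, `A`
#'   with CI, doses, `excess_per_100k` with CI, `doses_per_case` with CI and
#'   its display rounding.
#' @export
burden_table <- function(fit, tab, registry, sex = NULL, age_min = NULL,
                         age_max = NULL,
                         completeness_by_month = c("2021-10" = 0.78),
                         require_significant = TRUE) {
  rows <- list()
  for (brand in BRANDS) {
    for (rank in 1:2) {
      term <- paste0(brand, " dose ", rank, ", 1-7d")
      i <- match(term, fit$or_table$term)
      if (is.na(i)) next
      est <- fit$or_table[i, ]
      if (require_significant && !(est$ci_low > 1)) next
      case_rows <- tab$is_case & tab$category == term
      if (!any(case_rows)) next
      counts <- table(month_key(tab$index_date[case_rows]))
      e_c <- sum(correct_for_completeness(
        setNames(as.numeric(counts), names(counts)), completeness_by_month))
      dci <- delta_ci(e_c, est$beta, est$se)
      doses <- count_doses(registry, brand, rank, sex, age_min, age_max)
      if (doses == 0) next
      bm <- burden_metrics(dci$A, c(dci$lower, dci$upper), doses)
      rows[[term]] <- data.frame(
        brand = brand, dose_rank = rank,
        exposed_cases_raw = sum(case_rows), exposed_cases_corrected = e_c,
        or = est$or, or_low = est$ci_low, or_high = est$ci_high,
        attributable = dci$A, attributable_low = dci$lower,
        attributable_high = dci$upper, doses = doses,
        excess_per_100k = bm$excess_per_100k,
        excess_per_100k_low = bm$excess_per_100k_low,
        excess_per_100k_high = bm$excess_per_100k_high,
        doses_per_case = bm$doses_per_case,
        doses_per_case_low = bm$doses_per_case_low,
        doses_per_case_high = bm$doses_per_case_high,
        doses_per_case_display = round_doses_per_case(bm$doses_per_case),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(brand = character(), dose_rank = integer(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
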