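# Study orchestration: full matched case-control analysis for both
# conditions, subgroup fits by sex and age bracket, burden tables, and the
# sensitivity analyses (period restriction and the four exclusions).

AGE_BRACKETS <- data.frame(
  label = c("12-17", "18-24", "25-29", "30-39", "40-50"),
  min = c(12L, 18L, 25L, 30L, 40L),
  max = c(17L, 24L, 29L, 39L, 50L),
  stringsAsFactors = FALSE
)

#' Age bracket label for completed ages
#' @param age_years Integer ages.
#' @return Character bracket labels (`NA` outside 12-50).
#' @export
age_bracket <- function(age_years) {
  idx <- findInterval(age_years, AGE_BRACKETS$min)
  idx[age_years < AGE_BRACKETS$min[1] |
        age_years > AGE_BRACKETS$max[nrow(AGE_BRACKETS)]] <- NA
  AGE_BRACKETS$label[idx]
}

#' Study configuration
#'
#' @param conditions Conditions to analyse.
#' @param ratio Matched controls per case.
#' @param seed Seed for control sampling.
#' @param restrict_before Sensitivity cutoff date (cases at or after it are
#'   dropped in the period-restricted analysis).
#' @param recent_hospitalization_days Lookback for the
#'   recent-hospitalization exclusion.
#' @param completeness_by_month Reporting completeness used in burden
#'   correction.
#' @return List of class `study_config`.
#' @export
study_config <- function(conditions = CONDITIONS, ratio = 10L, seed = 1L,
                         restrict_before = as.Date("2021-07-19"),
                         recent_hospitalization_days = 28L,
                         completeness_by_month = c("2021-10" = 0.78)) {
  structure(list(conditions = conditions, ratio = as.integer(ratio),
                 seed = as.integer(seed),
                 restrict_before = as.Date(restrict_before),
                 recent_hospitalization_days = as.integer(recent_hospitalization_days),
                 completeness_by_month = completeness_by_month),
            class = "study_config")
}

#' Characteristics table of cases and controls
#'
#' Counts and percentages (one decimal, of the column total) by role for sex,
#' age bracket, deprivation group, 5-year carditis history, 30-day SARS-CoV-2
#' infection, and receipt of any mRNA vaccine on or before the index date.
#'
#' @param tab An analysis table from [build_analysis_table()].
#' @param registry The registry (for vaccine receipt).
#' @return Data frame: `variable`, `level`, `cases_n`, `cases_pct`,
#'   `controls_n`, `controls_pct`.
#' @export
characteristics_table <- function(tab, registry) {
  out <- data.frame(variable = character(), level = character(),
                    cases_n = integer(), cases_pct = numeric(),
                    controls_n = integer(), controls_pct = numeric(),
                    stringsAsFactors = FALSE)
  if (nrow(tab) == 0L) return(out)
  v <- registry$vaccinations
  m <- merge(tab[, c("person_id", "index_date")], v, by = "person_id")
  received <- unique(paste(m$person_id, m$index_date)[m$date <= m$index_date])
  any_mrna <- paste(tab$person_id, tab$index_date) %in% received

  n_case <- sum(tab$is_case)
  n_ctl <- sum(!tab$is_case)
  row <- function(variable, level, flag) {
    data.frame(variable = variable, level = level,
               cases_n = sum(flag & tab$is_case),
               cases_pct = pct(sum(flag & tab$is_case), n_case),
               controls_n = sum(flag & !tab$is_case),
               controls_pct = pct(sum(flag & !tab$is_case), n_ctl),
               stringsAsFactors = FALSE)
  }
  rows <- list(row("sex", "Male", tab$sex == "M"),
               row("sex", "Female", tab$sex == "F"))
  for (i in seq_len(nrow(AGE_BRACKETS))) {
    b <- AGE_BRACKETS[i, ]
    rows[[length(rows) + 1L]] <-
      row("age_bracket", b$label,
          tab$age_years >= b$min & tab$age_years <= b$max)
  }
  rows <- c(rows, list(
    row("deprivation", "Most deprived", tab$deprived),
    row("deprivation", "Least deprived", !tab$deprived),
    row("history_carditis_5y", "Yes", tab$history_carditis_5y),
    row("infection_30d", "Yes", tab$infection_30d),
    row("mrna_vaccine_receipt", "Yes", any_mrna)))
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Association table (overall model)
#'
#' Per exposure category: case and control counts, univariable OR and
#' multivariable (adjusted) OR with 95% CIs; covariate rows carry the
#' multivariable estimates only.
#'
#' @param tab An analysis table.
#' @param uni,multi Fits from [univariable_exposure_fit()] and
#'   [multivariable_fit()]; computed if `NULL`.
#' @return Data frame with one row per category/covariate.
#' @export
association_table <- function(tab, uni = NULL, multi = NULL) {
  if (is.null(uni)) uni <- univariable_exposure_fit(tab)
  if (is.null(multi)) multi <- multivariable_fit(tab)
  lev <- exposure_levels()
  counts_case <- table(factor(tab$category[tab$is_case], lev))
  counts_ctl <- table(factor(tab$category[!tab$is_case], lev))
  pull <- function(fit, term) {
    i <- match(term, fit$or_table$term)
    if (is.na(i)) rep(NA_real_, 3) else
      unlist(fit$or_table[i, c("or", "ci_low", "ci_high")], use.names = FALSE)
  }
  rows <- lapply(lev, function(l) {
    u <- pull(uni, l); m <- pull(multi, l)
    data.frame(term = l, cases = as.integer(counts_case[[l]]),
               controls = as.integer(counts_ctl[[l]]),
               or = u[1], or_low = u[2], or_high = u[3],
               aor = m[1], aor_low = m[2], aor_high = m[3],
               reference = l == "unexposed", stringsAsFactors = FALSE)
  })
  for (cv in c("history_carditis_5y", "infection_30d", "least_deprived")) {
    m <- pull(multi, cv)
    flag <- if (cv == "least_deprived") !tab$deprived else tab[[cv]]
    rows[[length(rows) + 1L]] <- data.frame(
      term = cv, cases = sum(flag & tab$is_case),
      controls = sum(flag & !tab$is_case),
      or = NA_real_, or_low = NA_real_, or_high = NA_real_,
      aor = m[1], aor_low = m[2], aor_high = m[3],
      reference = FALSE, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Subgroup odds-ratio table
#'
#' Refits the multivariable model within sex and sex x age-bracket subgroups
#' (matched sets are homogeneous in sex and age, so subgrouping filters whole
#' sets) and reports the four brand x dose 1-7 day categories. Categories
#' with no exposed case in a subgroup are marked not estimable instead of
#' failing.
#'
#' @param tab An analysis table (one condition).
#' @param by_age Also split by age bracket (default) or by sex only.
#' @return Data frame: subgroup descriptors, `n_cases`, term, OR with CI (NA
#'   with a `note` when not estimable).
#' @export
subgroup_or_table <- function(tab, by_age = TRUE) {
  sexes <- c("M", "F")
  brackets <- if (by_age) AGE_BRACKETS$label else "12-50"
  terms <- paste0(rep(BRANDS, each = 2), " dose ", 1:2, ", 1-7d")
  rows <- list()
  for (sx in sexes) {
    for (br in brackets) {
      sub <- tab[tab$sex == sx, , drop = FALSE]
      if (br != "12-50") {
        b <- AGE_BRACKETS[AGE_BRACKETS$label == br, ]
        sub <- sub[sub$age_years >= b$min & sub$age_years <= b$max, ,
                   drop = FALSE]
      }
      n_cases <- sum(sub$is_case)
      if (n_cases == 0L) next
      fit <- tryCatch(multivariable_fit(sub, drop_inestimable = TRUE),
                      error = function(e) NULL)
      for (term in terms) {
        aor <- aor_low <- aor_high <- NA_real_
        if (is.null(fit)) {
          note <- "not estimable (model failed)"
        } else {
          i <- match(term, fit$or_table$term)
          if (is.na(i)) {
            note <- unname(fit$dropped[term])
            if (is.na(note)) note <- "not estimable"
          } else {
            note <- NA_character_
            aor <- fit$or_table$or[i]
            aor_low <- fit$or_table$ci_low[i]
            aor_high <- fit$or_table$ci_high[i]
          }
        }
        rows[[length(rows) + 1L]] <- data.frame(
          sex = sx, age_bracket = br, n_cases = n_cases, term = term,
          aor = aor, aor_low = aor_low, aor_high = aor_high,
          note = note, stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

run_one_condition <- function(registry, cases, config) {
  sets <- build_matched_sets(registry, cases, config$ratio, config$seed)
  tab <- build_analysis_table(registry, sets)
  uni <- univariable_exposure_fit(tab, drop_inestimable = TRUE)
  multi <- multivariable_fit(tab, drop_inestimable = TRUE)
  subgroups <- subgroup_or_table(tab)
  overall_bt <- burden_table(multi, tab, registry,
                             completeness_by_month = config$completeness_by_month)
  burden <- do.call(rbind, c(
    list(if (nrow(overall_bt)) cbind(sex = "all", age_bracket = "12-50",
                                     overall_bt)),
    lapply(seq_len(nrow(AGE_BRACKETS)), function(i) {
      b <- AGE_BRACKETS[i, ]
      do.call(rbind, lapply(c("M", "F"), function(sx) {
        sub <- tab[tab$sex == sx & tab$age_years >= b$min &
                     tab$age_years <= b$max, , drop = FALSE]
        if (!sum(sub$is_case)) return(NULL)
        fit <- tryCatch(multivariable_fit(sub, drop_inestimable = TRUE),
                        error = function(e) NULL)
        if (is.null(fit)) return(NULL)
        bt <- burden_table(fit, sub, registry, sex = sx, age_min = b$min,
                           age_max = b$max,
                           completeness_by_month = config$completeness_by_month)
        if (!nrow(bt)) return(NULL)
        cbind(sex = sx, age_bracket = b$label, bt)
      }))
    })))
  list(condition = cases$condition[1] %||% NA_character_,
       cases = cases, sets = sets, analysis_table = tab,
       characteristics = characteristics_table(tab, registry),
       association = association_table(tab, uni, multi),
       fit_univariable = uni, fit_multivariable = multi,
       subgroups = subgroups, burden = burden)
}

#' Run the full matched case-control study
#'
#' For each configured condition: ascertain cases, draw 10:1 matched sets,
#' build the analysis table, fit univariable and multivariable conditional
#' logistic models, produce the characteristics, association, subgroup and
#' burden tables. Deterministic given the registry and `config$seed`.
#'
#' @param registry A `registry` (or a directory path readable by
#'   [read_registry()]).
#' @param config A [study_config()].
#' @return Named list per condition of report bundles.
#' @export
run_study <- function(registry, config = study_config()) {
  if (is.character(registry)) registry <- read_registry(registry)
  out <- lapply(config$conditions, function(cond) {
    cases <- detect_cases(registry, cond)
    run_one_condition(registry, cases, config)
  })
  names(out) <- config$conditions
  out
}

exclude_recent_hospitalization <- function(registry, cases, days) {
  s <- registry$hospital_stays
  s <- s[s$recorded, c("person_id", "admission_date")]
  m <- merge(cases[, c("person_id", "index_date")], s, by = "person_id")
  bad <- m$admission_date < m$index_date &
    m$admission_date >= m$index_date - days
  drop_ids <- unique(m$person_id[bad])
  cases[!(cases$person_id %in% drop_ids), , drop = FALSE]
}

#' Sensitivity analyses
#'
#' Re-runs the association analysis under each sensitivity condition:
#' restriction to index dates before `config$restrict_before`, and exclusion
#' of cases with (i) 5-year carditis history, (ii) 30-day SARS-CoV-2
#' infection, (iii) dual myocarditis/pericarditis diagnosis, (iv) any
#' hospitalization within `config$recent_hospitalization_days` before the
#' index date. Controls are re-drawn for the filtered cases under the same
#' seed policy.
#'
#' @param registry A `registry`.
#' @param condition Condition to analyse.
#' @param config A [study_config()].
#' @param which Subset of analyses to run.
#' @return Named list of association tables (plus the filtered case counts).
#' @export
run_sensitivity <- function(registry, condition, config = study_config(),
                            which = c("restrict_before", "exclude_history",
                                      "exclude_infection",
                                      "exclude_dual_diagnosis",
                                      "exclude_recent_hospitalization")) {
  which <- match.arg(which, several.ok = TRUE)
  cases <- detect_cases(registry, condition)
  flags <- history_lookup(registry, cases$person_id, cases$index_date)
  filters <- list(
    restrict_before = function(cs)
      cs[cs$index_date < config$restrict_before, , drop = FALSE],
    exclude_history = function(cs)
      cs[!flags$history_carditis_5y[match(cs$person_id, cases$person_id)], ,
         drop = FALSE],
    exclude_infection = function(cs)
      cs[!flags$infection_30d[match(cs$person_id, cases$person_id)], ,
         drop = FALSE],
    exclude_dual_diagnosis = function(cs)
      cs[!cs$has_other_condition_code, , drop = FALSE],
    exclude_recent_hospitalization = function(cs)
      exclude_recent_hospitalization(registry, cs,
                                     config$recent_hospitalization_days)
  )
  out <- lapply(which, function(nm) {
    cs <- filters[[nm]](cases)
    if (nrow(cs) == 0L) return(list(n_cases = 0L, association = NULL))
    sets <- build_matched_sets(registry, cs, config$ratio, config$seed)
    tab <- build_analysis_table(registry, sets)
    list(n_cases = nrow(cs),
         association = association_table(
           tab, univariable_exposure_fit(tab, drop_inestimable = TRUE),
           multivariable_fit(tab, drop_inestimable = TRUE)))
  })
  names(out) <- which
  out
}
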