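# Synthetic claims-style registry: configuration, generator, container, CSV IO.
#
# The generator emulates the linked person-level tables of a national claims
# system (demographics, Covid-19 vaccinations, hospital stays with ICD-10
# codes, SARS-CoV-2 tests) with a known data-generating mechanism, so every
# downstream stage of the matched case-control pipeline can be tested against
# ground truth.

CONDITIONS <- c("myocarditis", "pericarditis")
BRANDS <- c("BNT162b2", "mRNA-1273")

# ICD-10 families (dot-free). I51.4 is a single code, not a family, so it is
# listed as an exact prefix of itself.
CONDITION_CODES <- list(
  myocarditis  = c("I40", "I41", "I514"),
  pericarditis = c("I30", "I32")
)

#' Exposure category levels
#'
#' The nine-level vaccine exposure classification used throughout the
#' analysis: `unexposed` (reference; never vaccinated or most recent dose more
#' than 21 days before the index date) plus brand x dose-rank x risk-window
#' for the two mRNA brands, two dose ranks and the 1-7 and 8-21 day windows.
#'
#' @return Character vector of length 9; the first element is the reference.
#' @export
exposure_levels <- function() {
  c("unexposed",
    as.vector(t(outer(BRANDS, c("dose 1, 1-7d", "dose 1, 8-21d",
                                "dose 2, 1-7d", "dose 2, 8-21d"),
                      paste))))
}

# Default window-specific odds ratios used as the generator's true effects:
# the multivariable point estimates of the study the pipeline reproduces.
default_true_or <- function() {
  lev <- setdiff(exposure_levels(), "unexposed")
  list(
    myocarditis  = setNames(c(1.8, 1.2, 8.1, 1.3, 3.0, 1.1, 30, 0.59), lev),
    pericarditis = setNames(c(1.3, 0.93, 2.9, 1.3, 1.2, 0.73, 5.5, 1.5), lev)
  )
}

default_covariate_effects <- function() {
  list(
    myocarditis  = c(history = 160, infection = 9,   least_deprived = 0.88),
    pericarditis = c(history = 250, infection = 4,   least_deprived = 0.87)
  )
}

#' Simulation configuration for a synthetic registry
#'
#' Bundles and validates every knob of the synthetic data-generating process.
#' Defaults encode the study conditions the pipeline is built for: the
#' May 12 - October 31 2021 window, ages 12-50, window-specific odds ratios
#' equal to the published multivariable estimates, 78% reporting completeness
#' for October admissions, and uptake parameters back-solved from the printed
#' national dose totals.
#'
#' @param n_persons Number of persons in the registry.
#' @param study_start,study_end Study window (`Date` or ISO-8601 string).
#' @param age_range Integer vector `c(min, max)` of completed years.
#' @param sex_ratio Proportion male.
#' @param n_departments Number of residence areas used as matching strata.
#' @param baseline_daily_rate Baseline hazard, events per person-day, applying
#'   to each condition separately in an unexposed, covariate-free person.
#' @param true_or Named list per condition of multiplicative effects for the
#'   eight exposed categories (names must match `exposure_levels()[-1]`).
#'   A single named vector is recycled to both conditions.
#' @param covariate_effects Named list per condition of multiplicative effects
#'   `c(history=, infection=, least_deprived=)`. The history effect applies to
#'   persons with a carditis admission predating the window; the infection
#'   effect for 30 days after a positive test; the least-deprived effect to
#'   deprivation quintiles 1-2.
#' @param p_vaccinated Probability a person receives a first dose in-window.
#' @param brand_shares Named probabilities for the two brands.
#' @param dose_gap_mean,dose_gap_sd Dose 1 to dose 2 gap: discretised normal,
#'   floored at 14 days. Second doses falling after `study_end` are dropped.
#' @param history_prevalence Probability of a carditis hospitalization 1-5
#'   years before the window.
#' @param infection_rate Probability of a positive SARS-CoV-2 test at a
#'   uniform date in-window.
#' @param dual_diagnosis_prob Named vector: probability that a stay for one
#'   condition also carries a code of the other.
#' @param completeness_october Fraction of final-month admissions present in
#'   the discharge database (the remainder are flagged unrecorded).
#' @param other_stay_rate Probability of one unrelated in-window stay.
#' @param seed Master seed; per-table substreams are derived from it.
#' @return A validated list of class `sim_config`.
#' @export
simulation_config <- function(n_persons = 100000L,
                              study_start = as.Date("2021-05-12"),
                              study_end = as.Date("2021-10-31"),
                              age_range = c(12L, 50L),
                              sex_ratio = 0.5,
                              n_departments = 96L,
                              baseline_daily_rate = 2.5e-7,
                              true_or = NULL,
                              covariate_effects = NULL,
                              p_vaccinated = 0.75,
                              brand_shares = c("BNT162b2" = 0.881,
                                               "mRNA-1273" = 0.119),
                              dose_gap_mean = 28,
                              dose_gap_sd = 5,
                              history_prevalence = 6e-4,
                              infection_rate = 0.04,
                              dual_diagnosis_prob = c(myocarditis = 0.054,
                                                      pericarditis = 0.023),
                              completeness_october = 0.78,
                              other_stay_rate = 0.002,
                              seed = 1L) {
  lev <- setdiff(exposure_levels(), "unexposed")
  if (is.null(true_or)) true_or <- default_true_or()
  if (!is.list(true_or)) true_or <- list(myocarditis = true_or,
                                         pericarditis = true_or)
  if (is.null(covariate_effects)) covariate_effects <- default_covariate_effects()
  if (!is.list(covariate_effects)) {
    covariate_effects <- list(myocarditis = covariate_effects,
                              pericarditis = covariate_effects)
  }
  cfg <- list(
    n_persons = as.integer(n_persons),
    study_start = as.Date(study_start), study_end = as.Date(study_end),
    age_range = as.integer(age_range), sex_ratio = sex_ratio,
    n_departments = as.integer(n_departments),
    baseline_daily_rate = baseline_daily_rate,
    true_or = true_or, covariate_effects = covariate_effects,
    p_vaccinated = p_vaccinated, brand_shares = brand_shares,
    dose_gap_mean = dose_gap_mean, dose_gap_sd = dose_gap_sd,
    history_prevalence = history_prevalence, infection_rate = infection_rate,
    dual_diagnosis_prob = dual_diagnosis_prob,
    completeness_october = completeness_october,
    other_stay_rate = other_stay_rate,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  chk <- function(ok, field, why) {
    if (!isTRUE(ok)) stopf("invalid configuration: '%s' %s", field, why)
  }
  chk(cfg$n_persons >= 1L, "n_persons", "must be >= 1")
  chk(cfg$study_end > cfg$study_start, "study_end", "must follow study_start")
  chk(length(cfg$age_range) == 2L && cfg$age_range[1] <= cfg$age_range[2],
      "age_range", "must be c(min, max) with min <= max")
  chk(cfg$sex_ratio >= 0 && cfg$sex_ratio <= 1, "sex_ratio",
      "must be in [0, 1]")
  chk(cfg$n_departments >= 1L, "n_departments", "must be >= 1")
  chk(cfg$baseline_daily_rate >= 0, "baseline_daily_rate", "must be >= 0")
  lev <- setdiff(exposure_levels(), "unexposed")
  for (cond in CONDITIONS) {
    or <- cfg$true_or[[cond]]
    chk(!is.null(or) && all(lev %in% names(or)), "true_or",
        sprintf("must name every exposed category for %s", cond))
    chk(all(or > 0), "true_or", "entries must be > 0")
    ce <- cfg$covariate_effects[[cond]]
    chk(all(c("history", "infection", "least_deprived") %in% names(ce)),
        "covariate_effects",
        sprintf("must name history, infection, least_deprived for %s", cond))
    chk(all(ce > 0), "covariate_effects", "entries must be > 0")
  }
  chk(cfg$p_vaccinated >= 0 && cfg$p_vaccinated <= 1, "p_vaccinated",
      "must be in [0, 1]")
  chk(all(BRANDS %in% names(cfg$brand_shares)) &&
        abs(sum(cfg$brand_shares) - 1) < 1e-8, "brand_shares",
      "must name both brands and sum to 1")
  chk(cfg$dose_gap_mean >= 14, "dose_gap_mean", "must be >= 14 days")
  chk(cfg$history_prevalence >= 0 && cfg$history_prevalence <= 1,
      "history_prevalence", "must be in [0, 1]")
  chk(cfg$infection_rate >= 0 && cfg$infection_rate <= 1, "infection_rate",
      "must be in [0, 1]")
  chk(all(cfg$dual_diagnosis_prob >= 0 & cfg$dual_diagnosis_prob <= 1),
      "dual_diagnosis_prob", "must be in [0, 1]")
  chk(cfg$completeness_october > 0 && cfg$completeness_october <= 1,
      "completeness_october", "must be in (0, 1]")
  chk(cfg$other_stay_rate >= 0 && cfg$other_stay_rate <= 1,
      "other_stay_rate", "must be in [0, 1]")
  invisible(cfg)
}

#' Construct a registry container
#'
#' A registry is the in-memory image of the four linked person-level tables
#' plus the study window. Invariants (unique ids, contiguous dose ranks,
#' dose-2 after dose-1) are checked on construction.
#'
#' @param persons Data frame: `person_id`, `sex` ("M"/"F"), `age_years`,
#'   `department`, `deprivation_quintile` (1-5).
#' @param vaccinations Data frame: `person_id`, `brand`, `dose_rank`, `date`.
#' @param hospital_stays Data frame: `person_id`, `admission_date`,
#'   `discharge_date`, `icd10_codes` (";"-separated dot-free codes),
#'   `recorded` (logical).
#' @param tests Data frame: `person_id`, `date`, `result`.
#' @param study_start,study_end Study window dates.
#' @return Object of class `registry`.
#' @export
new_registry <- function(persons, vaccinations, hospital_stays, tests,
                         study_start, study_end) {
  r <- list(persons = persons, vaccinations = vaccinations,
            hospital_stays = hospital_stays, tests = tests,
            study_start = as.Date(study_start), study_end = as.Date(study_end))
  class(r) <- "registry"
  validate_registry(r)
  r
}

validate_registry <- function(r) {
  p <- r$persons
  if (anyDuplicated(p$person_id)) {
    stopf("registry invariant violated: duplicate person_id (row %d)",
          anyDuplicated(p$person_id))
  }
  v <- r$vaccinations
  if (nrow(v)) {
    key <- paste(v$person_id, v$dose_rank)
    if (anyDuplicated(key)) {
      stopf("registry invariant violated: duplicate dose rank for a person (row %d)",
            anyDuplicated(key))
    }
    d2 <- v[v$dose_rank == 2L, c("person_id", "date")]
    if (nrow(d2)) {
      d1 <- v[v$dose_rank == 1L, c("person_id", "date")]
      m <- merge(d2, d1, by = "person_id", all.x = TRUE,
                 suffixes = c("_2", "_1"))
      if (anyNA(m$date_1)) {
        stopf("registry invariant violated: dose 2 without dose 1 (person %s)",
              m$person_id[which(is.na(m$date_1))[1]])
      }
      if (any(m$date_2 <= m$date_1)) {
        stopf("registry invariant violated: dose 2 not after dose 1 (person %s)",
              m$person_id[which(m$date_2 <= m$date_1)[1]])
      }
    }
  }
  s <- r$hospital_stays
  if (nrow(s) && any(s$discharge_date < s$admission_date)) {
    stopf("registry invariant violated: discharge before admission (row %d)",
          which(s$discharge_date < s$admission_date)[1])
  }
  invisible(r)
}

#' @export
print.registry <- function(x, ...) {
  cat(sprintf(
    "<registry> %d persons, %d vaccinations, %d stays, %d tests; window %s..%s\n",
    nrow(x$persons), nrow(x$vaccinations), nrow(x$hospital_stays),
    nrow(x$tests), format(x$study_start), format(x$study_end)))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Event simulation
#
# Discrete daily Bernoulli hazard per person per condition:
#   h(t) = baseline * OR[exposure category at t] * infection(t) * history * depriv.
# The day grid is 0..T-1 (offsets from study_start). Exposure at day t follows
# the most-recent-dose rule with d = t - dose_day >= 1. Because the hazard is
# piecewise constant between dose/test change-points, the first event day is
# drawn exactly by truncated-geometric sampling per constant segment (segments
# are disjoint days with independent Bernoulli draws, so the overall first
# event is the minimum over per-segment first events).

simulate_first_event_day <- function(n_days, base_rate, or_map, eff,
                                     d1, d2, brand, test_day, person_mult) {
  n <- length(d1)
  if (base_rate <= 0 || n == 0L) return(rep(NA_integer_, n))
  bp <- cbind(0L,
              d1 + 1L, d1 + 8L, d1 + 22L,
              d2 + 1L, d2 + 8L, d2 + 22L,
              test_day + 1L, test_day + 31L,
              n_days)
  pid <- rep(seq_len(n), times = ncol(bp))
  v <- as.integer(bp)
  keep <- !is.na(v)
  pid <- pid[keep]
  v <- pmin(pmax(v[keep], 0L), n_days)
  o <- order(pid, v)
  pid <- pid[o]; v <- v[o]
  m <- length(v)
  dup <- c(FALSE, pid[-1L] == pid[-m] & v[-1L] == v[-m])
  pid <- pid[!dup]; v <- v[!dup]
  m <- length(v)
  is_last <- c(pid[-1L] != pid[-m], TRUE)
  seg_p <- pid[!is_last]
  seg_s <- v[!is_last]
  seg_len <- v[which(!is_last) + 1L] - seg_s

  t0 <- seg_s                      # category is constant within a segment
  D1 <- d1[seg_p]; D2 <- d2[seg_p]; B <- brand[seg_p]; TD <- test_day[seg_p]
  use2 <- !is.na(D2) & D2 < t0
  use1 <- !use2 & !is.na(D1) & D1 < t0
  dd <- rep(NA_integer_, length(t0))
  dd[use2] <- t0[use2] - D2[use2]
  dd[use1] <- t0[use1] - D1[use1]
  rank <- ifelse(use2, 2L, 1L)
  win <- rep(NA_character_, length(t0))
  win[!is.na(dd) & dd >= 1L & dd <= 7L] <- "1-7d"
  win[!is.na(dd) & dd >= 8L & dd <= 21L] <- "8-21d"
  cat_mult <- rep(1, length(t0))
  exposed <- !is.na(win)
  if (any(exposed)) {
    nm <- paste0(B[exposed], " dose ", rank[exposed], ", ", win[exposed])
    cat_mult[exposed] <- or_map[nm]
  }
  inf_mult <- rep(1, length(t0))
  inf_on <- !is.na(TD) & t0 >= TD + 1L & t0 <= TD + 30L
  inf_mult[inf_on] <- eff[["infection"]]
  h <- pmin(base_rate * cat_mult * inf_mult * person_mult[seg_p], 0.5)

  u <- runif(length(h))
  g <- 1 + floor(log(u) / log1p(-h))   # geometric first-success day within segment
  hit <- is.finite(g) & g <= seg_len
  ev_day <- seg_s[hit] + as.integer(g[hit]) - 1L
  ev_p <- seg_p[hit]
  out <- rep(NA_integer_, n)
  if (length(ev_p)) {
    o2 <- order(ev_p, ev_day)
    first <- !duplicated(ev_p[o2])
    out[ev_p[o2][first]] <- ev_day[o2][first]
  }
  out
}

#' Generate a synthetic registry
#'
#' Draws the four linked tables under the configured data-generating process.
#' Deterministic given `config$seed`: each table is drawn from its own
#' deterministic substream of the master seed. Carditis events arise from a
#' per-person per-condition daily Bernoulli hazard equal to the baseline rate
#' times the configured odds ratio of the person's exposure category on that
#' day times the covariate multipliers; each event becomes a hospital stay
#' with a diagnosis code of the condition (first event only, per condition).
#' Admissions in the final study month are flagged unrecorded with probability
#' `1 - completeness_october`.
#'
#' @param config A `sim_config` from [simulation_config()].
#' @return A [new_registry()] object.
#' @export
generate_registry <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(simulation_config, config)
  validate_config(config)
  n <- config$n_persons
  n_days <- as.integer(config$study_end - config$study_start) + 1L
  seed <- config$seed

  persons <- with_seed(substream_seed(seed, "persons"), {
    data.frame(
      person_id = seq_len(n),
      sex = ifelse(runif(n) < config$sex_ratio, "M", "F"),
      age_years = sample(config$age_range[1]:config$age_range[2], n,
                         replace = TRUE),
      department = sample.int(config$n_departments, n, replace = TRUE),
      deprivation_quintile = sample.int(5L, n, replace = TRUE),
      stringsAsFactors = FALSE
    )
  })

  vac <- with_seed(substream_seed(seed, "vaccinations"), {
    has_d1 <- runif(n) < config$p_vaccinated
    brand <- sample(names(config$brand_shares), n, replace = TRUE,
                    prob = config$brand_shares)
    d1 <- sample.int(n_days, n, replace = TRUE) - 1L
    gap <- pmax(14L, as.integer(round(rnorm(n, config$dose_gap_mean,
                                            config$dose_gap_sd))))
    d2 <- d1 + gap
    d1[!has_d1] <- NA_integer_
    d2[!has_d1] <- NA_integer_
    d2[!is.na(d2) & d2 >= n_days] <- NA_integer_   # not received in-window
    list(brand = brand, d1 = d1, d2 = d2)
  })
  i1 <- which(!is.na(vac$d1)); i2 <- which(!is.na(vac$d2))
  vaccinations <- data.frame(
    person_id = c(i1, i2),
    brand = c(vac$brand[i1], vac$brand[i2]),
    dose_rank = c(rep(1L, length(i1)), rep(2L, length(i2))),
    date = config$study_start + c(vac$d1[i1], vac$d2[i2]),
    stringsAsFactors = FALSE
  )
  vaccinations <- vaccinations[order(vaccinations$person_id,
                                     vaccinations$dose_rank), ]
  rownames(vaccinations) <- NULL

  hist <- with_seed(substream_seed(seed, "history"), {
    flag <- runif(n) < config$history_prevalence
    cond <- sample(CONDITIONS, n, replace = TRUE)
    days_before <- sample(365:1824, n, replace = TRUE)
    list(flag = flag, cond = cond, days_before = days_before)
  })

  test_day <- with_seed(substream_seed(seed, "tests"), {
    flag <- runif(n) < config$infection_rate
    td <- sample.int(n_days, n, replace = TRUE) - 1L
    td[!flag] <- NA_integer_
    td
  })
  ti <- which(!is.na(test_day))
  tests <- data.frame(person_id = ti,
                      date = config$study_start + test_day[ti],
                      result = rep("positive", length(ti)),
                      stringsAsFactors = FALSE)

  least_depr <- persons$deprivation_quintile <= 2L
  final_month <- month_key(config$study_end)

  stay_list <- list()
  ih <- which(hist$flag)
  if (length(ih)) {
    code <- ifelse(hist$cond[ih] == "myocarditis", "I401", "I309")
    adm <- config$study_start - hist$days_before[ih]
    stay_list$history <- data.frame(
      person_id = ih, admission_date = adm, discharge_date = adm + 3L,
      icd10_codes = code, recorded = TRUE, stringsAsFactors = FALSE)
  }

  oth <- with_seed(substream_seed(seed, "stays_other"), {
    flag <- runif(n) < config$other_stay_rate
    day <- sample.int(n_days, n, replace = TRUE) - 1L
    rec_u <- runif(n)
    list(flag = flag, day = day, rec_u = rec_u)
  })
  io <- which(oth$flag)
  if (length(io)) {
    adm <- config$study_start + oth$day[io]
    unrec <- month_key(adm) == final_month &
      oth$rec_u[io] > config$completeness_october
    stay_list$other <- data.frame(
      person_id = io, admission_date = adm, discharge_date = adm + 1L,
      icd10_codes = "Z038", recorded = !unrec, stringsAsFactors = FALSE)
  }

  primary_code <- c(myocarditis = "I401", pericarditis = "I309")
  code_pool <- list(myocarditis  = c("I400", "I401", "I409", "I514"),
                    pericarditis = c("I300", "I301", "I309", "I320"))
  code_prob <- list(myocarditis  = c(0.15, 0.55, 0.20, 0.10),
                    pericarditis = c(0.10, 0.20, 0.60, 0.10))
  for (cond in CONDITIONS) {
    stay_list[[cond]] <- with_seed(substream_seed(seed, paste0("events_", cond)), {
      eff <- config$covariate_effects[[cond]]
      person_mult <- ifelse(hist$flag, eff[["history"]], 1) *
        ifelse(least_depr, eff[["least_deprived"]], 1)
      ev <- simulate_first_event_day(
        n_days, config$baseline_daily_rate, config$true_or[[cond]], eff,
        vac$d1, vac$d2, vac$brand, test_day, person_mult)
      ie <- which(!is.na(ev))
      if (!length(ie)) return(NULL)
      adm <- config$study_start + ev[ie]
      los <- 1L + rpois(length(ie), 3)
      codes <- sample(code_pool[[cond]], length(ie), replace = TRUE,
                      prob = code_prob[[cond]])
      dual <- runif(length(ie)) < config$dual_diagnosis_prob[[cond]]
      other <- setdiff(CONDITIONS, cond)
      codes[dual] <- paste(codes[dual], primary_code[[other]], sep = ";")
      unrec <- month_key(adm) == final_month &
        runif(length(ie)) > config$completeness_october
      data.frame(person_id = ie, admission_date = adm,
                 discharge_date = adm + los, icd10_codes = codes,
                 recorded = !unrec, stringsAsFactors = FALSE)
    })
  }
  hospital_stays <- do.call(rbind, stay_list)
  if (is.null(hospital_stays)) {
    hospital_stays <- data.frame(
      person_id = integer(), admission_date = as.Date(character()),
      discharge_date = as.Date(character()), icd10_codes = character(),
      recorded = logical(), stringsAsFactors = FALSE)
  }
  hospital_stays <- hospital_stays[order(hospital_stays$person_id,
                                         hospital_stays$admission_date), ]
  rownames(hospital_stays) <- NULL

  new_registry(persons, vaccinations, hospital_stays, tests,
               config$study_start, config$study_end)
}

# ---------------------------------------------------------------------------
# CSV round-trip

REGISTRY_FILES <- c(persons = "persons.csv", vaccinations = "vaccinations.csv",
                    hospital_stays = "hospital_stays.csv", tests = "tests.csv",
                    meta = "meta.csv")

REGISTRY_COLUMNS <- list(
  persons = c(person_id = "integer", sex = "character", age_years = "integer",
              department = "integer", deprivation_quintile = "integer"),
  vaccinations = c(person_id = "integer", brand = "character",
                   dose_rank = "integer", date = "Date"),
  hospital_stays = c(person_id = "integer", admission_date = "Date",
                     discharge_date = "Date", icd10_codes = "character",
                     recorded = "logical"),
  tests = c(person_id = "integer", date = "Date", result = "character")
)

#' Write a registry to a directory of CSV files
#'
#' Emits `persons.csv`, `vaccinations.csv`, `hospital_stays.csv`, `tests.csv`
#' and a one-row `meta.csv` holding the study window. Dates are ISO-8601.
#'
#' @param registry A `registry` object.
#' @param directory Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_registry <- function(registry, directory) {
  stopifnot(inherits(registry, "registry"))
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(directory, REGISTRY_FILES)
  names(paths) <- names(REGISTRY_FILES)
  for (tbl in names(REGISTRY_COLUMNS)) {
    df <- registry[[tbl]]
    for (col in names(REGISTRY_COLUMNS[[tbl]])) {
      if (REGISTRY_COLUMNS[[tbl]][[col]] == "Date") {
        df[[col]] <- format(df[[col]], "%Y-%m-%d")
      }
    }
    write.csv(df, paths[[tbl]], row.names = FALSE)
  }
  write.csv(data.frame(study_start = format(registry$study_start),
                       study_end = format(registry$study_end)),
            paths[["meta"]], row.names = FALSE)
  invisible(paths)
}

read_registry_table <- function(path, spec) {
  if (!file.exists(path)) stopf("parse error: missing file '%s'", path)
  cls <- setNames(ifelse(spec == "Date", "character", spec), names(spec))
  df <- suppressWarnings(read.csv(path, stringsAsFactors = FALSE,
                                  colClasses = cls))
  missing_cols <- setdiff(names(spec), names(df))
  if (length(missing_cols)) {
    stopf("parse error in '%s': missing column '%s'", basename(path),
          missing_cols[1])
  }
  df <- df[names(spec)]
  for (col in names(spec)) {
    if (spec[[col]] == "Date") {
      parsed <- as.Date(df[[col]], format = "%Y-%m-%d")
      bad <- which(is.na(parsed) & !is.na(df[[col]]) & nzchar(df[[col]]))
      if (length(bad)) {
        stopf("parse error in '%s': malformed date '%s' at row %d",
              basename(path), df[[col]][bad[1]], bad[1])
      }
      df[[col]] <- parsed
    }
  }
  df
}

#' Read a registry from a directory of CSV files
#'
#' Inverse of [write_registry()]; `read_registry(write_registry(r))`
#' reproduces `r`. Schema violations (missing column, malformed date,
#' duplicate dose rank) raise a parse error naming the offending row.
#'
#' @param directory Directory containing the registry CSV files.
#' @return A `registry` object.
#' @export
read_registry <- function(directory) {
  tabs <- lapply(names(REGISTRY_COLUMNS), function(tbl) {
    read_registry_table(file.path(directory, REGISTRY_FILES[[tbl]]),
                        REGISTRY_COLUMNS[[tbl]])
  })
  names(tabs) <- names(REGISTRY_COLUMNS)
  v <- tabs$vaccinations
  if (nrow(v)) {
    key <- paste(v$person_id, v$dose_rank)
    dup <- anyDuplicated(key)
    if (dup) {
      stopf("parse error in 'vaccinations.csv': duplicate dose rank %d for person %s at row %d",
            v$dose_rank[dup], v$person_id[dup], dup)
    }
  }
  meta <- read.csv(file.path(directory, REGISTRY_FILES[["meta"]]),
                   stringsAsFactors = FALSE)
  new_registry(tabs$persons, tabs$vaccinations, tabs$hospital_stays,
               tabs$tests, as.Date(meta$study_start), as.Date(meta$study_end))
}

#' An empty registry
#'
#' Header-only tables with the default study window; useful as a fixture and
#' for schema documentation.
#' @param study_start,study_end Study window dates.
#' @return A `registry` with zero rows in every table.
#' @export
empty_registry <- function(study_start = as.Date("2021-05-12"),
                           study_end = as.Date("2021-10-31")) {
  mk <- function(spec) {
    cols <- lapply(spec, function(cls) {
      switch(cls, integer = integer(), character = character(),
             logical = logical(), Date = as.Date(character()))
    })
    as.data.frame(cols, stringsAsFactors = FALSE)
  }
  new_registry(mk(REGISTRY_COLUMNS$persons), mk(REGISTRY_COLUMNS$vaccinations),
               mk(REGISTRY_COLUMNS$hospital_stays), mk(REGISTRY_COLUMNS$tests),
               study_start, study_end)
}
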