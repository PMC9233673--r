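# Case ascertainment from hospital-stay records.
#
# Cases are persons with a recorded hospital stay in the study window carrying
# an ICD-10 code of the condition: myocarditis I40.x / I41.x / I51.4,
# pericarditis I30.x / I32.x (codes stored dot-free, matched by prefix so the
# whole .x family is captured). The first qualifying admission defines the
# single index date per person per condition.

split_codes <- function(icd10_codes) strsplit(icd10_codes, ";", fixed = TRUE)

codes_match <- function(code_list, prefixes) {
  vapply(code_list, function(codes) {
    any(outer(codes, prefixes, startsWith))
  }, logical(1), USE.NAMES = FALSE)
}

check_condition <- function(condition) {
  if (!condition %in% CONDITIONS) {
    stopf("unknown condition '%s'; supported conditions: %s", condition,
          paste(CONDITIONS, collapse = ", "))
  }
  condition
}

#' Detect cases of a condition from hospital stays
#'
#' Scans recorded hospital stays admitted within `window` for diagnosis codes
#' of `condition` and returns one case per person at the first qualifying
#' admission. Stays flagged unrecorded (e.g. final-month reporting lag) are
#' invisible to detection. The result is independent of the row order of the
#' stay table.
#'
#' @param registry A `registry`.
#' @param condition `"myocarditis"` or `"pericarditis"`.
#' @param window Length-2 date vector; defaults to the registry study window.
#' @return Data frame of case records: `person_id`, `condition`, `index_date`,
#'   `has_other_condition_code` (a code of the other condition on the same
#'   stay), `age_at_index`, `sex`, `department`, sorted by index date then
#'   person id.
#' @export
detect_cases <- function(registry, condition,
                         window = c(registry$study_start, registry$study_end)) {
  check_condition(condition)
  stopifnot(inherits(registry, "registry"), length(window) == 2L)
  window <- as.Date(window)
  s <- registry$hospital_stays
  s <- s[s$recorded & s$admission_date >= window[1] &
           s$admission_date <= window[2], , drop = FALSE]
  if (nrow(s) == 0L) return(empty_cases(condition))
  codes <- split_codes(s$icd10_codes)
  hit <- codes_match(codes, CONDITION_CODES[[condition]])
  s <- s[hit, , drop = FALSE]
  codes <- codes[hit]
  if (nrow(s) == 0L) return(empty_cases(condition))
  other <- setdiff(CONDITIONS, condition)
  s$has_other_condition_code <- codes_match(codes, CONDITION_CODES[[other]])
  o <- order(s$person_id, s$admission_date)
  s <- s[o, , drop = FALSE]
  s <- s[!duplicated(s$person_id), , drop = FALSE]
  out <- data.frame(person_id = s$person_id, condition = condition,
                    index_date = s$admission_date,
                    has_other_condition_code = s$has_other_condition_code,
                    stringsAsFactors = FALSE)
  p <- registry$persons
  idx <- match(out$person_id, p$person_id)
  out$age_at_index <- p$age_years[idx]
  out$sex <- p$sex[idx]
  out$department <- p$department[idx]
  out <- out[order(out$index_date, out$person_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_cases <- function(condition) {
  data.frame(person_id = integer(), condition = character(),
             index_date = as.Date(character()),
             has_other_condition_code = logical(), age_at_index = integer(),
             sex = character(), department = integer(),
             stringsAsFactors = FALSE)
}

# Days spanned by "five years" of history; calendar arithmetic is avoided so
# the window length does not depend on leap-day position.
HISTORY_DAYS <- 1826L
INFECTION_DAYS <- 30L

#' Covariate history flags at an index date
#'
#' For each (person, index date) pair returns the prior-carditis flag — any
#' recorded stay coded for myocarditis or pericarditis admitted in
#' `[index - 5 years, index)` — and the prior-infection flag — a positive
#' SARS-CoV-2 test, or a recorded Covid-coded stay, in `[index - 30 days,
#' index)`. Both windows are half-open: an admission on the index date itself
#' is the case event, not history.
#'
#' @param registry A `registry`.
#' @param person_id Integer vector.
#' @param index_date Date vector, recycled against `person_id`.
#' @param covid_code_prefix ICD-10 prefix identifying Covid-19 stays.
#' @return Data frame with `person_id`, `index_date`, `history_carditis_5y`,
#'   `infection_30d`.
#' @export
history_lookup <- function(registry, person_id, index_date,
                           covid_code_prefix = "U071") {
  n <- max(length(person_id), length(index_date))
  person_id <- rep_len(person_id, n)
  index_date <- rep_len(as.Date(index_date), n)
  unknown <- !(person_id %in% registry$persons$person_id)
  if (any(unknown)) {
    warning(sprintf("history_lookup: %d person id(s) absent from registry; flags set FALSE",
                    sum(unknown)), call. = FALSE)
  }
  q <- data.frame(.row = seq_len(n), person_id = person_id,
                  index_date = index_date)

  s <- registry$hospital_stays
  s <- s[s$recorded, , drop = FALSE]
  flag_from_stays <- function(prefixes, lookback) {
    if (nrow(s) == 0L) return(logical(n))
    hit <- codes_match(split_codes(s$icd10_codes), prefixes)
    ss <- s[hit, c("person_id", "admission_date"), drop = FALSE]
    if (nrow(ss) == 0L) return(logical(n))
    m <- merge(q, ss, by = "person_id")
    ok <- m$admission_date < m$index_date &
      m$admission_date >= m$index_date - lookback
    out <- logical(n)
    out[unique(m$.row[ok])] <- TRUE
    out
  }
  carditis_prefixes <- unique(unlist(CONDITION_CODES))
  history <- flag_from_stays(carditis_prefixes, HISTORY_DAYS)

  infection <- flag_from_stays(covid_code_prefix, INFECTION_DAYS)
  tt <- registry$tests
  tt <- tt[tt$result == "positive", , drop = FALSE]
  if (nrow(tt)) {
    m <- merge(q, tt, by = "person_id")
    ok <- m$date < m$index_date & m$date >= m$index_date - INFECTION_DAYS
    infection[unique(m$.row[ok])] <- TRUE
  }
  data.frame(person_id = person_id, index_date = index_date,
             history_carditis_5y = history, infection_30d = infection)
}
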