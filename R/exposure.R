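# Exposure-window classification and adjustment covariates.
#
# Exposure at an index date is determined by the most recent dose received
# strictly before that date: d = index - dose date (whole days, d >= 1).
# d in [1, 7] or [8, 21] maps to the brand x dose-rank window category;
# d > 21, a same-day dose (d = 0), or no dose at all is "unexposed". The nine
# categories partition every person-index-date. Controls are classified at
# their case's index date.

#' Classify vaccine exposure at an index date
#'
#' @param vaccinations Vaccination rows of one person (`brand`, `dose_rank`,
#'   `date`).
#' @param index_date The index date.
#' @return One of [exposure_levels()].
#' @export
classify_exposure <- function(vaccinations, index_date) {
  index_date <- as.Date(index_date)
  if (nrow(vaccinations) == 0L) return("unexposed")
  d <- as.integer(index_date - as.Date(vaccinations$date))
  keep <- d >= 1L              # doses on/after the index date never count
  if (!any(keep)) return("unexposed")
  i <- which(keep)[which.min(d[keep])]   # most recent exposure
  window_category(vaccinations$brand[i], vaccinations$dose_rank[i], d[i])
}

window_category <- function(brand, dose_rank, d) {
  win <- ifelse(d >= 1L & d <= 7L, "1-7d",
                ifelse(d >= 8L & d <= 21L, "8-21d", NA_character_))
  out <- ifelse(is.na(win), "unexposed",
                paste0(brand, " dose ", dose_rank, ", ", win))
  out
}

# Vectorized classification for (person_id, index_date) pairs.
classify_exposure_table <- function(vaccinations, person_id, index_date) {
  n <- length(person_id)
  out <- rep("unexposed", n)
  if (nrow(vaccinations) == 0L || n == 0L) return(factor(out, exposure_levels()))
  q <- data.frame(.row = seq_len(n), person_id = person_id,
                  index_date = as.Date(index_date))
  m <- merge(q, vaccinations, by = "person_id")
  m$d <- as.integer(m$index_date - m$date)
  m <- m[m$d >= 1L, , drop = FALSE]
  if (nrow(m)) {
    m <- m[order(m$.row, m$d), , drop = FALSE]
    m <- m[!duplicated(m$.row), , drop = FALSE]  # most recent dose
    out[m$.row] <- window_category(m$brand, m$dose_rank, m$d)
  }
  factor(out, levels = exposure_levels())
}

#' Exposure and covariates for one person at an index date
#'
#' Combines [classify_exposure()] with [history_lookup()] flags and the
#' deprivation binarization (quintiles 1-2 = least deprived, 3-5 = most
#' deprived).
#'
#' @param registry A `registry`.
#' @param person_id One person id.
#' @param index_date The index date.
#' @return One-row data frame: `category`, `history_carditis_5y`,
#'   `infection_30d`, `deprived` (TRUE for quintiles 3-5).
#' @export
build_covariates <- function(registry, person_id, index_date) {
  stopifnot(length(person_id) == 1L)
  v <- registry$vaccinations
  cat <- classify_exposure(v[v$person_id == person_id, , drop = FALSE],
                           index_date)
  h <- history_lookup(registry, person_id, index_date)
  q <- registry$persons$deprivation_quintile[
    match(person_id, registry$persons$person_id)]
  if (is.na(q)) {
    stopf("missing deprivation quintile for person %s (no imputation)",
          person_id)
  }
  data.frame(category = factor(cat, levels = exposure_levels()),
             history_carditis_5y = h$history_carditis_5y,
             infection_30d = h$infection_30d,
             deprived = q >= 3L)
}

#' Analysis table for matched sets
#'
#' One row per set member with the model inputs: exposure category at the
#' set's index date, the two history flags and the deprivation indicator.
#' This is the direct input of the conditional-logistic module.
#'
#' @param registry A `registry`.
#' @param sets Output of [build_matched_sets()].
#' @return Data frame: `set_id`, `condition`, `person_id`, `is_case`,
#'   `index_date`, `category`, `history_carditis_5y`, `infection_30d`,
#'   `deprived`, `sex`, `age_years`.
#' @export
build_analysis_table <- function(registry, sets) {
  q <- registry$persons$deprivation_quintile[
    match(sets$person_id, registry$persons$person_id)]
  if (anyNA(q)) {
    stopf("missing deprivation quintile for person %s (no imputation)",
          sets$person_id[which(is.na(q))[1]])
  }
  h <- history_lookup(registry, sets$person_id, sets$index_date)
  data.frame(
    set_id = sets$set_id, condition = sets$condition,
    person_id = sets$person_id, is_case = sets$role == "case",
    index_date = sets$index_date,
    category = classify_exposure_table(registry$vaccinations,
                                       sets$person_id, sets$index_date),
    history_carditis_5y = h$history_carditis_5y,
    infection_30d = h$infection_30d,
    deprived = q >= 3L,
    sex = sets$sex, age_years = sets$age_years,
    stringsAsFactors = FALSE
  )
}
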