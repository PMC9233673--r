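# Risk-set matched control sampling.
#
# Each case is matched at its index date to `ratio` controls drawn by simple
# random sampling without replacement within the stratum of sex, completed
# age in years, and department of residence. Eligibility follows the
# incidence-density convention: a control must not be a detected case (of
# either condition) on or before the index date, but a person who becomes a
# case later may serve as a control before their own index date. "Without
# replacement" is read across the whole study per condition: a person serves
# as a control for at most one case of a given condition.

stratum_key <- function(sex, age_years, department) {
  paste(sex, age_years, department, sep = "|")
}

#' Build matched case-control sets
#'
#' Processes cases in index-date order (ties broken by person id) and samples
#' `ratio` eligible controls per case from the case's stratum. Deterministic
#' given `seed`; the caller's RNG state is left untouched. Cases of different
#' conditions are matched independently (separate without-replacement pools).
#'
#' @param registry A `registry`.
#' @param cases Case records from [detect_cases()] (one or both conditions).
#' @param ratio Controls per case (default 10).
#' @param seed Integer seed for the sampling stream.
#' @param on_short `"fail"` (default) to error when a stratum cannot supply
#'   `ratio` eligible controls, mirroring the fixed 1:10 design; `"keep"` to
#'   retain the set with fewer controls and warn.
#' @return Long data frame of set members: `set_id`, `condition`, `role`
#'   (`"case"`/`"control"`), `person_id`, `index_date`, `sex`, `age_years`,
#'   `department`.
#' @export
build_matched_sets <- function(registry, cases, ratio = 10L, seed = 1L,
                               on_short = c("fail", "keep")) {
  on_short <- match.arg(on_short)
  stopifnot(inherits(registry, "registry"), ratio >= 1L)
  ratio <- as.integer(ratio)
  p <- registry$persons
  key <- stratum_key(p$sex, p$age_years, p$department)
  stratum_members <- split(p$person_id, key)

  # First detected case index date per person, either condition: bars use as
  # a control from that date onward.
  first_dx <- rep(as.Date(NA), max(p$person_id, 0L))
  for (cond in CONDITIONS) {
    cc <- detect_cases(registry, cond)
    idx <- cc$person_id
    upd <- is.na(first_dx[idx]) | cc$index_date < first_dx[idx]
    first_dx[idx[upd]] <- cc$index_date[upd]
  }

  out <- vector("list", length(unique(cases$condition)))
  names(out) <- unique(cases$condition)
  for (cond in names(out)) {
    cs <- cases[cases$condition == cond, , drop = FALSE]
    cs <- cs[order(cs$index_date, cs$person_id), , drop = FALSE]
    used <- logical(length(first_dx))
    sets <- vector("list", nrow(cs))
    out[[cond]] <- with_seed(substream_seed(seed, paste0("match_", cond)), {
      for (i in seq_len(nrow(cs))) {
        k <- stratum_key(cs$sex[i], cs$age_at_index[i], cs$department[i])
        cand <- stratum_members[[k]]
        cand <- cand[cand != cs$person_id[i] & !used[cand]]
        dx <- first_dx[cand]
        cand <- cand[is.na(dx) | dx > cs$index_date[i]]
        if (length(cand) < ratio) {
          if (on_short == "fail") {
            stopf("stratum '%s' has only %d eligible controls for case %s (need %d); use on_short = \"keep\" to allow short sets",
                  k, length(cand), cs$person_id[i], ratio)
          }
          warning(sprintf("set %d (%s): only %d of %d controls available",
                          i, cond, length(cand), ratio), call. = FALSE)
          pick <- resample(cand, length(cand))
        } else {
          pick <- resample(cand, ratio)
        }
        used[pick] <- TRUE
        sets[[i]] <- data.frame(
          set_id = paste0(substr(cond, 1, 4), "_", i),
          condition = cond,
          role = c("case", rep("control", length(pick))),
          person_id = c(cs$person_id[i], pick),
          index_date = cs$index_date[i],
          sex = cs$sex[i], age_years = cs$age_at_index[i],
          department = cs$department[i],
          stringsAsFactors = FALSE)
      }
      do.call(rbind, sets)
    })
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Validate matched-set invariants
#'
#' Report-only checker: stratum homogeneity of all members, exactly one case
#' per set, no control reuse within a condition, and no control already a
#' detected case on or before the set's index date.
#'
#' @param sets Output of [build_matched_sets()].
#' @param registry The registry the sets were drawn from.
#' @return Data frame of violations (`set_id`, `problem`); zero rows on
#'   success.
#' @export
validate_sets <- function(sets, registry) {
  viol <- list()
  add <- function(set_id, problem) {
    viol[[length(viol) + 1L]] <<- data.frame(set_id = set_id,
                                             problem = problem,
                                             stringsAsFactors = FALSE)
  }
  p <- registry$persons
  idx <- match(sets$person_id, p$person_id)
  actual <- stratum_key(p$sex[idx], p$age_years[idx], p$department[idx])
  claimed <- stratum_key(sets$sex, sets$age_years, sets$department)
  bad <- sets$set_id[actual != claimed]
  for (s in unique(bad)) add(s, "member outside stratum (sex/age/department mismatch)")

  n_case <- tapply(sets$role == "case", sets$set_id, sum)
  for (s in names(n_case)[n_case != 1L]) add(s, "set does not have exactly one case")

  ctl <- sets[sets$role == "control", , drop = FALSE]
  for (cond in unique(ctl$condition)) {
    cc <- ctl[ctl$condition == cond, , drop = FALSE]
    dup_ids <- unique(cc$person_id[duplicated(cc$person_id)])
    for (id in dup_ids) {
      for (s in unique(cc$set_id[cc$person_id == id])) {
        add(s, sprintf("control %s reused within condition %s", id, cond))
      }
    }
  }

  for (cond in CONDITIONS) {
    cs <- detect_cases(registry, cond)
    if (!nrow(cs)) next
    m <- merge(ctl, cs[, c("person_id", "index_date")], by = "person_id",
               suffixes = c("", "_dx"))
    bad <- m$index_date_dx <= m$index_date
    for (i in which(bad)) {
      add(m$set_id[i], sprintf("control %s diagnosed with %s on or before index date",
                               m$person_id[i], cond))
    }
  }
  if (!length(viol)) {
    return(data.frame(set_id = character(), problem = character(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, viol)
  res <- res[!duplicated(res), , drop = FALSE]
  rownames(res) <- NULL
  res
}
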