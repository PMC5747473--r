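#' Classify a cognition test score
#'
#' Maps a 27-point cognition score to the three-level classification used
#' throughout: scores of 11 or less are cognitive impairment, split into
#' impairment without dementia (7-11) and dementia (0-6); 12 and above is
#' non-impaired. Missing scores stay missing.
#'
#' @param score integer vector of scores in `[0, 27]`, `NA` allowed.
#' @return factor with levels `N`, `CIND`, `DEM`.
#' @seealso [cognition_binary()] to collapse to the two living model states.
#' @export
classify_cognition <- function(score) {
  if (any(!is.na(score) & (score < 0 | score > 27))) {
    stop("cognition score outside [0, 27]", call. = FALSE)
  }
  lab <- c("DEM", "CIND", "N")[findInterval(score, c(0, 7, 12))]
  factor(lab, levels = c("N", "CIND", "DEM"))
}

#' Collapse a cognition classification to the two living states
#'
#' @param state factor from [classify_cognition()].
#' @return character vector with values `N` (non-impaired) or `I`
#'   (impaired), `NA` preserved.
#' @export
cognition_binary <- function(state) {
  out <- as.character(state)
  out[!is.na(out) & out != "N"] <- "I"
  out
}

#' Carry a diabetes diagnosis forward within person
#'
#' Once a person reports an ever-diagnosis of diabetes, the flag stays set
#' for all later waves until death or censoring (absorbing exposure).
#'
#' @param panel long-format panel with `person_id`, `wave`, `diabetes_ever`.
#' @return the panel with `diabetes_ever` monotone non-decreasing in wave
#'   within each person.
#' @export
carry_forward_diabetes <- function(panel) {
  panel <- panel[order(panel$person_id, panel$wave), , drop = FALSE]
  panel$diabetes_ever <- as.logical(
    ave(as.numeric(panel$diabetes_ever), panel$person_id, FUN = cummax)
  )
  panel
}

#' Build the person-period transition file
#'
#' Converts a long panel into one row per observed wave-to-wave transition,
#' the unit on which the multinomial transition models are fitted. The
#' entry filter keeps persons whose first interview falls in `entry_year`
#' at completed ages within `entry_age_range`. For each consecutive record
#' pair of a retained person: the origin state is the classified cognition
#' score at the earlier interview; the destination is `D` if the person is
#' dead at the later record (death overrides missing cognition), censoring
#' (`lost`) yields no period, and pairs with a missing origin score or a
#' missing destination score while alive are dropped and counted.
#'
#' @param panel long-format panel as from [simulate_panel()], diabetes
#'   flags already absorbing (see [carry_forward_diabetes()]).
#' @param entry_year calendar year of study entry (default: earliest year
#'   in the panel).
#' @param entry_age_range completed-age range retained at entry.
#' @return `data.frame` with columns `person_id`, `origin_age`,
#'   `origin_state`, `dest_state`, `interval`, `sex`, `education`, `race`,
#'   `diabetes`, plus a `drop_report` attribute counting candidate pairs,
#'   retained periods, pairs dropped for missing cognition, censored pairs
#'   and persons excluded by the entry filter.
#' @export
build_person_periods <- function(panel, entry_year = min(panel$year),
                                 entry_age_range = c(50, 74)) {
  panel <- panel[order(panel$person_id, panel$wave), , drop = FALSE]
  dup <- panel$person_id[duplicated(panel[c("person_id", "wave")])]
  if (length(dup)) {
    stop("duplicated waves for person_id ", dup[1], call. = FALSE)
  }

  first <- !duplicated(panel$person_id)
  ok_entry <- panel$year[first] == entry_year &
    floor(panel$age[first]) >= entry_age_range[1] &
    floor(panel$age[first]) <= entry_age_range[2]
  keep_ids <- panel$person_id[first][ok_entry]
  n_excluded <- sum(!ok_entry)
  panel <- panel[panel$person_id %in% keep_ids, , drop = FALSE]

  n <- nrow(panel)
  same <- panel$person_id[-n] == panel$person_id[-1]
  i0 <- which(same)          # origin rows
  i1 <- i0 + 1L              # destination rows
  if (any(panel$age[i1] <= panel$age[i0])) {
    bad <- panel$person_id[i0][panel$age[i1] <= panel$age[i0]][1]
    stop("non-increasing age within person_id ", bad, call. = FALSE)
  }

  origin <- cognition_binary(classify_cognition(panel$cog_score[i0]))
  dest_vital <- panel$vital[i1]
  dest <- cognition_binary(classify_cognition(panel$cog_score[i1]))
  dest[dest_vital == "dead"] <- "D"
  dest[dest_vital == "lost"] <- NA_character_

  censored <- dest_vital == "lost"
  usable <- !is.na(origin) & !censored & !is.na(dest)
  dropped_missing <- sum(!usable & !censored)

  periods <- data.frame(
    person_id = panel$person_id[i0][usable],
    origin_age = panel$age[i0][usable],
    origin_state = factor(origin[usable], levels = ORIGIN_STATES),
    dest_state = factor(dest[usable], levels = DEST_STATES),
    interval = panel$age[i1][usable] - panel$age[i0][usable],
    sex = panel$sex[i0][usable],
    education = panel$education[i0][usable],
    race = panel$race[i0][usable],
    diabetes = as.logical(panel$diabetes_ever[i0][usable]),
    stringsAsFactors = FALSE
  )
  attr(periods, "drop_report") <- list(
    n_candidate_pairs = length(i0),
    n_periods = nrow(periods),
    n_dropped_missing_cognition = dropped_missing,
    n_censored_pairs = sum(censored),
    n_persons_excluded_entry = n_excluded
  )
  periods
}

#' Crude death rate per 1,000 person-years
#'
#' @param deaths number of deaths.
#' @param person_years person-years of follow-up.
#' @return deaths per 1,000 person-years; 0 when there are no deaths.
#' @export
crude_death_rate <- function(deaths, person_years) {
  if (deaths == 0) return(0)
  1000 * deaths / person_years
}

summary_block <- function(panel_first, periods, death_credit) {
  py <- sum(periods$interval * ifelse(periods$dest_state == "D", death_credit, 1))
  deaths <- sum(periods$dest_state == "D")
  trans <- table(origin = periods$origin_state, dest = periods$dest_state)
  entry_state <- cognition_binary(classify_cognition(panel_first$cog_score))
  list(
    n_persons = nrow(panel_first),
    person_years = py,
    n_deaths = deaths,
    crude_death_rate = crude_death_rate(deaths, py),
    diabetes_prevalence = 100 * mean(panel_first$diabetes_ever),
    impairment_prevalence_at_entry = 100 * mean(entry_state == "I", na.rm = TRUE),
    transitions = trans
  )
}

#' Descriptive summary of a panel and its person-period file
#'
#' Sample sizes, person-years, deaths, crude death rates per 1,000
#' person-years, baseline diabetes and impairment prevalence, and
#' transition counts, overall and split by diabetes exposure. The split
#' classifies person-periods by the absorbing diabetes flag at the origin
#' interview (time-varying exposure) and persons by their baseline flag.
#'
#' @param panel long-format panel.
#' @param periods person-period file from [build_person_periods()].
#' @param death_credit fraction of the interval credited to person-years
#'   when the period ends in death (default 0.5: a mid-interval death in a
#'   2-year interval contributes 1 year).
#' @return object of class `sample_summary` with components `total`,
#'   `diabetes`, `no_diabetes`.
#' @export
summarize_sample <- function(panel, periods, death_credit = 0.5) {
  if (nrow(panel) == 0 || nrow(periods) == 0) {
    stop("empty panel or person-period file", call. = FALSE)
  }
  panel <- panel[order(panel$person_id, panel$wave), , drop = FALSE]
  keep <- panel$person_id %in% unique(periods$person_id)
  first <- panel[!duplicated(panel$person_id) & keep, , drop = FALSE]
  out <- list(
    total = summary_block(first, periods, death_credit),
    diabetes = summary_block(first[first$diabetes_ever, , drop = FALSE],
                             periods[periods$diabetes, , drop = FALSE],
                             death_credit),
    no_diabetes = summary_block(first[!first$diabetes_ever, , drop = FALSE],
                                periods[!periods$diabetes, , drop = FALSE],
                                death_credit)
  )
  class(out) <- "sample_summary"
  out
}

#' @export
print.sample_summary <- function(x, ...) {
  fmt <- function(b) {
    sprintf("n=%d  person-years=%.0f  deaths=%d  rate/1000=%.1f  diabetes=%.1f%%  impaired@entry=%.1f%%",
            b$n_persons, b$person_years, b$n_deaths, b$crude_death_rate,
            b$diabetes_prevalence, b$impairment_prevalence_at_entry)
  }
  cat("Sample summary\n")
  cat("  total:      ", fmt(x$total), "\n")
  cat("  diabetes:   ", fmt(x$diabetes), "\n")
  cat("  no diabetes:", fmt(x$no_diabetes), "\n")
  invisible(x)
}

#' Age-specific prevalence of cognitive impairment
#'
#' Share of interviews with a non-missing cognition score classified as
#' impaired, within age groups, split by sex and diabetes status.
#'
#' @param panel long-format panel.
#' @param age_breaks left-closed break points partitioning the age axis
#'   (default five-year groups 50-54 ... 85-89).
#' @return long `data.frame` with `sex`, `diabetes`, `age_group`,
#'   `n_interviews` and `prevalence` (percent; `NA` for empty cells).
#' @export
prevalence_by_age <- function(panel, age_breaks = seq(50, 90, by = 5)) {
  alive <- panel[panel$vital == "alive" & !is.na(panel$cog_score), , drop = FALSE]
  alive <- alive[alive$age >= min(age_breaks) & alive$age < max(age_breaks), ,
                 drop = FALSE]
  grp <- cut(alive$age, breaks = age_breaks, right = FALSE)
  imp <- cognition_binary(classify_cognition(alive$cog_score)) == "I"
  cells <- expand.grid(sex = SEX_LEVELS, diabetes = c(FALSE, TRUE),
                       age_group = levels(grp), stringsAsFactors = FALSE)
  cells$n_interviews <- mapply(function(s, d, g) {
    sum(alive$sex == s & alive$diabetes_ever == d & grp == g, na.rm = TRUE)
  }, cells$sex, cells$diabetes, cells$age_group)
  cells$prevalence <- mapply(function(s, d, g) {
    sel <- alive$sex == s & alive$diabetes_ever == d & grp == g
    if (!any(sel, na.rm = TRUE)) return(NA_real_)
    100 * mean(imp[which(sel)])
  }, cells$sex, cells$diabetes, cells$age_group)
  cells[order(cells$sex, cells$diabetes, cells$age_group), , drop = FALSE]
}
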