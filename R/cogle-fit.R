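# One full pipeline pass: prepare -> fit -> scenario -> Markov chain.
# Returns the tidy estimate table plus the fitted pieces. `opts` is the
# validated option list assembled by cogle().
cogle_pipeline <- function(panel, opts, keep_fits = FALSE) {
  panel <- carry_forward_diabetes(panel)
  periods <- build_person_periods(panel, opts$entry_year, opts$entry_age_range)
  profile <- covariate_means(periods, unit = opts$profile_unit)

  fits <- lapply(setNames(SEX_LEVELS, SEX_LEVELS), function(sx) {
    list(N = fit_transition_model(periods, sx, "N", ridge = opts$ridge),
         I = fit_transition_model(periods, sx, "I", ridge = opts$ridge))
  })

  first <- panel[!duplicated(panel$person_id), , drop = FALSE]
  first <- first[first$person_id %in% unique(periods$person_id), , drop = FALSE]
  sex_w <- setNames(vapply(SEX_LEVELS, function(s) mean(first$sex == s), 0),
                    SEX_LEVELS)

  grid <- seq(opts$start_age, opts$omega - opts$h, by = opts$h)
  profiles <- list(overall = profile)
  if (opts$by_education) {
    for (i in seq_along(EDU_LEVELS)) {
      e <- c(0, 0, 0); e[i] <- 1
      profiles[[EDU_LEVELS[i]]] <-
        covariate_profile(e, profile$race, profile$diabetes)
    }
  }

  rows <- list()
  for (edu in names(profiles)) {
    for (scen in opts$scenarios) {
      per_sex <- lapply(SEX_LEVELS, function(sx) {
        surf <- scenario_surface(fits[[sx]]$N, fits[[sx]]$I, profiles[[edu]],
                                 scen, panel = panel, ages = grid,
                                 omega = opts$omega, mix = opts$mix)
        chain <- build_chain(surf, h = opts$h, omega = opts$omega,
                             start_age = opts$start_age)
        lt <- state_expectancies(chain, init = opts$init,
                                 start_age = opts$start_age,
                                 half_final = opts$half_final)
        on <- onset_distribution(chain, start_age = opts$start_age,
                                 onset_label = opts$onset_label)
        c(LE_total = lt$LE_total, LE_N = lt$LE_N, LE_I = lt$LE_I,
          onset_age = on$mean_onset_age, pr_ever_impaired = on$pr_ever)
      })
      names(per_sex) <- SEX_LEVELS
      # pooled = baseline-sex-share-weighted average of the sex-specific
      # chain results (the models themselves stay sex-stratified)
      pooled <- sex_w["male"] * per_sex$male + sex_w["female"] * per_sex$female
      pooled["onset_age"] <-
        (sex_w["male"] * per_sex$male["pr_ever_impaired"] * per_sex$male["onset_age"] +
         sex_w["female"] * per_sex$female["pr_ever_impaired"] * per_sex$female["onset_age"]) /
        pooled["pr_ever_impaired"]
      for (sx in c(SEX_LEVELS, "pooled")) {
        est <- if (sx == "pooled") pooled else per_sex[[sx]]
        rows[[length(rows) + 1L]] <- data.frame(
          sex = sx, scenario = scen, education = edu, t(est),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  out <- list(results = results, profile = profile, sex_weights = sex_w,
              periods = periods)
  if (keep_fits) out$fits <- fits
  out
}

results_vector <- function(results) {
  v <- unlist(lapply(seq_len(nrow(results)), function(i) {
    est <- as.numeric(results[i, c("LE_total", "LE_N", "LE_I",
                                   "onset_age", "pr_ever_impaired")])
    setNames(est, paste(c("LE_total", "LE_N", "LE_I", "onset_age", "pr_ever"),
                        results$sex[i], results$scenario[i],
                        results$education[i], sep = "."))
  }))
  v
}

#' Fit the cognitive life-expectancy model to a panel
#'
#' The central estimator. From a long-format longitudinal panel it
#' (1) applies the absorbing diabetes coding and builds the person-period
#' transition file, (2) fits sex- and origin-state-stratified multinomial
#' logistic transition models with age, age squared, education,
#' race/ethnicity and diabetes, (3) predicts age-specific transition
#' surfaces at the sample-mean covariate profile under the observed,
#' no-diabetes and full-diabetes scenarios, and (4) runs the discrete-time
#' Markov chain matrix population model to obtain total life expectancy,
#' years lived with and without cognitive impairment, and the mean age at
#' first onset of impairment at `start_age`, by sex (with a
#' baseline-sex-share pooled row). Optionally, percentile confidence
#' intervals from a cluster bootstrap over persons.
#'
#' @param panel long-format panel: columns `person_id`, `wave`, `year`,
#'   `age`, `sex`, `education`, `race`, `diabetes_ever`, `cog_score`,
#'   `vital`, `death_year` (see [simulate_panel()] for the layout).
#' @param scenarios subset of `"observed"`, `"no_diabetes"`,
#'   `"full_diabetes"`.
#' @param start_age age at which expectancies and onset are evaluated.
#' @param h Markov step in years (the interview interval).
#' @param omega closure age of the chain.
#' @param entry_year,entry_age_range entry filter passed to
#'   [build_person_periods()].
#' @param init initial distribution over `(N, I)` at `start_age`; the
#'   default starts everyone cognitively non-impaired.
#' @param ridge ridge penalty for the transition fits (see
#'   [fit_transition_model()]).
#' @param by_education additionally evaluate each education level
#'   (profile set to the education vertex, race held at sample means).
#' @param mix scenario mixing rule, see [scenario_surface()].
#' @param profile_unit unit for covariate means, see [covariate_means()].
#' @param half_final,onset_label occupancy and onset-dating conventions,
#'   see [state_expectancies()] and [onset_distribution()].
#' @param B bootstrap replications (0 = no intervals).
#' @param seed bootstrap master seed.
#' @return object of class `cogle`: `results` (tidy estimate table, with
#'   `lower.*`/`upper.*` columns when `B > 0`), `fits`, `profile`,
#'   `sample_summary`, `sex_weights`, `boot`, `opts`, `panel`.
#' @export
cogle <- function(panel,
                  scenarios = SCENARIO_NAMES,
                  start_age = 50, h = 2, omega = 110,
                  entry_year = min(panel$year),
                  entry_age_range = c(50, 74),
                  init = c(N = 1, I = 0),
                  ridge = 0,
                  by_education = FALSE,
                  mix = c("probability", "logit"),
                  profile_unit = c("periods", "persons"),
                  half_final = FALSE,
                  onset_label = "midpoint",
                  B = 0, seed = 1L) {
  scenarios <- match.arg(scenarios, SCENARIO_NAMES, several.ok = TRUE)
  opts <- list(
    scenarios = scenarios, start_age = start_age, h = h, omega = omega,
    entry_year = entry_year, entry_age_range = entry_age_range,
    init = init, ridge = ridge, by_education = by_education,
    mix = match.arg(mix), profile_unit = match.arg(profile_unit),
    half_final = half_final, onset_label = onset_label
  )
  main <- cogle_pipeline(panel, opts, keep_fits = TRUE)
  summ <- summarize_sample(carry_forward_diabetes(panel), main$periods)

  boot <- NULL
  results <- main$results
  if (B > 0) {
    stat <- function(p) results_vector(cogle_pipeline(p, opts)$results)
    boot <- cluster_bootstrap(panel, stat, B = B, seed = seed)
    q <- c("LE_total", "LE_N", "LE_I", "onset_age", "pr_ever")
    qcol <- c("LE_total", "LE_N", "LE_I", "onset_age", "pr_ever_impaired")
    for (j in seq_along(q)) {
      key <- paste(q[j], results$sex, results$scenario, results$education,
                   sep = ".")
      results[[paste0(qcol[j], "_lo")]] <- boot$ci["lower", key]
      results[[paste0(qcol[j], "_hi")]] <- boot$ci["upper", key]
    }
  }

  structure(
    list(results = results, fits = main$fits, profile = main$profile,
         sample_summary = summ, sex_weights = main$sex_weights,
         drop_report = attr(main$periods, "drop_report"),
         boot = boot, opts = opts, panel = panel, call = match.call()),
    class = "cogle"
  )
}
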