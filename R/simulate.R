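# Cumulative log-survival of the diagnosis hazard on an integer age grid,
# used both for prevalence at entry and incidence between waves.
hazard_log_surv <- function(config, max_age = 130) {
  grid <- seq(config$diabetes_from_age, max_age)
  h <- pmin(pmax(config$diabetes_hazard(grid), 0), 1 - 1e-12)
  ls <- c(0, cumsum(log1p(-h)))
  function(age) {
    age <- pmin(pmax(age, config$diabetes_from_age), max_age + 1)
    stats::approx(c(grid, max_age + 1), ls, xout = age, rule = 2)$y
  }
}

#' Simulate a synthetic longitudinal aging panel
#'
#' Generates a long-format panel (one row per person-wave) from the
#' data-generating truth in a [sim_config()]: latent cognition states
#' evolve wave-to-wave by the configured softmax transition probabilities,
#' diabetes diagnosis arrives by an age-specific hazard and is absorbing,
#' deaths occur between interviews and are recorded at the following wave,
#' persons can be lost to follow-up, and observed cognition scores are
#' drawn uniformly from the latent state's score band (12-27 non-impaired,
#' 0-11 impaired) and then masked missing at the configured rate.
#'
#' @param config a [sim_config()].
#' @return `data.frame` with columns `person_id`, `wave`, `year`, `age`,
#'   `sex`, `education`, `race`, `diabetes_ever`, `cog_score`, `vital`
#'   (`alive`/`dead`/`lost`) and `death_year`. A `dead` or `lost` row is a
#'   person's last row. Deterministic given `config$seed`.
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, simulate_panel_impl(config))
}

simulate_panel_impl <- function(config) {
  n <- config$n_persons
  h <- config$wave_interval
  lsurv <- hazard_log_surv(config)

  age <- runif(n, config$entry_age_range[1], config$entry_age_range[2] + 1)
  sex <- SEX_LEVELS[1L + (runif(n) < config$sex_split)]
  education <- sample(EDU_LEVELS, n, replace = TRUE, prob = config$education_probs)
  race <- sample(RACE_LEVELS, n, replace = TRUE, prob = config$race_probs)
  diabetes <- runif(n) < 1 - exp(lsurv(age) - lsurv(config$diabetes_from_age))
  p_imp <- plogis(config$baseline_impairment[1] +
                    config$baseline_impairment[2] * (age - 65))
  latent <- ifelse(runif(n) < p_imp, "I", "N")

  active <- rep(TRUE, n)          # still under observation, alive
  died <- rep(FALSE, n)           # died in the previous interval
  lost <- rep(FALSE, n)           # lost in the previous interval
  death_year <- rep(NA_real_, n)

  rows <- vector("list", config$n_waves)
  for (w in seq_len(config$n_waves)) {
    year <- config$entry_year + (w - 1) * h
    cur_age <- age + (w - 1) * h
    emit <- active | died | lost
    if (!any(emit)) break

    score <- rep(NA_integer_, n)
    obs_alive <- active & !died & !lost
    nN <- sum(obs_alive & latent == "N")
    nI <- sum(obs_alive & latent == "I")
    score[obs_alive & latent == "N"] <- sample(12:27, nN, replace = TRUE)
    score[obs_alive & latent == "I"] <- sample(0:11, nI, replace = TRUE)
    if (config$cognition_missing_prob > 0) {
      miss <- obs_alive & runif(n) < config$cognition_missing_prob
      score[miss] <- NA_integer_
    }

    vital <- rep("alive", n)
    vital[died] <- "dead"
    vital[lost] <- "lost"
    rows[[w]] <- data.frame(
      person_id = which(emit),
      wave = w,
      year = year,
      age = cur_age[emit],
      sex = sex[emit],
      education = education[emit],
      race = race[emit],
      diabetes_ever = diabetes[emit],
      cog_score = score[emit],
      vital = vital[emit],
      death_year = death_year[emit],
      stringsAsFactors = FALSE
    )
    active[died | lost] <- FALSE
    died[] <- FALSE
    lost[] <- FALSE
    if (w == config$n_waves) break

    # wave-to-wave transition for persons still under observation
    idx_active <- which(active)
    if (length(idx_active) == 0) next
    dest <- rep(NA_character_, n)
    for (sx in SEX_LEVELS) {
      for (org in ORIGIN_STATES) {
        grp <- idx_active[sex[idx_active] == sx & latent[idx_active] == org]
        if (length(grp) == 0) next
        X <- cbind(1, cur_age[grp], cur_age[grp]^2,
                   education[grp] == EDU_LEVELS[2], education[grp] == EDU_LEVELS[3],
                   race[grp] == RACE_LEVELS[2], race[grp] == RACE_LEVELS[3],
                   race[grp] == RACE_LEVELS[4],
                   as.numeric(diabetes[grp]))
        P <- softmax_probs(X, config$true_coefficients[[sx]][[org]])
        # columns: stay, exit1, exit2; map back to destination labels
        labs <- c(org, rownames(config$true_coefficients[[sx]][[org]]))
        dest[grp] <- labs[sample_rows(P)]
      }
    }
    dies <- active & dest == "D"
    died[dies] <- TRUE
    death_year[dies] <- year + floor(runif(sum(dies)) * h)
    surv <- active & !dies
    latent[surv] <- dest[surv]

    if (config$attrition_prob > 0) {
      p_attr <- rep(config$attrition_prob, n)
      p_attr[latent == "I"] <- p_attr[latent == "I"] *
        config$attrition_impaired_multiplier
      lost[surv & runif(n) < p_attr] <- TRUE
    }

    # incident diabetes diagnoses during the interval (absorbing)
    newdx <- surv & !diabetes &
      runif(n) < 1 - exp(lsurv(cur_age + h) - lsurv(cur_age))
    diabetes[newdx] <- TRUE
  }

  panel <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  panel <- panel[order(panel$person_id, panel$wave), , drop = FALSE]
  rownames(panel) <- NULL
  panel
}

#' Exact transition surface implied by a generator configuration
#'
#' Oracle counterpart of [simulate_panel()]: evaluates the configured
#' softmax transition probabilities directly, with no sampling noise, for
#' a given sex, diabetes setting and covariate profile.
#'
#' @param config a [sim_config()].
#' @param diabetes_setting value in `[0, 1]` plugged into the diabetes
#'   covariate (0 and 1 give the two pure surfaces).
#' @param sex `"male"` or `"female"`.
#' @param profile a [covariate_profile()]; defaults to the configured
#'   population category probabilities.
#' @param ages age grid (default 50 to 110).
#' @return a [probability_surface()].
#' @export
true_surface <- function(config, diabetes_setting, sex,
                         profile = NULL, ages = 50:110) {
  stopifnot(inherits(config, "sim_config"))
  sex <- match.arg(sex, SEX_LEVELS)
  check_prob(diabetes_setting, "diabetes_setting", 1)
  if (is.null(profile)) {
    profile <- covariate_profile(config$education_probs, config$race_probs)
  }
  X <- profile_design(ages, profile, diabetes_setting)
  PN <- softmax_probs(X, config$true_coefficients[[sex]][["N"]])
  PI <- softmax_probs(X, config$true_coefficients[[sex]][["I"]])
  # generator matrices order exits as (switch, death) from either origin:
  # from N: (stay N, to I, to D); from I: (stay I, to N, to D)
  probability_surface(
    ages,
    P_N = PN[, c(1, 2, 3), drop = FALSE],
    P_I = PI[, c(2, 1, 3), drop = FALSE],
    provenance = list(source = "true_surface", sex = sex,
                      diabetes = diabetes_setting)
  )
}
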