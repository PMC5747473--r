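#' Build transition-model coefficients on the natural age scale
#'
#' Expresses an exit logit as a quadratic in centred, scaled age,
#' `level + slope * z + curve * z^2` with `z = (age - center) / scale`,
#' and returns the equivalent coefficients on `(intercept, age, age^2)`.
#' Centred parameterisation keeps the numbers interpretable: `level` is the
#' logit at `center` years, `slope`/`curve` the change per `scale` years.
#'
#' @param level logit relative to remaining in the origin state, at `center`.
#' @param slope linear change in the logit per `scale` years of age.
#' @param curve quadratic curvature per `scale` years squared.
#' @param center,scale age centring and scaling constants (years).
#' @return numeric vector `c(intercept, age, age2)` on the natural scale.
#' @export
quad_age_coef <- function(level, slope, curve, center = 70, scale = 10) {
  b2 <- curve / scale^2
  b1 <- slope / scale - 2 * center * curve / scale^2
  b0 <- level - slope * center / scale + curve * center^2 / scale^2
  c(b0, b1, b2)
}

make_stratum <- function(exit1, exit2, labels) {
  m <- rbind(exit1, exit2)
  rownames(m) <- labels
  colnames(m) <- COVARIATE_NAMES
  m
}

#' Default data-generating transition coefficients
#'
#' Per (sex, origin state) coefficient matrices for the two exit logits
#' (reference outcome: remain in the origin state) over the covariates
#' intercept, age, age squared, education dummies, race dummies and the
#' ever-diagnosed-diabetes indicator. The defaults describe a biennial
#' aging panel: mortality and impairment incidence rise with age (faster
#' than linearly on the logit scale), recovery from impairment declines
#' with age, education protects against impairment, and diabetes raises
#' both mortality and impairment incidence while lowering recovery.
#'
#' @param diabetes_death added to both death logits for the ever-diagnosed.
#' @param diabetes_impair added to the impairment-incidence logit.
#' @param diabetes_recovery added to the recovery logit (negative = harmful).
#' @return nested list `truth[[sex]][[origin]]`, each a 2 x 9 matrix with
#'   rows named by the non-reference destination states.
#' @export
default_transition_truth <- function(diabetes_death = 0.45,
                                     diabetes_impair = 0.40,
                                     diabetes_recovery = -0.20) {
  # covariate effects shared across strata (logit shifts)
  edu_imp <- c(-0.45, -0.95)   # hs_some_college, college on impairment
  edu_dth <- c(-0.15, -0.30)
  edu_rec <- c(0.30, 0.60)
  race_imp <- c(0.45, 0.35, 0.10)  # nh_black, hispanic, other
  race_dth <- c(0.15, 0.00, 0.00)
  race_rec <- c(-0.20, -0.15, 0.00)

  stratum <- function(imp_level, dth_level, rec_level, dthI_level) {
    fromN <- make_stratum(
      c(quad_age_coef(imp_level, 0.70, 0.15), edu_imp, race_imp, diabetes_impair),
      c(quad_age_coef(dth_level, 0.95, 0.18), edu_dth, race_dth, diabetes_death),
      c("I", "D")
    )
    fromI <- make_stratum(
      c(quad_age_coef(rec_level, -0.45, 0.00), edu_rec, race_rec, diabetes_recovery),
      c(quad_age_coef(dthI_level, 0.80, 0.14), edu_dth, race_dth, diabetes_death),
      c("N", "D")
    )
    list(N = fromN, I = fromI)
  }

  list(
    male = stratum(imp_level = -2.15, dth_level = -2.62,
                   rec_level = -0.55, dthI_level = -1.82),
    female = stratum(imp_level = -2.25, dth_level = -3.10,
                     rec_level = -0.55, dthI_level = -2.25)
  )
}

#' Configuration for the synthetic panel generator
#'
#' Collects the design of the emulated longitudinal study and the
#' data-generating truth. Defaults emulate a biennial panel of Americans
#' aged 50-74 at entry followed for 12 years, with roughly 2.3% of persons
#' ever lost to follow-up and 13.8% of cognition responses missing.
#'
#' @param n_persons number of persons at entry.
#' @param entry_age_range closed age interval sampled uniformly at entry.
#' @param wave_interval years between interviews.
#' @param n_waves number of interview waves (default 7 spanning 12 years).
#' @param entry_year calendar year of wave 1.
#' @param sex_split proportion female.
#' @param education_probs probabilities of `less_hs`, `hs_some_college`,
#'   `college` (must sum to 1).
#' @param race_probs probabilities of `nh_white`, `nh_black`, `hispanic`,
#'   `other` (must sum to 1).
#' @param true_coefficients nested coefficient list as produced by
#'   [default_transition_truth()].
#' @param diabetes_hazard per-year probability of a first diabetes
#'   diagnosis; a scalar or a function of age. Accumulates from
#'   `diabetes_from_age` to set prevalence at entry, and drives incident
#'   diagnoses between waves. Diagnosis is absorbing.
#' @param diabetes_from_age age from which the diagnosis hazard accrues.
#' @param baseline_impairment length-2 vector `(logit at age 65, slope per
#'   year)` of the probability of being cognitively impaired at entry.
#' @param attrition_prob per-wave probability that a surviving person is
#'   lost before the next interview. The default gives ~2.3% of persons
#'   ever lost over seven waves.
#' @param attrition_impaired_multiplier multiplies the attrition probability
#'   for persons currently impaired (1 = attrition independent of state).
#' @param cognition_missing_prob per-interview probability that the
#'   cognition score is missing.
#' @param seed integer seed; the generator is deterministic given the seed.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_persons,
                       entry_age_range = c(50, 74),
                       wave_interval = 2,
                       n_waves = 7,
                       entry_year = 2000,
                       sex_split = 0.57,
                       education_probs = c(0.238, 0.570, 0.192),
                       race_probs = c(0.761, 0.139, 0.080, 0.020),
                       true_coefficients = default_transition_truth(),
                       diabetes_hazard = 0.0049,
                       diabetes_from_age = 30,
                       baseline_impairment = c(-1.72, 0.055),
                       attrition_prob = 0.0045,
                       attrition_impaired_multiplier = 1,
                       cognition_missing_prob = 0.138,
                       seed = 1L) {
  if (!is.numeric(n_persons) || length(n_persons) != 1 || n_persons < 1) {
    stop_cfg("n_persons", "must be a positive count")
  }
  if (length(entry_age_range) != 2 || entry_age_range[1] > entry_age_range[2] ||
      entry_age_range[1] < 50 || entry_age_range[2] > 110) {
    stop_cfg("entry_age_range", "must be an increasing range within [50, 110]")
  }
  if (!is.numeric(wave_interval) || wave_interval < 1) {
    stop_cfg("wave_interval", "must be >= 1 year")
  }
  if (!is.numeric(n_waves) || n_waves < 1) stop_cfg("n_waves", "must be >= 1")
  check_prob(sex_split, "sex_split", 1)
  check_simplex(education_probs, "education_probs", 3)
  check_simplex(race_probs, "race_probs", 4)
  check_prob(attrition_prob, "attrition_prob", 1)
  check_prob(cognition_missing_prob, "cognition_missing_prob", 1)
  if (!is.numeric(attrition_impaired_multiplier) ||
      attrition_impaired_multiplier < 0) {
    stop_cfg("attrition_impaired_multiplier", "must be non-negative")
  }
  hazard_fn <- if (is.function(diabetes_hazard)) {
    diabetes_hazard
  } else {
    check_prob(diabetes_hazard, "diabetes_hazard", 1)
    function(age) rep(diabetes_hazard, length(age))
  }
  for (sx in SEX_LEVELS) {
    for (org in ORIGIN_STATES) {
      m <- true_coefficients[[sx]][[org]]
      if (is.null(m) || !is.matrix(m) || any(dim(m) != c(2, length(COVARIATE_NAMES)))) {
        stop_cfg("true_coefficients",
                 sprintf("missing or malformed matrix for sex '%s', origin '%s'", sx, org))
      }
    }
  }
  structure(
    list(
      n_persons = as.integer(n_persons),
      entry_age_range = as.numeric(entry_age_range),
      wave_interval = as.numeric(wave_interval),
      n_waves = as.integer(n_waves),
      entry_year = as.integer(entry_year),
      sex_split = sex_split,
      education_probs = education_probs,
      race_probs = race_probs,
      true_coefficients = true_coefficients,
      diabetes_hazard = hazard_fn,
      diabetes_from_age = diabetes_from_age,
      baseline_impairment = baseline_impairment,
      attrition_prob = attrition_prob,
      attrition_impaired_multiplier = attrition_impaired_multiplier,
      cognition_missing_prob = cognition_missing_prob,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic panel configuration\n")
  cat(sprintf("  persons: %d, waves: %d every %g years from %d\n",
              x$n_persons, x$n_waves, x$wave_interval, x$entry_year))
  cat(sprintf("  entry ages: [%g, %g], %.0f%% female\n",
              x$entry_age_range[1], x$entry_age_range[2], 100 * x$sex_split))
  cat(sprintf("  attrition/wave: %.4f, cognition missing: %.3f, seed: %d\n",
              x$attrition_prob, x$cognition_missing_prob, x$seed))
  invisible(x)
}
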