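SCENARIO_NAMES <- c("observed", "no_diabetes", "full_diabetes")

#' Empirical CDF of age at first observed diabetes diagnosis
#'
#' Among persons ever diagnosed during follow-up, the age at the first
#' interview reporting the diagnosis. Persons already diagnosed at their
#' first interview are left-censored and contribute at their entry age
#' (their true diagnosis age is earlier, so lifetime exposure is
#' understated; the count is reported).
#'
#' @param panel long-format panel with absorbing diabetes flags.
#' @return object of class `diagnosis_cdf`: the diagnosis ages, the
#'   left-censored count and an `ecdf` function `F_dx(a)`.
#' @export
diagnosis_age_cdf <- function(panel) {
  panel <- panel[order(panel$person_id, panel$wave), , drop = FALSE]
  dx <- panel[panel$diabetes_ever, , drop = FALSE]
  if (nrow(dx) == 0) {
    stop("no ever-diabetic persons in the panel; the full-diabetes scenario is undefined",
         call. = FALSE)
  }
  firstdx <- dx[!duplicated(dx$person_id), , drop = FALSE]
  entry <- panel[!duplicated(panel$person_id), c("person_id", "wave")]
  left_censored <- sum(firstdx$wave == entry$wave[match(firstdx$person_id,
                                                        entry$person_id)])
  structure(
    list(ages = sort(firstdx$age), n = nrow(firstdx),
         n_left_censored = left_censored, F = ecdf(firstdx$age)),
    class = "diagnosis_cdf"
  )
}

#' @export
print.diagnosis_cdf <- function(x, ...) {
  cat(sprintf("Diagnosis-age CDF: %d ever-diabetic persons (%d left-censored at entry)\n",
              x$n, x$n_left_censored))
  cat(sprintf("  quartiles: %s\n",
              paste(round(quantile(x$ages, c(.25, .5, .75)), 1), collapse = " / ")))
  invisible(x)
}

#' Observed age-specific diabetes prevalence weights
#'
#' Share of interviews with an ever-diagnosis of diabetes within age bins
#' of width `h` aligned to the chain's age grid. Empty cells are filled
#' from the nearest populated cell.
#'
#' @param panel long-format panel.
#' @param ages age-grid points at which weights are needed.
#' @param h bin width in years.
#' @return numeric vector `w(a)` in `[0, 1]`, one entry per age in `ages`,
#'   with an attribute `n_filled` counting cells carried from neighbours.
#' @export
observed_prevalence_weights <- function(panel, ages = 50:110, h = 2) {
  alive <- panel[panel$vital == "alive", , drop = FALSE]
  if (nrow(alive) == 0) stop("no interviews in panel", call. = FALSE)
  bin <- findInterval(alive$age, c(ages, max(ages) + h), rightmost.closed = FALSE)
  bin[alive$age < ages[1]] <- NA
  w <- vapply(seq_along(ages), function(i) {
    sel <- which(!is.na(bin) & bin == i)
    if (!length(sel)) NA_real_ else mean(alive$diabetes_ever[sel])
  }, 0)
  n_filled <- sum(is.na(w))
  if (anyNA(w)) {
    filled <- which(!is.na(w))
    if (!length(filled)) stop("no populated age cells", call. = FALSE)
    for (i in which(is.na(w))) {
      w[i] <- w[filled[which.min(abs(filled - i))]]
    }
  }
  attr(w, "n_filled") <- n_filled
  w
}

#' Scenario transition surface
#'
#' Builds the probability surface for one of the three diabetes scenarios
#' as an age-wise convex combination of the diabetes = 1 and diabetes = 0
#' predicted surfaces: `P(a) = w(a) P1(a) + (1 - w(a)) P0(a)`.
#'
#' * `observed`: `w(a)` is the observed age-specific diabetes prevalence
#'   ([observed_prevalence_weights()]).
#' * `no_diabetes`: `w = 0` everywhere.
#' * `full_diabetes`: `w(a) = F_dx(a)`, the observed CDF of diagnosis ages
#'   among ever-diabetics ([diagnosis_age_cdf()]), forced to 1 at the
#'   closure age: everyone is eventually diagnosed, and before their
#'   diagnosis age eventual diabetics transition at non-diabetic rates.
#'
#' Mixing probabilities (rather than plugging a fractional diabetes value
#' into the logit) represents a heterogeneous population of diagnosed and
#' undiagnosed individuals; the logit plug-in is available via
#' `mix = "logit"`.
#'
#' @param fit_N,fit_I `transition_fit` objects of one sex.
#' @param profile a [covariate_profile()].
#' @param scenario scenario name.
#' @param panel panel used for weights (needed for `observed` and
#'   `full_diabetes`).
#' @param ages age grid.
#' @param omega closure age for `full_diabetes` (weight forced to 1).
#' @param mix `"probability"` (convex combination, default) or `"logit"`
#'   (fractional diabetes covariate).
#' @return a [probability_surface()] with the scenario recorded in its
#'   provenance.
#' @export
scenario_surface <- function(fit_N, fit_I, profile, scenario, panel = NULL,
                             ages = 50:110, omega = 110,
                             mix = c("probability", "logit")) {
  scenario <- match.arg(scenario, SCENARIO_NAMES)
  mix <- match.arg(mix)
  w <- switch(scenario,
    no_diabetes = rep(0, length(ages)),
    observed = {
      if (is.null(panel)) stop("panel needed for the observed scenario", call. = FALSE)
      as.numeric(observed_prevalence_weights(panel, ages))
    },
    full_diabetes = {
      if (is.null(panel)) stop("panel needed for the full-diabetes scenario", call. = FALSE)
      cdf <- diagnosis_age_cdf(panel)
      wv <- cdf$F(ages)
      wv[ages >= omega] <- 1
      wv
    }
  )
  if (any(w < 0 | w > 1)) stop("scenario weights outside [0, 1]", call. = FALSE)

  if (mix == "logit") {
    X <- profile_design(ages, profile, w)   # age-varying diabetes covariate
    PN <- softmax_probs(X[, fit_N$covariates, drop = FALSE],
                        fit_N$coefficients)           # cols N, I, D
    PI <- softmax_probs(X[, fit_I$covariates, drop = FALSE],
                        fit_I$coefficients)           # cols I, N, D
    out <- probability_surface(ages, PN, PI[, c(2, 1, 3)])
  } else {
    s1 <- predict_surface(fit_N, fit_I, profile, diabetes = 1, ages = ages)
    s0 <- predict_surface(fit_N, fit_I, profile, diabetes = 0, ages = ages)
    out <- probability_surface(
      ages,
      P_N = w * s1$P_N + (1 - w) * s0$P_N,
      P_I = w * s1$P_I + (1 - w) * s0$P_I
    )
  }
  out$provenance <- list(source = "scenario_surface", scenario = scenario,
                         sex = fit_N$sex, mix = mix, weights = w)
  out
}
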