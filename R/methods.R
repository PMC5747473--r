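#' @export
print.cogle <- function(x, ...) {
  cat("Cognitive life-expectancy model\n")
  s <- x$sample_summary$total
  cat(sprintf("  %d persons, %.0f person-years, %d deaths (%.1f /1000 py)\n",
              s$n_persons, s$person_years, s$n_deaths, s$crude_death_rate))
  cat(sprintf("  scenarios: %s; start age %g, step %g y, closure %g\n",
              paste(x$opts$scenarios, collapse = ", "),
              x$opts$start_age, x$opts$h, x$opts$omega))
  ov <- x$results[x$results$education == "overall", , drop = FALSE]
  df <- data.frame(sex = ov$sex, scenario = ov$scenario,
                   LE_total = round(ov$LE_total, 2),
                   LE_N = round(ov$LE_N, 2), LE_I = round(ov$LE_I, 2),
                   onset_age = round(ov$onset_age, 2))
  print(df, row.names = FALSE)
  if (!is.null(x$boot)) {
    cat(sprintf("  95%% percentile CIs from %d cluster-bootstrap replications (%d failed)\n",
                x$boot$B, x$boot$n_failed))
  }
  invisible(x)
}

#' @export
summary.cogle <- function(object, ...) {
  structure(list(results = object$results,
                 sample_summary = object$sample_summary,
                 profile = object$profile,
                 drop_report = object$drop_report,
                 boot = object$boot),
            class = "summary.cogle")
}

#' @export
print.summary.cogle <- function(x, ...) {
  print(x$sample_summary)
  dr <- x$drop_report
  cat(sprintf("  person-periods: %d retained of %d candidate pairs (%d dropped for missing cognition, %d censored)\n",
              dr$n_periods, dr$n_candidate_pairs,
              dr$n_dropped_missing_cognition, dr$n_censored_pairs))
  cat("\nEstimates", if (!is.null(x$boot)) "(with 95% percentile CIs)", "\n")
  out <- x$results
  num <- vapply(out, is.numeric, TRUE)
  out[num] <- lapply(out[num], round, 3)
  print(out, row.names = FALSE)
  invisible(x)
}

#' Coefficients of the fitted transition models
#'
#' @param object a [cogle()] fit.
#' @param ... unused.
#' @return nested list `coef[[sex]][[origin]]` of natural-scale exit-logit
#'   coefficient matrices (rows: destination states, reference = stay).
#' @export
coef.cogle <- function(object, ...) {
  lapply(object$fits, function(f) lapply(f, coef))
}

#' Predicted transition surface from a fitted model
#'
#' @param object a [cogle()] fit.
#' @param sex `"male"` or `"female"`.
#' @param scenario scenario name, or `NULL` to predict at a fixed
#'   `diabetes` value instead.
#' @param diabetes diabetes covariate in `[0, 1]`, used when `scenario`
#'   is `NULL`.
#' @param ages age grid.
#' @param profile covariate profile (default: the fit's sample means).
#' @param ... unused.
#' @return a [probability_surface()].
#' @export
predict.cogle <- function(object, sex = "female", scenario = "observed",
                          diabetes = NULL, ages = 50:110,
                          profile = object$profile, ...) {
  sex <- match.arg(sex, SEX_LEVELS)
  f <- object$fits[[sex]]
  if (!is.null(diabetes)) {
    return(predict_surface(f$N, f$I, profile, diabetes, ages))
  }
  scenario_surface(f$N, f$I, profile, scenario, panel = object$panel,
                   ages = ages, omega = object$opts$omega,
                   mix = object$opts$mix)
}

#' Simulate panels from a fitted model
#'
#' Parametric simulation: generates synthetic panels whose data-generating
#' transition coefficients are the fitted ones and whose demographic mix
#' matches the estimation sample, using the same panel design (waves,
#' interval, entry ages) as the fitted data.
#'
#' @param object a [cogle()] fit.
#' @param nsim number of panels.
#' @param seed integer seed.
#' @param n_persons persons per panel (default: as in the fitted panel).
#' @param ... passed on to [sim_config()].
#' @return a panel `data.frame`, or a list of them when `nsim > 1`.
#' @export
simulate.cogle <- function(object, nsim = 1, seed = 1L,
                           n_persons = NULL, ...) {
  truth <- lapply(object$fits, function(f) {
    list(N = coef(f$N), I = coef(f$I))
  })
  first <- object$panel[!duplicated(object$panel$person_id), , drop = FALSE]
  cfg <- function(s) {
    sim_config(
      n_persons = n_persons %||% length(unique(object$panel$person_id)),
      wave_interval = object$opts$h,
      entry_year = object$opts$entry_year,
      entry_age_range = object$opts$entry_age_range,
      sex_split = mean(first$sex == "female"),
      education_probs = vapply(EDU_LEVELS, function(l) mean(first$education == l), 0),
      race_probs = vapply(RACE_LEVELS, function(l) mean(first$race == l), 0),
      true_coefficients = truth,
      seed = s,
      ...
    )
  }
  panels <- lapply(seq_len(nsim), function(i) {
    simulate_panel(cfg(derive_seed(seed, i)))
  })
  if (nsim == 1) panels[[1]] else panels
}

#' Plot a fitted cognitive life-expectancy model
#'
#' `type = "lifetable"`: stacked bars of years lived without and with
#' cognitive impairment by scenario and sex. `type = "onset"`: mean age at
#' first onset by scenario and sex. `type = "surface"`: age profiles of
#' the predicted transition probabilities for one sex and scenario.
#'
#' @param x a [cogle()] fit.
#' @param type plot type.
#' @param sex sex for `type = "surface"`.
#' @param scenario scenario for `type = "surface"`.
#' @param ... passed to the underlying graphics calls.
#' @return `x`, invisibly.
#' @export
plot.cogle <- function(x, type = c("lifetable", "onset", "surface"),
                       sex = "female", scenario = "observed", ...) {
  type <- match.arg(type)
  ov <- x$results[x$results$education == "overall", , drop = FALSE]
  if (type == "lifetable") {
    m <- rbind(ov$LE_N, ov$LE_I)
    lab <- paste(ov$scenario, ov$sex, sep = "\n")
    bp <- graphics::barplot(m, names.arg = lab, col = c("grey80", "grey40"),
                            ylab = sprintf("years from age %g", x$opts$start_age),
                            main = "Life expectancy with and without cognitive impairment",
                            cex.names = 0.7, ...)
    graphics::text(bp, ov$LE_total, labels = sprintf("%.1f", ov$LE_total), pos = 3)
    graphics::legend("topright", fill = c("grey40", "grey80"),
                     legend = c("impaired", "non-impaired"), bty = "n")
  } else if (type == "onset") {
    bp <- graphics::barplot(ov$onset_age, names.arg = paste(ov$scenario, ov$sex, sep = "\n"),
                            ylab = "mean age at first onset",
                            ylim = c(0, max(ov$onset_age, na.rm = TRUE) * 1.1),
                            main = "Age at first onset of cognitive impairment",
                            cex.names = 0.7, ...)
    graphics::text(bp, ov$onset_age, labels = sprintf("%.1f", ov$onset_age), pos = 3)
  } else {
    surf <- predict(x, sex = sex, scenario = scenario)
    graphics::matplot(surf$ages, cbind(surf$P_N[, c("I", "D")], surf$P_I[, "D"]),
                      type = "l", lty = 1:3, col = c("black", "firebrick", "grey40"),
                      xlab = "age", ylab = "2-year transition probability",
                      main = sprintf("Transition probabilities (%s, %s)", sex, scenario),
                      ...)
    graphics::legend("topleft", lty = 1:3, col = c("black", "firebrick", "grey40"),
                     legend = c("N to I", "N to D", "I to D"), bty = "n")
  }
  invisible(x)
}
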