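#' Run the full study pipeline on a panel
#'
#' Convenience wrapper assembling all study outputs: descriptive
#' statistics, age-specific impairment prevalence, and the life-expectancy
#' and onset-age estimates for every scenario, by sex (and optionally by
#' education), with cluster-bootstrap intervals when `B > 0`.
#'
#' @param panel long-format panel.
#' @param B bootstrap replications (0 = none).
#' @param seed bootstrap seed.
#' @param by_education also evaluate the three education levels.
#' @param ... further arguments to [cogle()].
#' @return list of class `cogle_study`: `fit` (the [cogle()] object),
#'   `table1` (sample summary), `prevalence` (age-group prevalence table)
#'   and `results` (tidy estimate table).
#' @export
run_full_study <- function(panel, B = 0, seed = 1L, by_education = FALSE, ...) {
  fit <- cogle(panel, B = B, seed = seed, by_education = by_education, ...)
  structure(
    list(fit = fit,
         table1 = fit$sample_summary,
         prevalence = prevalence_by_age(carry_forward_diabetes(panel)),
         results = fit$results),
    class = "cogle_study"
  )
}

#' @export
print.cogle_study <- function(x, ...) {
  print(x$fit)
  invisible(x)
}

table1_df <- function(s) {
  blk <- function(b, label) {
    data.frame(group = label, n_persons = b$n_persons,
               person_years = b$person_years, n_deaths = b$n_deaths,
               crude_death_rate = b$crude_death_rate,
               diabetes_prevalence = b$diabetes_prevalence,
               impairment_prevalence_at_entry = b$impairment_prevalence_at_entry)
  }
  rbind(blk(s$total, "total"), blk(s$diabetes, "diabetes"),
        blk(s$no_diabetes, "no_diabetes"))
}

#' Write study outputs to disk
#'
#' Serialises a [run_full_study()] result as plain-text tables:
#' `table1.csv` (descriptives by diabetes status), `prevalence.csv`
#' (age-group impairment prevalence), `lifetable.csv` and `onset.csv`
#' (estimates in long format) and, when a bootstrap was run, `ci.json`.
#'
#' @param study a `cogle_study`.
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
write_cogle_report <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(table1_df(study$table1),
                   file.path(dir, "table1.csv"), row.names = FALSE)
  utils::write.csv(study$prevalence,
                   file.path(dir, "prevalence.csv"), row.names = FALSE)
  res <- study$results
  lt_cols <- grep("^(sex|scenario|education|LE_)", names(res), value = TRUE)
  on_cols <- grep("^(sex|scenario|education|onset_|pr_ever)", names(res), value = TRUE)
  utils::write.csv(res[lt_cols], file.path(dir, "lifetable.csv"), row.names = FALSE)
  utils::write.csv(res[on_cols], file.path(dir, "onset.csv"), row.names = FALSE)
  if (!is.null(study$fit$boot)) {
    ci <- study$fit$boot$ci
    jsonlite::write_json(
      list(B = study$fit$boot$B, n_failed = study$fit$boot$n_failed,
           level = study$fit$boot$level,
           lower = as.list(ci["lower", ]), upper = as.list(ci["upper", ])),
      file.path(dir, "ci.json"), auto_unbox = TRUE, digits = NA
    )
  }
  invisible(dir)
}
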