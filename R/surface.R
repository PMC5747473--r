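#' Covariate profile for transition-probability prediction
#'
#' A profile fixes the non-age covariates at which transition probabilities
#' are predicted. Category vectors may be fractional (e.g. sample means),
#' in which case the prediction is evaluated at the mean dummy values.
#'
#' @param education length-3 vector over `less_hs`, `hs_some_college`,
#'   `college`; must sum to 1.
#' @param race length-4 vector over `nh_white`, `nh_black`, `hispanic`,
#'   `other`; must sum to 1.
#' @param diabetes value in `[0, 1]`; the default profile value, usually
#'   overridden per scenario.
#' @return object of class `covariate_profile`.
#' @export
covariate_profile <- function(education, race, diabetes = 0) {
  check_simplex(education, "education", 3, tol = 1e-9)
  check_simplex(race, "race", 4, tol = 1e-9)
  check_prob(diabetes, "diabetes", 1)
  structure(
    list(education = as.numeric(education), race = as.numeric(race),
         diabetes = as.numeric(diabetes)),
    class = "covariate_profile"
  )
}

#' @export
print.covariate_profile <- function(x, ...) {
  cat("Covariate profile\n")
  cat("  education:", paste(sprintf("%s=%.3f", EDU_LEVELS, x$education), collapse = ", "), "\n")
  cat("  race:     ", paste(sprintf("%s=%.3f", RACE_LEVELS, x$race), collapse = ", "), "\n")
  cat(sprintf("  diabetes:  %.3f\n", x$diabetes))
  invisible(x)
}

# Design matrix rows for a profile evaluated on an age grid:
# (1, age, age^2, edu dummies, race dummies, diabetes).
profile_design <- function(ages, profile, diabetes) {
  X <- cbind(1, ages, ages^2,
             profile$education[2], profile$education[3],
             profile$race[2], profile$race[3], profile$race[4],
             diabetes)
  colnames(X) <- COVARIATE_NAMES
  X
}

# Softmax over (reference score 0, exit scores X beta'); beta is the
# 2 x p exit-coefficient matrix. Columns ordered (stay, exit1, exit2).
softmax_probs <- function(X, beta) {
  scores <- cbind(0, X %*% t(beta))
  m <- scores[, 1L]
  for (j in 2:ncol(scores)) m <- pmax(m, scores[, j])
  e <- exp(scores - m)
  e / rowSums(e)
}

#' Age-indexed transition-probability surface
#'
#' Transition probabilities from the living origin states `N` (cognitively
#' non-impaired) and `I` (impaired) to destinations `N`, `I`, `D` (dead),
#' on an age grid. Each row is a probability distribution.
#'
#' @param ages numeric age grid.
#' @param P_N,P_I matrices with one row per age and columns `N`, `I`, `D`;
#'   transitions out of the non-impaired and impaired state respectively.
#' @param provenance free-form list recording how the surface was built
#'   (fit identifiers, profile, scenario label).
#' @return object of class `prob_surface`.
#' @export
probability_surface <- function(ages, P_N, P_I, provenance = list()) {
  P_N <- as.matrix(P_N); P_I <- as.matrix(P_I)
  if (nrow(P_N) != length(ages) || nrow(P_I) != length(ages) ||
      ncol(P_N) != 3 || ncol(P_I) != 3) {
    stop("surface matrices must be length(ages) x 3", call. = FALSE)
  }
  for (nm in c("P_N", "P_I")) {
    P <- get(nm)
    if (any(P < -1e-12 | P > 1 + 1e-12)) {
      stop(nm, ": probabilities outside [0, 1]", call. = FALSE)
    }
    if (max(abs(rowSums(P) - 1)) > 1e-10) {
      stop(nm, ": rows must sum to 1", call. = FALSE)
    }
  }
  colnames(P_N) <- colnames(P_I) <- DEST_STATES
  structure(
    list(ages = as.numeric(ages), P_N = P_N, P_I = P_I, provenance = provenance),
    class = "prob_surface"
  )
}

#' @export
print.prob_surface <- function(x, ...) {
  cat(sprintf("Transition-probability surface over ages %g-%g (%d points)\n",
              min(x$ages), max(x$ages), length(x$ages)))
  if (!is.null(x$provenance$scenario)) {
    cat("  scenario:", x$provenance$scenario, "\n")
  }
  i <- unique(round(seq(1, length(x$ages), length.out = min(5, length(x$ages)))))
  df <- data.frame(age = x$ages[i],
                   round(x$P_N[i, , drop = FALSE], 4),
                   round(x$P_I[i, , drop = FALSE], 4))
  names(df) <- c("age", paste0("N.", DEST_STATES), paste0("I.", DEST_STATES))
  print(df, row.names = FALSE)
  invisible(x)
}
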