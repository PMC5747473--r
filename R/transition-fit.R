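#' Design matrix for person-periods
#'
#' One row per person-period: intercept, age at the origin interview, age
#' squared, education dummies (reference `less_hs`), race dummies
#' (reference `nh_white`) and the diabetes indicator at origin.
#'
#' @param periods person-period `data.frame` from [build_person_periods()].
#' @return numeric matrix with columns in the package-wide covariate order.
#' @export
period_design <- function(periods) {
  bad_edu <- setdiff(unique(as.character(periods$education)), EDU_LEVELS)
  bad_race <- setdiff(unique(as.character(periods$race)), RACE_LEVELS)
  if (length(bad_edu)) stop("unknown education level: ", bad_edu[1], call. = FALSE)
  if (length(bad_race)) stop("unknown race level: ", bad_race[1], call. = FALSE)
  X <- cbind(1, periods$origin_age, periods$origin_age^2,
             periods$education == EDU_LEVELS[2], periods$education == EDU_LEVELS[3],
             periods$race == RACE_LEVELS[2], periods$race == RACE_LEVELS[3],
             periods$race == RACE_LEVELS[4],
             as.numeric(periods$diabetes))
  colnames(X) <- COVARIATE_NAMES
  X
}

# Newton-Raphson maximum-likelihood fit of a softmax (multinomial logit)
# model. y takes values 1..K with 1 the reference outcome; returns the
# p x (K-1) coefficient matrix for outcomes 2..K. An optional ridge
# penalty 0.5*ridge*sum(B[-intercept]^2) stabilises separated or empty
# cells. Parameter stacking order for the Hessian: outcome-major.
multinom_newton <- function(X, y, ridge = 0, max_iter = 60, tol = 1e-10) {
  n <- nrow(X); p <- ncol(X); K <- max(y)
  Y <- matrix(0, n, K); Y[cbind(seq_len(n), y)] <- 1
  B <- matrix(0, p, K - 1)
  pen_mask <- rep(c(0, rep(1, p - 1)), K - 1)  # no penalty on intercepts
  yi <- cbind(seq_len(n), y)

  # penalised log-likelihood plus the softmax probabilities at B
  evaluate <- function(B) {
    sc <- cbind(0, X %*% B)
    m <- sc[, 1L]
    for (j in 2:K) m <- pmax(m, sc[, j])
    e <- exp(sc - m)
    rs <- rowSums(e)
    list(ll = sum(sc[yi]) - sum(m + log(rs)) - 0.5 * ridge * sum((B[-1, ])^2),
         P = e / rs)
  }

  cur <- evaluate(B)
  converged <- FALSE
  H <- NULL
  for (it in seq_len(max_iter)) {
    P <- cur$P
    g <- as.vector(crossprod(X, Y[, -1, drop = FALSE] - P[, -1, drop = FALSE])) -
      ridge * pen_mask * as.vector(B)
    H <- matrix(0, p * (K - 1), p * (K - 1))
    for (j in seq_len(K - 1)) {
      for (k in j:(K - 1)) {
        w <- P[, j + 1] * ((j == k) - P[, k + 1])
        blk <- -crossprod(X, X * w)
        rj <- (j - 1) * p + seq_len(p); rk <- (k - 1) * p + seq_len(p)
        H[rj, rk] <- blk
        if (k != j) H[rk, rj] <- blk
      }
    }
    diag(H) <- diag(H) - ridge * pen_mask

    step <- tryCatch(solve(H, -g), error = function(e) NULL)
    if (is.null(step)) break
    lambda <- 1
    repeat {
      B_new <- B + matrix(lambda * step, p, K - 1)
      nxt <- evaluate(B_new)
      if (is.finite(nxt$ll) && nxt$ll >= cur$ll - 1e-12) break
      lambda <- lambda / 2
      if (lambda < 1e-8) { B_new <- B; nxt <- cur; break }
    }
    delta <- abs(nxt$ll - cur$ll)
    B <- B_new
    cur <- nxt
    if (delta < tol * (abs(cur$ll) + 1)) {
      converged <- TRUE
      break
    }
  }
  vcov <- if (!is.null(H)) tryCatch(solve(-H), error = function(e) NULL)
  list(coefficients = B, loglik = cur$ll + 0.5 * ridge * sum((B[-1, ])^2),
       converged = converged, vcov = vcov, iterations = it)
}

#' Fit a stratified multinomial transition model
#'
#' Maximum-likelihood multinomial logistic regression of the destination
#' state on age, age squared, education, race/ethnicity and diabetes, for
#' one (sex, origin cognition state) stratum. The reference outcome is
#' remaining in the origin state, so coefficients are exit logits for the
#' state switch and for death. Age and age squared are standardised
#' internally before optimisation (age squared reaches 110^2 on the
#' natural scale); reported coefficients are on the natural scale.
#'
#' @param periods person-period file from [build_person_periods()].
#' @param sex `"male"` or `"female"`.
#' @param origin_state `"N"` or `"I"`.
#' @param ridge ridge penalty on non-intercept coefficients (0 = plain
#'   maximum likelihood). If the unpenalised fit fails to converge (e.g.
#'   an empty outcome-by-category cell in a bootstrap replicate), the fit
#'   is retried with a small ridge and the value used is recorded.
#' @param covariates names of non-intercept design columns to include
#'   (default: all of them). Dropping sparse category dummies is the
#'   collapse remedy for strata with empty outcome-by-category cells.
#' @return object of class `transition_fit` with components `sex`,
#'   `origin_state`, `outcome_labels` (reference first), `coefficients`
#'   (natural-scale matrix, one row per non-reference destination),
#'   `covariates`, `vcov`, `loglik`, `converged`, `n_periods` and `ridge`.
#' @export
fit_transition_model <- function(periods, sex, origin_state, ridge = 0,
                                 covariates = COVARIATE_NAMES[-1]) {
  sex <- match.arg(sex, SEX_LEVELS)
  origin_state <- match.arg(origin_state, ORIGIN_STATES)
  sub <- periods[periods$sex == sex & periods$origin_state == origin_state, ,
                 drop = FALSE]
  labels <- if (origin_state == "N") c("N", "I", "D") else c("I", "N", "D")
  y <- match(as.character(sub$dest_state), labels)
  counts <- tabulate(y, nbins = 3)
  if (any(counts == 0)) {
    stop(sprintf(
      "empty outcome class '%s' in stratum (%s, origin %s); collapse categories or enlarge the sample",
      labels[which(counts == 0)[1]], sex, origin_state), call. = FALSE)
  }

  covariates <- match.arg(covariates, COVARIATE_NAMES[-1], several.ok = TRUE)
  keep_cols <- c("(Intercept)", covariates)
  X <- period_design(sub)[, keep_cols, drop = FALSE]
  age_cols <- which(keep_cols %in% c("age", "age2"))
  mu <- colMeans(X[, age_cols, drop = FALSE])
  sdv <- apply(X[, age_cols, drop = FALSE], 2, sd)
  sdv[sdv == 0] <- 1
  Xs <- X
  if (length(age_cols)) {
    Xs[, age_cols] <- sweep(sweep(X[, age_cols, drop = FALSE], 2, mu), 2, sdv, "/")
  }

  fit <- multinom_newton(Xs, y, ridge = ridge)
  ridge_used <- ridge
  if (!fit$converged || is.null(fit$vcov)) {
    for (r in c(1e-6, 1e-4)) {
      if (r <= ridge_used) next
      fit2 <- multinom_newton(Xs, y, ridge = r)
      if (fit2$converged && !is.null(fit2$vcov)) {
        fit <- fit2; ridge_used <- r
        break
      }
    }
  }

  # invert the age standardisation: b_nat = M b_std per outcome
  p <- ncol(X)
  M <- diag(p)
  for (j in age_cols) {
    M[j, j] <- 1 / sdv[match(j, age_cols)]
    M[1, j] <- -mu[match(j, age_cols)] / sdv[match(j, age_cols)]
  }
  B_nat <- M %*% fit$coefficients
  Tmat <- kronecker(diag(2), M)
  vcov_nat <- if (!is.null(fit$vcov)) Tmat %*% fit$vcov %*% t(Tmat) else NULL

  coefs <- t(B_nat)
  rownames(coefs) <- labels[-1]
  colnames(coefs) <- keep_cols
  par_names <- as.vector(outer(keep_cols, labels[-1],
                               function(c, o) paste(o, c, sep = ":")))
  if (!is.null(vcov_nat)) dimnames(vcov_nat) <- list(par_names, par_names)

  structure(
    list(sex = sex, origin_state = origin_state, outcome_labels = labels,
         coefficients = coefs, covariates = keep_cols, vcov = vcov_nat,
         loglik = fit$loglik, converged = fit$converged,
         n_periods = nrow(sub), ridge = ridge_used,
         iterations = fit$iterations),
    class = "transition_fit"
  )
}

#' @export
coef.transition_fit <- function(object, ...) object$coefficients

#' @export
print.transition_fit <- function(x, ...) {
  cat(sprintf("Multinomial transition model: sex %s, origin state %s\n",
              x$sex, x$origin_state))
  cat(sprintf("  %d person-periods, reference outcome '%s', logLik %.2f%s%s\n",
              x$n_periods, x$outcome_labels[1], x$loglik,
              if (x$converged) "" else " [NOT CONVERGED]",
              if (x$ridge > 0) sprintf(" (ridge %g)", x$ridge) else ""))
  print(round(x$coefficients, 5))
  invisible(x)
}

#' Predict destination probabilities from a transition fit
#'
#' @param object a `transition_fit`.
#' @param ages ages at which to predict.
#' @param profile a [covariate_profile()].
#' @param diabetes diabetes covariate value in `[0, 1]`.
#' @param ... unused.
#' @return matrix with one row per age, columns in `outcome_labels` order
#'   (reference outcome first); rows sum to 1.
#' @export
predict.transition_fit <- function(object, ages, profile, diabetes, ...) {
  X <- profile_design(ages, profile, diabetes)[, object$covariates, drop = FALSE]
  P <- softmax_probs(X, object$coefficients)
  colnames(P) <- object$outcome_labels
  rownames(P) <- ages
  P
}

#' Mean covariate profile of a person-period file
#'
#' Category proportions over person-periods (the estimation sample), used
#' to predict transition probabilities at the overall sample mean.
#'
#' @param periods person-period file.
#' @param unit `"periods"` (default, matches the estimation sample) or
#'   `"persons"` (first period per person).
#' @return a [covariate_profile()] with the diabetes component set to the
#'   sample share of diabetic person-periods.
#' @export
covariate_means <- function(periods, unit = c("periods", "persons")) {
  unit <- match.arg(unit)
  if (nrow(periods) == 0) stop("empty person-period file", call. = FALSE)
  if (unit == "persons") {
    periods <- periods[!duplicated(periods$person_id), , drop = FALSE]
  }
  edu <- vapply(EDU_LEVELS, function(l) mean(periods$education == l), 0)
  race <- vapply(RACE_LEVELS, function(l) mean(periods$race == l), 0)
  covariate_profile(edu, race, mean(periods$diabetes))
}

#' Predict the age-indexed transition surface from a pair of fits
#'
#' Evaluates both origin-state fits of one sex at a covariate profile and
#' a diabetes setting over an age grid, assembling the row-stochastic
#' transition-probability surface used by the Markov chain.
#'
#' @param fit_N,fit_I `transition_fit` objects for origin states `N` and
#'   `I` of the same sex.
#' @param profile a [covariate_profile()].
#' @param diabetes diabetes covariate value in `[0, 1]`.
#' @param ages age grid (default 50 to 110).
#' @return a [probability_surface()].
#' @export
predict_surface <- function(fit_N, fit_I, profile, diabetes, ages = 50:110) {
  if (fit_N$origin_state != "N" || fit_I$origin_state != "I") {
    stop("fits must be for origin states N and I respectively", call. = FALSE)
  }
  if (fit_N$sex != fit_I$sex) {
    stop("fits are for different sexes", call. = FALSE)
  }
  if (!fit_N$converged || !fit_I$converged) {
    stop("cannot predict from a non-converged fit", call. = FALSE)
  }
  PN <- predict(fit_N, ages, profile, diabetes)      # cols N, I, D
  PI <- predict(fit_I, ages, profile, diabetes)      # cols I, N, D
  probability_surface(
    ages, P_N = PN, P_I = PI[, c("N", "I", "D")],
    provenance = list(source = "predict_surface", sex = fit_N$sex,
                      diabetes = diabetes)
  )
}
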