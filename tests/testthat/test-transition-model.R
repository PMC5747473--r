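make_periods <- function(n = 2000, seed = 1, truth = NULL, sex_split = 0.5) {
  cfg <- sim_config(n_persons = n, seed = seed, sex_split = sex_split,
                    true_coefficients = truth %||% default_transition_truth(),
                    attrition_prob = 0, cognition_missing_prob = 0)
  build_person_periods(simulate_panel(cfg))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("the design matrix encodes covariates in the documented order", {
  pp <- data.frame(origin_age = c(60, 50), origin_state = "N",
                   education = c("college", "less_hs"),
                   race = c("nh_white", "nh_white"),
                   diabetes = c(TRUE, FALSE))
  X <- period_design(pp)
  expect_equal(unname(X[1, ]), c(1, 60, 3600, 0, 1, 0, 0, 0, 1))
  expect_equal(unname(X[2, ]), c(1, 50, 2500, 0, 0, 0, 0, 0, 0))
  pp$education <- "phd"
  expect_error(period_design(pp), "unknown education")
})

test_that("fitted probabilities average to the outcome frequencies", {
  # intercept score equation of the MLE: mean fitted probability per
  # destination equals the empirical destination share, exactly
  truth <- flat_truth(from_N = c(-0.7, -0.7), from_I = c(-0.7, -0.7))
  periods <- make_periods(1500, seed = 11, truth = truth)
  fit <- fit_transition_model(periods, "female", "N")
  expect_true(fit$converged)
  sub <- periods[periods$sex == "female" & periods$origin_state == "N", ]
  emp <- prop.table(table(factor(sub$dest_state, c("N", "I", "D"))))
  P <- cogle:::softmax_probs(period_design(sub), coef(fit))
  expect_equal(unname(colMeans(P)), as.numeric(emp), tolerance = 1e-6)
  # and a genuinely intercept-only (single covariate pattern) stratum
  # reproduces the pattern-wise frequencies through the ridge-stabilised fit
  sub1 <- sub
  sub1$origin_age <- 70; sub1$education <- "less_hs"
  sub1$race <- "nh_white"; sub1$diabetes <- FALSE
  fit1 <- fit_transition_model(sub1, "female", "N", ridge = 1e-8)
  emp1 <- prop.table(table(factor(sub1$dest_state, c("N", "I", "D"))))
  pred1 <- predict(fit1, ages = 70, covariate_profile(c(1, 0, 0), c(1, 0, 0, 0)),
                   diabetes = 0)
  expect_equal(as.numeric(pred1), as.numeric(emp1), tolerance = 1e-4)
})

test_that("duplicating every period leaves the estimates unchanged", {
  periods <- make_periods(600, seed = 2)
  f1 <- fit_transition_model(periods, "male", "N")
  f2 <- fit_transition_model(rbind(periods, periods), "male", "N")
  expect_equal(coef(f1), coef(f2), tolerance = 1e-6)
})

test_that("the in-package MLE matches nnet::multinom", {
  skip_if_not_installed("nnet")
  periods <- make_periods(3000, seed = 4)
  fit <- fit_transition_model(periods, "female", "N")
  sub <- periods[periods$sex == "female" & periods$origin_state == "N", ]
  sub$dest <- factor(as.character(sub$dest_state), levels = c("N", "I", "D"))
  sub$age_c <- (sub$origin_age - 65) / 10
  ref <- nnet::multinom(
    dest ~ age_c + I(age_c^2) + education + race + diabetes,
    data = transform(sub,
                     education = factor(education, levels = cogle:::EDU_LEVELS),
                     race = factor(race, levels = cogle:::RACE_LEVELS)),
    trace = FALSE, maxit = 500, reltol = 1e-12
  )
  expect_equal(fit$loglik, as.numeric(stats::logLik(ref)), tolerance = 1e-5)
  # compare on predictions (coefficient parameterisations differ)
  nd <- data.frame(age_c = (c(55, 70, 85) - 65) / 10,
                   education = factor("less_hs", levels = cogle:::EDU_LEVELS),
                   race = factor("nh_white", levels = cogle:::RACE_LEVELS),
                   diabetes = FALSE)
  ours0 <- predict(fit, ages = c(55, 70, 85),
                   covariate_profile(c(1, 0, 0), c(1, 0, 0, 0)), diabetes = 0)
  theirs <- predict(ref, newdata = nd, type = "probs")
  expect_equal(unname(ours0), unname(theirs[, c("N", "I", "D")]),
               tolerance = 1e-4)
})

test_that("empty outcome classes and non-convergence are surfaced", {
  periods <- make_periods(300, seed = 6)
  nodeath <- periods[periods$dest_state != "D", ]
  expect_error(fit_transition_model(nodeath, "female", "N"), "empty outcome")
})

test_that("predicted surfaces are row-stochastic and shift-invariant", {
  periods <- make_periods(1200, seed = 8)
  fN <- fit_transition_model(periods, "female", "N")
  fI <- fit_transition_model(periods, "female", "I")
  prof <- covariate_means(periods)
  surf <- predict_surface(fN, fI, prof, diabetes = 0.3)
  expect_lt(max(abs(rowSums(surf$P_N) - 1)), 1e-10)
  expect_lt(max(abs(rowSums(surf$P_I) - 1)), 1e-10)
  expect_true(all(surf$P_N >= 0 & surf$P_N <= 1))

  # softmax invariance: adding a constant to every outcome score
  X <- cogle:::profile_design(50:60, prof, 0.3)
  beta <- coef(fN)
  # adding a constant k to all three outcome scores leaves probabilities
  # unchanged: softmax((0, s1, s2)) == softmax((k, s1+k, s2+k))
  sc <- cbind(0, X %*% t(beta))
  k <- 5
  e1 <- exp(sc - apply(sc, 1, max)); p1 <- e1 / rowSums(e1)
  sc2 <- sc + k
  e2 <- exp(sc2 - apply(sc2, 1, max)); p2 <- e2 / rowSums(e2)
  expect_equal(p1, p2, tolerance = 1e-12)

  # mismatched strata are rejected
  fM <- fit_transition_model(periods, "male", "N")
  expect_error(predict_surface(fM, fI, prof, 0), "different sexes")
  expect_error(predict_surface(fI, fI, prof, 0), "origin states")
})

test_that("covariate means summarise the estimation sample", {
  periods <- make_periods(800, seed = 9)
  prof <- covariate_means(periods)
  expect_s3_class(prof, "covariate_profile")
  expect_equal(sum(prof$education), 1, tolerance = 1e-12)
  expect_equal(prof$education[3], mean(periods$education == "college"))
  expect_equal(prof$race[2], mean(periods$race == "nh_black"))
  all_col <- periods; all_col$education <- "college"
  expect_equal(covariate_means(all_col)$education, c(0, 0, 1))
})

test_that("fitted surfaces recover the data-generating truth", {
  truth <- default_transition_truth()
  errs <- sapply(c(4000, 32000), function(n) {
    cfg <- sim_config(n_persons = n, seed = 21, attrition_prob = 0,
                      cognition_missing_prob = 0)
    periods <- build_person_periods(simulate_panel(cfg))
    fN <- fit_transition_model(periods, "female", "N")
    fI <- fit_transition_model(periods, "female", "I")
    prof <- covariate_profile(cfg$education_probs, cfg$race_probs)
    ages <- seq(52, 82, by = 2)   # inside the observed origin-age support
    fitted <- predict_surface(fN, fI, prof, diabetes = 0, ages = ages)
    tru <- true_surface(cfg, 0, "female", prof, ages = ages)
    dev <- abs(cbind(fitted$P_N - tru$P_N, fitted$P_I - tru$P_I))
    c(mean = mean(dev), max = max(dev))
  })
  expect_lt(errs["mean", 2], errs["mean", 1])
  expect_lt(errs["max", 2], 0.05)
})

test_that("Wald intervals cover the true coefficients at roughly the nominal rate", {
  cfg <- sim_config(n_persons = 15000, seed = 31, attrition_prob = 0,
                    cognition_missing_prob = 0)
  periods <- build_person_periods(simulate_panel(cfg))
  covered <- total <- 0
  for (sx in c("male", "female")) {
    for (org in c("N", "I")) {
      fit <- fit_transition_model(periods, sx, org)
      est <- as.vector(t(coef(fit)))
      se <- sqrt(diag(fit$vcov))
      tru <- as.vector(t(cfg$true_coefficients[[sx]][[org]]))
      covered <- covered + sum(abs(est - tru) <= qnorm(0.975) * se)
      total <- total + length(tru)
    }
  }
  expect_gt(covered / total, 0.85)   # 72 coefficients, nominal 95%
})
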