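# Shared fixture builders. All fixtures are generated in code; tests fix
# seeds where sampling is involved.

# Transition truth with constant (age-free) exit logits, handy for exact
# frequency checks. `from_N` and `from_I` are length-2 logit vectors for
# (switch, death) relative to staying.
flat_truth <- function(from_N = c(-2, -3), from_I = c(-1, -2),
                       diabetes = c(0, 0, 0)) {
  mat <- function(l1, l2, labels, d1, d2) {
    m <- rbind(c(l1, rep(0, 8)), c(l2, rep(0, 8)))
    m[1, 9] <- d1; m[2, 9] <- d2
    rownames(m) <- labels
    colnames(m) <- cogle:::COVARIATE_NAMES
    m
  }
  # diabetes = (death, impairment, recovery) logit shifts
  one_sex <- list(
    N = mat(from_N[1], from_N[2], c("I", "D"), diabetes[2], diabetes[1]),
    I = mat(from_I[1], from_I[2], c("N", "D"), diabetes[3], diabetes[1])
  )
  list(male = one_sex, female = one_sex)
}

# Default truth with the education and race effects removed, so that the
# model is profile-independent (used where the estimand must not depend
# on the replicate's covariate mix).
age_only_truth <- function(...) {
  tr <- default_transition_truth(...)
  for (sx in names(tr)) {
    for (org in names(tr[[sx]])) {
      tr[[sx]][[org]][, 4:8] <- 0
    }
  }
  tr
}

# Surface with the same transition rows at every age.
constant_surface <- function(pN, pI, ages = seq(50, 108, by = 2)) {
  probability_surface(
    ages,
    P_N = matrix(pN, length(ages), 3, byrow = TRUE),
    P_I = matrix(pI, length(ages), 3, byrow = TRUE)
  )
}

# Annual-step chain with constant impairment probability b and death
# probability q from either state, long horizon so that closed-form
# geometric results hold to high precision.
geometric_chain <- function(q = 0.1, b = 0, q_I = q, horizon = 600) {
  ages <- seq(50, 50 + horizon - 1, by = 1)
  surf <- probability_surface(
    ages,
    P_N = matrix(c(1 - b - q, b, q), length(ages), 3, byrow = TRUE),
    P_I = matrix(c(0, 1 - q_I, q_I), length(ages), 3, byrow = TRUE)
  )
  build_chain(surf, h = 1, omega = 50 + horizon, start_age = 50)
}

# Random valid chain for property tests.
random_chain <- function(seed, n_ages = 20, h = 2) {
  set.seed(seed)
  ages <- seq(50, 50 + (n_ages - 1) * h, by = h)
  rowp <- function() {
    x <- rgamma(3, shape = c(5, 1, 1))
    x / sum(x)
  }
  PN <- t(replicate(n_ages, rowp()))
  PI <- t(replicate(n_ages, rowp()))[, c(2, 1, 3)]
  surf <- probability_surface(ages, PN, PI)
  build_chain(surf, h = h, omega = max(ages) + h, start_age = 50)
}

# Tiny hand-written panel: one row per entry of `states`, which is a list
# person_id -> character vector over waves with entries "N", "I", "D"
# (death record), "L" (lost record), or NA (missing cognition).
hand_panel <- function(states, entry_age = 60, entry_year = 2000, h = 2,
                       sex = "female", diabetes = FALSE) {
  rows <- list()
  for (pid in seq_along(states)) {
    st <- states[[pid]]
    for (w in seq_along(st)) {
      if (is.na(st[w])) {
        vital <- "alive"; score <- NA_integer_
      } else if (st[w] == "D") {
        vital <- "dead"; score <- NA_integer_
      } else if (st[w] == "L") {
        vital <- "lost"; score <- NA_integer_
      } else {
        vital <- "alive"
        score <- if (st[w] == "N") 20L else 9L
      }
      rows[[length(rows) + 1L]] <- data.frame(
        person_id = pid, wave = w, year = entry_year + (w - 1) * h,
        age = entry_age + (w - 1) * h, sex = sex, education = "less_hs",
        race = "nh_white", diabetes_ever = diabetes, cog_score = score,
        vital = vital,
        death_year = if (identical(st[w], "D")) entry_year + (w - 1) * h - 1 else NA_real_,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}
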