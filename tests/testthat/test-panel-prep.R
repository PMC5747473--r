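test_that("cognition scores classify at the documented cut points", {
  expect_equal(as.character(classify_cognition(c(11, 7))), c("CIND", "CIND"))
  expect_equal(as.character(classify_cognition(6)), "DEM")
  expect_equal(as.character(classify_cognition(0)), "DEM")
  expect_equal(as.character(classify_cognition(c(12, 27))), c("N", "N"))
  expect_true(is.na(classify_cognition(NA)))
  expect_error(classify_cognition(28), "outside")
  expect_error(classify_cognition(-1), "outside")
  expect_equal(cognition_binary(classify_cognition(c(5, 9, 15, NA))),
               c("I", "I", "N", NA))
})

test_that("classification round-trips the generator's score bands", {
  cfg <- sim_config(n_persons = 500, cognition_missing_prob = 0, seed = 3)
  panel <- simulate_panel(cfg)
  alive <- panel[panel$vital == "alive", ]
  st <- cognition_binary(classify_cognition(alive$cog_score))
  expect_true(all((alive$cog_score >= 12) == (st == "N")))
})

test_that("diabetes diagnoses are carried forward within person", {
  panel <- hand_panel(list(c("N", "N", "N", "N")))
  panel$diabetes_ever <- c(FALSE, TRUE, FALSE, FALSE)
  out <- carry_forward_diabetes(panel)
  expect_equal(out$diabetes_ever, c(FALSE, TRUE, TRUE, TRUE))
  panel$diabetes_ever <- rep(FALSE, 4)
  expect_equal(carry_forward_diabetes(panel)$diabetes_ever, rep(FALSE, 4))
  panel$diabetes_ever <- c(TRUE, FALSE, FALSE, FALSE)
  expect_equal(carry_forward_diabetes(panel)$diabetes_ever, rep(TRUE, 4))
})

test_that("person periods pair consecutive waves with the documented drop rules", {
  pp <- build_person_periods(hand_panel(list(c("N", "I", "D"))))
  expect_equal(nrow(pp), 2)
  expect_equal(as.character(pp$origin_state), c("N", "I"))
  expect_equal(as.character(pp$dest_state), c("I", "D"))
  expect_equal(pp$interval, c(2, 2))

  # missing middle wave kills both adjacent pairs
  pp2 <- build_person_periods(hand_panel(list(c("N", NA, "N"))))
  expect_equal(nrow(pp2), 0)
  expect_equal(attr(pp2, "drop_report")$n_dropped_missing_cognition, 2)

  # death overrides a missing destination score
  pp3 <- build_person_periods(hand_panel(list(c("N", "D"))))
  expect_equal(as.character(pp3$dest_state), "D")

  # censoring produces no period
  pp4 <- build_person_periods(hand_panel(list(c("N", "N", "L"))))
  expect_equal(nrow(pp4), 1)
  expect_equal(attr(pp4, "drop_report")$n_censored_pairs, 1)
})

test_that("the entry filter excludes persons outside the age range", {
  panel <- rbind(hand_panel(list(c("N", "N")), entry_age = 76),
                 hand_panel(list(c("N", "N")), entry_age = 60))
  panel$person_id <- rep(1:2, each = 2)
  pp <- build_person_periods(panel)
  expect_equal(unique(pp$person_id), 2)
  expect_equal(attr(pp, "drop_report")$n_persons_excluded_entry, 1)
  # completed age 74 is still inside
  expect_equal(nrow(build_person_periods(
    hand_panel(list(c("N", "N")), entry_age = 74.9))), 1)
})

test_that("malformed panels are rejected with the person named", {
  panel <- hand_panel(list(c("N", "N")))
  panel$wave <- c(1, 1)
  expect_error(build_person_periods(panel), "person_id 1")
})

test_that("sample summaries reproduce the crude-rate arithmetic", {
  panel <- hand_panel(list(c("N", "N", "N"), c("N", "N", "D")))
  panel$person_id <- rep(1:2, each = 3)
  panel$diabetes_ever[4:6] <- TRUE
  pp <- build_person_periods(panel)
  s <- summarize_sample(panel, pp)
  # person 1: 2 periods x 2y; person 2: one 2y period + one death period
  # credited half the interval
  expect_equal(s$total$person_years, 4 + 2 + 1)
  expect_equal(s$total$n_deaths, 1)
  expect_equal(s$total$crude_death_rate, 1000 * 1 / 7)
  expect_equal(s$diabetes$person_years, 3)
  expect_equal(s$no_diabetes$person_years, 4)
  expect_equal(s$diabetes$n_deaths + s$no_diabetes$n_deaths, s$total$n_deaths)
  expect_equal(crude_death_rate(0, 1000), 0)

  # subgroup person-years and transition counts add to the totals
  cfg <- sim_config(n_persons = 2000, seed = 17)
  big <- carry_forward_diabetes(simulate_panel(cfg))
  bp <- build_person_periods(big)
  sb <- summarize_sample(big, bp)
  expect_equal(sb$diabetes$person_years + sb$no_diabetes$person_years,
               sb$total$person_years)
  expect_equal(sum(sb$total$transitions), nrow(bp))
  # person-years invariant under row permutation
  set.seed(1)
  shuf <- big[sample(nrow(big)), ]
  expect_equal(summarize_sample(shuf, build_person_periods(shuf))$total$person_years,
               sb$total$person_years)
})

test_that("age-specific prevalence reflects the classified scores", {
  panel <- hand_panel(list(c("I", "I"), c("N", "I")), entry_age = 60)
  panel$person_id <- rep(1:2, each = 2)
  pv <- prevalence_by_age(panel)
  cell <- pv[pv$sex == "female" & !pv$diabetes & pv$age_group == "[60,65)", ]
  expect_equal(cell$n_interviews, 4)       # ages 60 and 62 for both persons
  expect_equal(cell$prevalence, 75)        # impaired scores: 9, 9, 9 of 4
  # empty cells are NA, not zero
  expect_true(all(is.na(pv$prevalence[pv$n_interviews == 0])))
  expect_true(any(pv$n_interviews == 0))
})
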