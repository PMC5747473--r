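test_that("chains are built from surfaces with closure at omega", {
  surf <- constant_surface(c(0.8, 0.1, 0.1), c(0.05, 0.8, 0.15))
  ch <- build_chain(surf, h = 2, omega = 110, start_age = 50)
  expect_equal(ch$ages, seq(50, 108, by = 2))
  expect_equal(unname(ch$P[5, "N", ]), c(0.8, 0.1, 0.1))
  expect_equal(unname(ch$P[12, "I", ]), c(0.05, 0.8, 0.15))

  # one-step horizon: everyone is dead after a single interval
  ch1 <- build_chain(surf, h = 2, omega = 52, start_age = 50)
  lt <- state_expectancies(ch1)
  expect_equal(lt$LE_total, 2)

  # missing coverage is reported
  expect_error(build_chain(surf, h = 2, omega = 120), "112")
})

test_that("constant single-exit chains match the geometric closed form", {
  # annual death probability 0.1, no impairment: LE = sum 0.9^k = 10
  ch <- geometric_chain(q = 0.1, b = 0)
  lt <- state_expectancies(ch)
  expect_equal(lt$LE_total, 10, tolerance = 1e-9)
  expect_equal(lt$LE_N, 10, tolerance = 1e-9)
  expect_equal(lt$LE_I, 0)
})

test_that("LE components always add to the total and are conserved", {
  for (s in 1:20) {
    ch <- random_chain(s)
    init <- c(0.7, 0.3)
    lt <- state_expectancies(ch, init = init)
    expect_equal(lt$LE_N + lt$LE_I, lt$LE_total, tolerance = 1e-9)
    expect_gte(lt$LE_N, 0)
    expect_lte(lt$LE_total, ch$omega - ch$start_age + 1e-9)
    # conservation: transient + cumulative dead mass stays 1
    z <- init; dead <- 0
    for (i in seq_along(ch$ages)) {
      dead <- dead + sum(z * ch$P[i, , "D"])
      z <- c(sum(z * ch$P[i, , "N"]), sum(z * ch$P[i, , "I"]))
      expect_equal(sum(z) + dead, 1, tolerance = 1e-12)
    }
  }
})

test_that("forward iteration and the fundamental matrix agree on random chains", {
  # state_expectancies computes both routes and stops if they disagree
  # beyond 1e-8; exercise it across many random chains and both conventions
  for (s in 1:100) {
    ch <- random_chain(s, n_ages = sample(2:25, 1))
    expect_s3_class(state_expectancies(ch), "lifetable_result")
    expect_s3_class(state_expectancies(ch, init = c(0.4, 0.6),
                                       half_final = TRUE),
                    "lifetable_result")
  }
})

test_that("raising death probabilities never raises life expectancy", {
  for (s in 1:10) {
    ch <- random_chain(s + 200)
    le0 <- state_expectancies(ch)$LE_total
    lam <- 0.2
    ch2 <- ch
    for (org in c("N", "I")) {
      alive <- ch$P[, org, c("N", "I")]
      ch2$P[, org, c("N", "I")] <- (1 - lam) * alive
      ch2$P[, org, "D"] <- ch$P[, org, "D"] + lam * rowSums(alive)
    }
    expect_lte(state_expectancies(ch2)$LE_total, le0 + 1e-12)
  }
})

test_that("symmetric states swap expectancies when the start state swaps", {
  ages <- seq(50, 108, by = 2)
  pswap <- c(0.6, 0.3, 0.1)
  surf <- probability_surface(
    ages,
    P_N = matrix(pswap, length(ages), 3, byrow = TRUE),
    P_I = matrix(pswap[c(2, 1, 3)], length(ages), 3, byrow = TRUE)
  )
  ch <- build_chain(surf)
  a <- state_expectancies(ch, init = c(1, 0))
  b <- state_expectancies(ch, init = c(0, 1))
  expect_equal(a$LE_N, b$LE_I, tolerance = 1e-9)
  expect_equal(a$LE_I, b$LE_N, tolerance = 1e-9)
  expect_error(state_expectancies(ch, init = c(0.5, 0.4)), "distribution")
})

test_that("onset distribution matches competing-risk closed forms", {
  # constant annual b = q = 0.1: stay prob 0.8, Pr(onset first) = b/(b+q)
  ch <- geometric_chain(q = 0.1, b = 0.1)
  on <- onset_distribution(ch)
  expect_equal(on$pr_ever, 0.5, tolerance = 1e-9)
  # mean steps before onset given onset = s/(1-s) = 4; midpoint dating
  # puts the conditional mean onset age at 50 + 4 + 0.5
  expect_equal(on$mean_onset_age, 54.5, tolerance = 1e-8)

  # brute-force series oracle for an asymmetric case
  b <- 0.07; q <- 0.12; s <- 1 - b - q
  k <- 0:599
  asym <- onset_distribution(geometric_chain(q = q, b = b))
  expect_equal(asym$pr_ever, sum(s^k * b), tolerance = 1e-9)
  expect_equal(asym$mean_onset_age,
               sum((50 + k + 0.5) * s^k * b) / sum(s^k * b), tolerance = 1e-8)

  # no impairment hazard: onset never happens, mean undefined
  on0 <- onset_distribution(geometric_chain(q = 0.1, b = 0))
  expect_equal(on0$pr_ever, 0)
  expect_true(is.na(on0$mean_onset_age))

  # start/end conventions bracket the midpoint
  on_s <- onset_distribution(ch, onset_label = "start")
  on_e <- onset_distribution(ch, onset_label = "end")
  expect_equal(on_s$mean_onset_age + 0.5, on$mean_onset_age)
  expect_equal(on_e$mean_onset_age - 0.5, on$mean_onset_age)
})

test_that("the microsimulation oracle agrees with the matrix results", {
  ch <- geometric_chain(q = 0.1, b = 0, horizon = 300)
  ms <- microsim_oracle(ch, n_agents = 40000, seed = 2)
  expect_lt(abs(ms$lifetable$LE_total - 10), 3 * ms$lifetable$se_total)

  ch2 <- random_chain(77)
  lt <- state_expectancies(ch2, init = c(0.8, 0.2))
  on <- onset_distribution(ch2)
  ms2 <- microsim_oracle(ch2, n_agents = 60000, init = c(0.8, 0.2), seed = 3)
  expect_lt(abs(ms2$lifetable$LE_total - lt$LE_total), 3 * ms2$lifetable$se_total)
  expect_lt(abs(ms2$lifetable$LE_N - lt$LE_N), 3 * ms2$lifetable$se_N)
  expect_lt(abs(ms2$lifetable$LE_I - lt$LE_I), 3 * ms2$lifetable$se_I)
  expect_lt(abs(ms2$onset$pr_ever - on$pr_ever), 3 * ms2$onset$se_pr)
  expect_lt(abs(ms2$onset$mean_onset_age - on$mean_onset_age),
            3 * ms2$onset$se_mean)

  # single agent: one legal path, reproducible
  one <- microsim_oracle(ch2, 1, seed = 9)
  expect_identical(one, microsim_oracle(ch2, 1, seed = 9))
  expect_gte(one$lifetable$LE_total, 0)
})
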