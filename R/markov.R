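#' Build an age-by-state Markov chain from a probability surface
#'
#' Assembles the discrete-time matrix population model: one 2x3 transition
#' matrix (rows `N`, `I`; columns `N`, `I`, `D`) per age on the grid
#' `start_age, start_age + h, ..., omega - h`. The chain is closed at
#' `omega`: mass still alive at `omega` is absorbed into death.
#'
#' @param surface a [probability_surface()] covering the grid ages.
#' @param h step length in years (default 2, the interview interval).
#' @param omega closure age (default 110).
#' @param start_age first age of the chain (default 50).
#' @return object of class `markov_chain` with components `ages`, `h`,
#'   `omega`, `start_age` and `P` (array `n_ages x 2 x 3`).
#' @export
build_chain <- function(surface, h = 2, omega = 110, start_age = 50) {
  grid <- seq(start_age, omega - h, by = h)
  idx <- match(grid, surface$ages)
  if (anyNA(idx)) {
    stop("surface does not cover ages: ",
         paste(grid[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  P <- array(NA_real_, dim = c(length(grid), 2, 3),
             dimnames = list(NULL, ORIGIN_STATES, DEST_STATES))
  P[, "N", ] <- surface$P_N[idx, , drop = FALSE]
  P[, "I", ] <- surface$P_I[idx, , drop = FALSE]
  structure(
    list(ages = grid, h = h, omega = omega, start_age = start_age, P = P,
         provenance = surface$provenance),
    class = "markov_chain"
  )
}

#' @export
print.markov_chain <- function(x, ...) {
  cat(sprintf("Markov chain: ages %g-%g by %g, closure at %g\n",
              min(x$ages), max(x$ages), x$h, x$omega))
  invisible(x)
}

chain_start_index <- function(chain, start_age) {
  i0 <- match(start_age, chain$ages)
  if (is.na(i0)) stop("start_age not on the chain's age grid", call. = FALSE)
  i0
}

#' State-specific life expectancies from a Markov chain
#'
#' Computes total life expectancy and the expected years lived in the
#' cognitively non-impaired (`N`) and impaired (`I`) states from
#' `start_age`, for a cohort with initial state distribution `init`.
#' Occupancy convention: a person in state `s` at the start of an
#' interval contributes the full step `h` to `LE_s` (unit-reward discrete
#' Markov chain; see the `half_final` switch for the alternative).
#'
#' Two independent routes are computed and required to agree: forward
#' iteration of the state-occupancy vector, and the fundamental matrix
#' `(I - U)^(-1)` of the stacked age-by-state transient block.
#'
#' @param chain a [build_chain()] result.
#' @param init length-2 initial distribution over `(N, I)`; must sum to 1.
#' @param start_age starting age (default: first chain age).
#' @param half_final if `TRUE`, each interval contributes `h/2` for mass
#'   that dies during it (half-interval convention) instead of the default
#'   full-step occupancy.
#' @return object of class `lifetable_result` with `LE_total`, `LE_N`,
#'   `LE_I`, `start_age` and `init`.
#' @export
state_expectancies <- function(chain, init = c(N = 1, I = 0),
                               start_age = chain$start_age,
                               half_final = FALSE) {
  if (abs(sum(init) - 1) > 1e-9 || any(init < 0)) {
    stop("init must be a distribution over (N, I)", call. = FALSE)
  }
  i0 <- chain_start_index(chain, start_age)
  idx <- i0:length(chain$ages)

  # route 1: forward iteration of occupancy
  z <- as.numeric(init)
  occ <- c(0, 0)
  for (i in idx) {
    contrib <- z
    if (half_final) {
      pdie <- chain$P[i, , "D"]
      contrib <- z * (1 - pdie / 2)
    }
    occ <- occ + contrib
    z <- c(sum(z * chain$P[i, , "N"]), sum(z * chain$P[i, , "I"]))
  }
  le_iter <- chain$h * occ

  # route 2: fundamental matrix on the transient block
  n <- length(idx)
  U <- matrix(0, 2 * n, 2 * n)
  if (n > 1) {
    for (k in seq_len(n - 1)) {
      i <- idx[k]
      r <- (k - 1) * 2
      U[r + 1, r + 3] <- chain$P[i, "N", "N"]
      U[r + 1, r + 4] <- chain$P[i, "N", "I"]
      U[r + 2, r + 3] <- chain$P[i, "I", "N"]
      U[r + 2, r + 4] <- chain$P[i, "I", "I"]
    }
  }
  Nf <- solve(diag(2 * n) - U)
  visits <- as.numeric(c(init, rep(0, 2 * (n - 1))) %*% Nf)
  vis_N <- visits[seq(1, 2 * n, by = 2)]
  vis_I <- visits[seq(2, 2 * n, by = 2)]
  if (half_final) {
    pdN <- chain$P[idx, "N", "D"]
    pdI <- chain$P[idx, "I", "D"]
    le_fund <- chain$h * c(sum(vis_N * (1 - pdN / 2)), sum(vis_I * (1 - pdI / 2)))
  } else {
    le_fund <- chain$h * c(sum(vis_N), sum(vis_I))
  }

  if (max(abs(le_iter - le_fund)) > 1e-8) {
    stop("internal inconsistency: iteration and fundamental-matrix life expectancies disagree",
         call. = FALSE)
  }
  structure(
    list(LE_total = sum(le_iter), LE_N = le_iter[1], LE_I = le_iter[2],
         start_age = start_age, init = setNames(as.numeric(init), ORIGIN_STATES)),
    class = "lifetable_result"
  )
}

#' @export
print.lifetable_result <- function(x, ...) {
  cat(sprintf("Life expectancy at age %g: total %.2f (non-impaired %.2f, impaired %.2f)\n",
              x$start_age, x$LE_total, x$LE_N, x$LE_I))
  invisible(x)
}

#' Age-at-first-onset distribution of cognitive impairment
#'
#' First-passage analysis for a cohort starting cognitively non-impaired
#' at `start_age`: the impaired state is made absorbing (alongside death),
#' so the probability of first onset during `[a, a + h)` is
#' `g(a) = z_N(a) * p_NI(a)` with `z_N` the probability of having remained
#' continuously non-impaired. Reports the probability of ever becoming
#' impaired and the mean age at first onset conditional on onset. Onset
#' during an interval is dated at the interval midpoint by default
#' (unbiased under uniform within-interval onset).
#'
#' @param chain a [build_chain()] result.
#' @param start_age starting age (default: first chain age).
#' @param onset_label `"midpoint"`, `"start"` or `"end"` of the onset
#'   interval.
#' @return object of class `onset_result` with `interval_start` (ages `a`),
#'   `g` (onset mass per interval), `pr_ever` and `mean_onset_age` (`NA`
#'   when onset is impossible).
#' @export
onset_distribution <- function(chain, start_age = chain$start_age,
                               onset_label = c("midpoint", "start", "end")) {
  onset_label <- match.arg(onset_label)
  i0 <- chain_start_index(chain, start_age)
  idx <- i0:length(chain$ages)
  zN <- 1
  g <- numeric(length(idx))
  for (k in seq_along(idx)) {
    i <- idx[k]
    g[k] <- zN * chain$P[i, "N", "I"]
    zN <- zN * chain$P[i, "N", "N"]
  }
  a <- chain$ages[idx]
  label <- switch(onset_label,
                  midpoint = a + chain$h / 2,
                  start = a,
                  end = a + chain$h)
  pr <- sum(g)
  structure(
    list(interval_start = a, g = g, pr_ever = pr,
         mean_onset_age = if (pr > 0) sum(label * g) / pr else NA_real_,
         onset_label = onset_label, start_age = start_age),
    class = "onset_result"
  )
}

#' @export
print.onset_result <- function(x, ...) {
  cat(sprintf("First onset of impairment from age %g: Pr(ever) = %.3f, mean onset age = %s\n",
              x$start_age, x$pr_ever,
              if (is.na(x$mean_onset_age)) "undefined" else sprintf("%.2f", x$mean_onset_age)))
  invisible(x)
}

#' Microsimulation oracle for the matrix population model
#'
#' Agent-based simulation through a Markov chain, using the same occupancy
#' and onset conventions as [state_expectancies()] and
#' [onset_distribution()]. Serves as an independent stochastic check on
#' the matrix results; reports Monte-Carlo standard errors.
#'
#' @param chain a [build_chain()] result.
#' @param n_agents number of simulated individuals.
#' @param init length-2 initial distribution over `(N, I)`.
#' @param start_age starting age (default: first chain age).
#' @param seed integer seed.
#' @return list with `lifetable` (`LE_total`, `LE_N`, `LE_I` and their
#'   standard errors) and `onset` (`pr_ever`, `mean_onset_age`, standard
#'   errors; onset tracked for agents starting in `N`).
#' @export
microsim_oracle <- function(chain, n_agents, init = c(N = 1, I = 0),
                            start_age = chain$start_age, seed = 1L) {
  stopifnot(n_agents >= 1)
  if (abs(sum(init) - 1) > 1e-9) stop("init must sum to 1", call. = FALSE)
  with_seed(seed, {
    i0 <- chain_start_index(chain, start_age)
    idx <- i0:length(chain$ages)
    state <- 1L + (runif(n_agents) >= init[1])   # 1 = N, 2 = I, 3 = dead
    started_N <- state == 1L
    yrs <- matrix(0, n_agents, 2)
    onset_age <- rep(NA_real_, n_agents)
    for (i in idx) {
      alive <- state < 3L
      if (!any(alive)) break
      yrs[cbind(which(alive), state[alive])] <-
        yrs[cbind(which(alive), state[alive])] + chain$h
      cur <- state    # snapshot: both states transition simultaneously
      for (s in 1:2) {
        sel <- which(cur == s)
        if (!length(sel)) next
        dest <- sample_rows(matrix(chain$P[i, s, ], length(sel), 3,
                                   byrow = TRUE))
        if (s == 1L) {
          new_onset <- sel[dest == 2L & is.na(onset_age[sel])]
          onset_age[new_onset] <- chain$ages[i] + chain$h / 2
        }
        state[sel] <- dest
      }
    }
    total <- rowSums(yrs)
    onset_N <- onset_age[started_N]
    n_on <- sum(!is.na(onset_N))
    list(
      lifetable = list(
        LE_total = mean(total), LE_N = mean(yrs[, 1]), LE_I = mean(yrs[, 2]),
        se_total = sd(total) / sqrt(n_agents),
        se_N = sd(yrs[, 1]) / sqrt(n_agents),
        se_I = sd(yrs[, 2]) / sqrt(n_agents)
      ),
      onset = list(
        pr_ever = mean(!is.na(onset_N)),
        mean_onset_age = if (n_on > 0) mean(onset_N, na.rm = TRUE) else NA_real_,
        se_pr = sd(!is.na(onset_N)) / sqrt(sum(started_N)),
        se_mean = if (n_on > 1) sd(onset_N, na.rm = TRUE) / sqrt(n_on) else NA_real_
      ),
      n_agents = n_agents
    )
  })
}
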