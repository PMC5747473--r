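#' Cluster bootstrap over persons
#'
#' Nonparametric bootstrap for panel estimators: persons (clusters) are
#' resampled with replacement, each sampled person carrying all of their
#' waves, and the full estimation pipeline is rerun on every replicate.
#' Resampling whole persons preserves the within-person dependence of the
#' repeated observations. Confidence intervals are percentile intervals
#' of the replicate distribution. Replicates whose pipeline fails (e.g.
#' a non-converged fit) are dropped and counted; more than `max_fail`
#' failures is an error.
#'
#' @param panel long-format panel.
#' @param statistic function `panel -> named numeric vector` running the
#'   pipeline and returning the estimands.
#' @param B number of bootstrap replications (default 1000).
#' @param seed master seed; each replicate draws from a seed derived from
#'   `(seed, replicate index)` so results do not depend on execution
#'   order.
#' @param level confidence level (default 0.95).
#' @param max_fail maximum tolerated fraction of failed replicates.
#' @return object of class `bootstrap_result`: `point` (statistic on the
#'   original panel), `replicates` (B x q matrix), `ci` (2 x q), `B`,
#'   `n_failed`, `seed`.
#' @export
cluster_bootstrap <- function(panel, statistic, B = 1000, seed = 1L,
                              level = 0.95, max_fail = 0.1) {
  stopifnot(B >= 1)
  point <- statistic(panel)
  ids <- unique(panel$person_id)
  rows_by_person <- split(seq_len(nrow(panel)), match(panel$person_id, ids))

  reps <- matrix(NA_real_, B, length(point),
                 dimnames = list(NULL, names(point)))
  n_failed <- 0L
  for (b in seq_len(B)) {
    take <- with_seed(derive_seed(seed, b),
                      sample.int(length(ids), replace = TRUE))
    rows <- rows_by_person[take]
    res <- panel[unlist(rows), , drop = FALSE]
    # relabel so duplicated draws of one person stay distinct clusters
    res$person_id <- rep(seq_along(take), lengths(rows))
    val <- tryCatch(statistic(res), error = function(e) NULL)
    if (is.null(val) || anyNA(val)) {
      n_failed <- n_failed + 1L
    } else {
      reps[b, ] <- val
    }
  }
  if (n_failed > max_fail * B) {
    stop(sprintf(
      "%d of %d bootstrap replicates failed; consider collapsing sparse categories or a ridge penalty",
      n_failed, B), call. = FALSE)
  }
  alpha <- (1 - level) / 2
  ok <- reps[!apply(reps, 1, anyNA), , drop = FALSE]
  ci <- apply(ok, 2, quantile, probs = c(alpha, 1 - alpha), names = FALSE)
  rownames(ci) <- c("lower", "upper")
  structure(
    list(point = point, replicates = reps, ci = ci, B = B,
         n_failed = n_failed, level = level, seed = seed),
    class = "bootstrap_result"
  )
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("Cluster bootstrap: B = %d (%d failed), %g%% percentile intervals\n",
              x$B, x$n_failed, 100 * x$level))
  df <- data.frame(estimate = x$point,
                   lower = x$ci["lower", ], upper = x$ci["upper", ])
  print(round(df, 3))
  invisible(x)
}
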