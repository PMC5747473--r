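# Shared factor levels and covariate layout. Every design matrix in the
# package uses this column order; changing it is an API break.

SEX_LEVELS <- c("male", "female")
EDU_LEVELS <- c("less_hs", "hs_some_college", "college")
RACE_LEVELS <- c("nh_white", "nh_black", "hispanic", "other")
ORIGIN_STATES <- c("N", "I")
DEST_STATES <- c("N", "I", "D")
VITAL_LEVELS <- c("alive", "dead", "lost")

COVARIATE_NAMES <- c(
  "(Intercept)", "age", "age2",
  "edu_hs_some_college", "edu_college",
  "race_nh_black", "race_hispanic", "race_other",
  "diabetes"
)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_cfg <- function(field, msg) {
  stop(sprintf("invalid configuration field '%s': %s", field, msg), call. = FALSE)
}

check_prob <- function(x, field, len = NULL) {
  if (!is.numeric(x) || anyNA(x)) stop_cfg(field, "must be numeric and non-missing")
  if (!is.null(len) && length(x) != len) {
    stop_cfg(field, sprintf("must have length %d", len))
  }
  if (any(x < 0 | x > 1)) stop_cfg(field, "probabilities must lie in [0, 1]")
  invisible(x)
}

check_simplex <- function(x, field, len, tol = 1e-12) {
  check_prob(x, field, len)
  if (abs(sum(x) - 1) > tol) stop_cfg(field, "must sum to 1")
  invisible(x)
}

# Deterministic child seed for replicate streams; stays inside 32-bit range.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 69069 + index * 1013) %% 2147483587L)
}

# Run `expr` under a local RNG state seeded with `seed`, restoring the
# caller's stream afterwards.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# Vectorised categorical draw: one draw per row of the row-stochastic
# probability matrix `p`, returning column indices.
sample_rows <- function(p) {
  u <- runif(nrow(p))
  idx <- rep(1L, nrow(p))
  acc <- p[, 1L]
  for (j in seq_len(ncol(p) - 1L)) {
    idx <- idx + (u > acc)
    acc <- acc + p[, j + 1L]
  }
  idx
}
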