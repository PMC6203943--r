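# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so library code never perturbs the
# user's stream.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single non-missing number", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

# Truncated-normal sampler on [lo, hi] by inverse-CDF; vectorised, exact.
rtruncnorm <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(plo + stats::runif(n) * (phi - plo), mean, sd)
}

# Mean of a normal truncated to [lo, hi] (used by tests as an oracle too).
truncnorm_mean <- function(mean, sd, lo, hi) {
  a <- (lo - mean) / sd
  b <- (hi - mean) / sd
  mean + sd * (stats::dnorm(a) - stats::dnorm(b)) /
    (stats::pnorm(b) - stats::pnorm(a))
}

required_logbook_fields <- c(
  "set_id", "year", "month", "day", "vessel_id", "fleet", "observer",
  "latitude", "longitude", "hooks", "count_blue", "count_mako",
  "weight_blue", "weight_mako", "weight_other", "target"
)

assert_logbook <- function(records) {
  if (!is.data.frame(records)) {
    stop("`records` must be a data.frame of logbook sets", call. = FALSE)
  }
  missing_cols <- setdiff(required_logbook_fields, names(records))
  if (length(missing_cols)) {
    stop_config("logbook table is missing columns: %s",
                paste(missing_cols, collapse = ", "))
  }
  invisible(records)
}
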