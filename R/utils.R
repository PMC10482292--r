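# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG seed, restoring the global RNG state
# afterwards so callers' random streams are not perturbed. `seed = NULL`
# leaves the ambient stream untouched (used when a caller already seeded).
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
      stop("`seed` must be a single finite number or NULL", call. = FALSE)
    }
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
              add = TRUE)
    }
    set.seed(as.integer(seed))
  }
  force(code)
}

# Truncated-normal draws by inverse-CDF sampling; exact for any bounds and
# degenerate when sd = 0 (point mass clamped into [lower, upper]).
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  stopifnot(length(mean) == 1L, length(sd) == 1L, sd >= 0, lower < upper)
  if (sd == 0) {
    return(rep(min(max(mean, lower), upper), n))
  }
  p_lo <- pnorm(lower, mean, sd)
  p_hi <- pnorm(upper, mean, sd)
  x <- qnorm(runif(n, p_lo, p_hi), mean, sd)
  pmin(pmax(x, lower), upper)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == floor(x)
}

is_prob <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x <= 1
}

assert_columns <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop(sprintf("%s is missing required column(s): %s; available: %s",
                 what, paste(missing, collapse = ", "),
                 paste(names(df), collapse = ", ")),
         call. = FALSE)
  }
  invisible(df)
}
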