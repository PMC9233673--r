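# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

#' @importFrom stats model.matrix qnorm quantile rnorm rpois runif setNames
#' @importFrom utils read.csv write.csv
NULL

# Deterministic per-table sub-seed derived from a master seed, so that adding a
# table to the generator does not shift the draws of existing tables.
# Result is always a valid 32-bit seed.
substream_seed <- function(seed, name) {
  chars <- utf8ToInt(name)
  h <- sum(chars * seq_along(chars)) %% 1000003L
  (as.integer(seed) %% 2045839L) * 1009L + h * 97L
}

# Evaluate `expr` under `seed` without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# sample() that never deparses a length-1 x into 1:x.
resample <- function(x, size) x[sample.int(length(x), size)]

# Percentage as displayed in report tables: count/total * 100, one decimal.
pct <- function(n, total) round(100 * n / total, 1)

# "YYYY-MM" key used for month-specific reporting completeness.
month_key <- function(date) format(date, "%Y-%m")

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
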