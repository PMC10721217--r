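#' @keywords internal
"_PACKAGE"

#' @importFrom stats rbinom rbeta rpois runif rnorm sd pnorm qbeta optimize aggregate
#' @importFrom utils read.csv write.csv read.delim write.table packageVersion
NULL

# Argument checking ----------------------------------------------------------

stop_domain <- function(param, msg) {
  stop(sprintf("invalid `%s`: %s", param, msg), call. = FALSE)
}

check_probability <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0 || x > 1) {
    stop_domain(name, "must be a single finite number in [0, 1]")
  }
  invisible(x)
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop_domain(name, "must be a single finite positive number")
  }
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x < min || x != round(x)) {
    stop_domain(name, sprintf("must be a single integer >= %d", min))
  }
  invisible(as.integer(x))
}

# Seeded evaluation ----------------------------------------------------------

# Evaluate `expr` under `set.seed(seed)` while leaving the caller's RNG
# state untouched. All stochastic entry points funnel through this so that
# identical (spec, seed) pairs are bit-identical regardless of ambient state.
with_seed <- function(seed, expr) {
  check_count(seed, "seed", min = 0L)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Derive independent-stream child seeds from one root seed. Keeps results
# in [0, 2^31 - 2] so they remain valid R integer seeds.
derive_seeds <- function(seed, n) {
  check_count(seed, "seed", min = 0L)
  check_count(n, "n", min = 1L)
  (as.double(seed) * 1000003 + 7919 * seq_len(n)) %% 2147483647
}

# Formatting ------------------------------------------------------------------

# Round half away from zero, matching how the source tables print values
# (base round() uses banker's rounding).
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
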