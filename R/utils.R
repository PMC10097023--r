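#' @keywords internal
"_PACKAGE"

# Run `expr` under `seed` and restore the caller's RNG state afterwards, so
# generators are reproducible without clobbering an outer simulation stream.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
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
  set.seed(as.integer(seed))
  force(expr)
}

# Derive a stage seed from a global seed; double arithmetic (exact below
# 2^53) keeps the result inside the 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 97 + as.numeric(offset)) %% 2147483587)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    stopf("`%s` must be a single integer >= %s", name, min)
  }
  invisible(as.integer(x))
}

assert_fraction <- function(x, name, lo = 0, hi = 1, lo_open = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    (if (lo_open) x > lo else x >= lo) && x <= hi
  if (!ok) stopf("`%s` must be a number in %s%s, %s]", name,
                 if (lo_open) "(" else "[", lo, hi)
  invisible(as.numeric(x))
}

# Two-sided p-value for a Pearson correlation via the asymptotic t statistic.
cor_pvalue <- function(r, n) {
  if (n <= 2) return(rep(NA_real_, length(r)))
  r <- pmin(pmax(r, -1), 1)
  t <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  2 * stats::pt(-abs(t), df = n - 2)
}
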