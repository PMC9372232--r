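# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  expr
}

# Derive `n` independent sub-seeds from one master seed (kept below 2^31).
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

stop_polyhaz <- function(...) stop(..., call. = FALSE)

assert_prob <- function(x, name, open = FALSE) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    stop_polyhaz(sprintf("'%s' must be finite numeric", name))
  }
  lo_ok <- if (open) all(x > 0) else all(x >= 0)
  hi_ok <- if (open) all(x < 1) else all(x <= 1)
  if (!lo_ok || !hi_ok) {
    stop_polyhaz(sprintf("'%s' must lie in %s", name,
                         if (open) "(0, 1)" else "[0, 1]"))
  }
  invisible(x)
}

assert_count <- function(x, name, positive = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x) ||
      (positive && x < 1) || (!positive && x < 0)) {
    stop_polyhaz(sprintf("'%s' must be a single %s integer", name,
                         if (positive) "positive" else "non-negative"))
  }
  invisible(as.integer(x))
}

# Type-1 (inverse empirical CDF) quantile: smallest observed value with at
# least `p` of the sample at or below it.  No interpolation, so band counts
# are exact for distinct scores.
quantile_type1 <- function(x, p) {
  unname(quantile(x, probs = p, type = 1, names = FALSE))
}

#' Format a p-value with truncation at 1e-16
#'
#' P-values below `1e-16` are reported as the string `"<1e-16"`; larger
#' values are printed with three significant digits. Used for all reported
#' association p-values.
#'
#' @param p numeric vector of p-values.
#' @return character vector.
#' @export
#' @examples
#' format_pvalue(c(0.04, 1e-30))
format_pvalue <- function(p) {
  ifelse(p < 1e-16, "<1e-16", formatC(p, format = "g", digits = 3))
}

# Numeric floor used wherever a p-value is stored rather than printed.
truncate_pvalue <- function(p) pmax(p, 1e-16)
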