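# Genetic-risk-adjusted cumulative incidence curves: a population
# age-specific incidence table is split into clinically significant and
# non-significant components and multiplied by the mean percentile hazard
# ratios.  The direct product follows the rare-disease approximation used
# in the source methodology; an exact hazard-scaled alternative
# (1 - (1 - F)^HR) is also provided for comparison.

incidence_age_grid <- 40:70

#' Load and validate a population incidence table
#'
#' Reads a CSV with columns `age` and `cumulative_incidence`, checks
#' monotonicity (naming the first offending age otherwise) and coverage of
#' ages 40–70, and linearly interpolates onto the integer age grid.
#'
#' @param path CSV file path (or a data.frame with the same columns).
#' @return data.frame with `age` (40:70) and `cumulative_incidence`.
#' @export
load_incidence <- function(path) {
  df <- if (is.data.frame(path)) path else
    read.table(path, header = TRUE, sep = ",", stringsAsFactors = FALSE)
  need <- c("age", "cumulative_incidence")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop_polyhaz("incidence table missing columns: ",
                 paste(miss, collapse = ", "))
  }
  df <- df[order(df$age), ]
  y <- df$cumulative_incidence
  assert_prob(y, "cumulative_incidence")
  bad <- which(diff(y) < 0)
  if (length(bad)) {
    stop_polyhaz("non-monotone incidence at age ", df$age[bad[1L] + 1L])
  }
  if (min(df$age) > 40 || max(df$age) < 70) {
    stop_polyhaz("incidence table must cover ages 40-70")
  }
  out <- approx(df$age, y, xout = incidence_age_grid, method = "linear")
  data.frame(age = incidence_age_grid, cumulative_incidence = out$y)
}

#' Split a baseline incidence curve by clinical significance
#'
#' Given the age-specific fraction of incident cancers that are clinically
#' significant, returns `significant = fraction * baseline` and
#' `nonsignificant = (1 - fraction) * baseline`, re-checking both results
#' for monotonicity (an incompatible fraction schedule is an error).
#'
#' @param baseline data.frame from [load_incidence()].
#' @param fraction either a data.frame with columns `age` and
#'   `significant_fraction` (interpolated onto the grid) or a numeric
#'   vector/scalar of fractions in \[0, 1\].
#' @return data.frame with `age`, `significant`, `nonsignificant`.
#' @export
split_by_significance <- function(baseline, fraction) {
  ages <- baseline$age
  if (is.data.frame(fraction)) {
    need <- c("age", "significant_fraction")
    miss <- setdiff(need, names(fraction))
    if (length(miss)) {
      stop_polyhaz("fraction table missing columns: ",
                   paste(miss, collapse = ", "))
    }
    fr <- approx(fraction$age, fraction$significant_fraction, xout = ages,
                 method = "linear", rule = 2)$y
  } else {
    fr <- rep(fraction, length.out = length(ages))
  }
  assert_prob(fr, "significant_fraction")
  sig <- fr * baseline$cumulative_incidence
  nonsig <- (1 - fr) * baseline$cumulative_incidence
  for (nm in list(list(sig, "significant"), list(nonsig, "nonsignificant"))) {
    bad <- which(diff(nm[[1L]]) < -1e-12)
    if (length(bad)) {
      stop_polyhaz("fraction schedule produces a non-monotone ",
                   nm[[2L]], " curve at age ", ages[bad[1L] + 1L])
    }
  }
  data.frame(age = ages, significant = sig, nonsignificant = nonsig)
}

#' Risk-adjust an incidence curve by a hazard ratio
#'
#' `risk_adjust()` multiplies the cumulative incidence pointwise by the
#' mean hazard ratio, clipping at 1 with a warning (the direct product is
#' the source methodology's rare-disease approximation).
#' `risk_adjust_exact()` applies the exact proportional-hazards
#' transformation `1 - (1 - F)^HR`, which needs no clipping.
#'
#' @param curve numeric vector of cumulative incidence values in \[0, 1\].
#' @param hr positive hazard ratio (typically the mean HR80/50 or HR95/50).
#' @return adjusted curve, same length.
#' @export
risk_adjust <- function(curve, hr) {
  if (!is.numeric(hr) || length(hr) != 1L || !is.finite(hr) || hr <= 0) {
    stop_polyhaz("hr must be a single positive number")
  }
  assert_prob(curve, "curve")
  out <- curve * hr
  if (any(out > 1)) {
    warning(sprintf("risk-adjusted incidence clipped at 1.0 for %d age(s)",
                    sum(out > 1)), call. = FALSE)
    out <- pmin(out, 1)
  }
  out
}

#' @rdname risk_adjust
#' @export
risk_adjust_exact <- function(curve, hr) {
  if (!is.numeric(hr) || length(hr) != 1L || !is.finite(hr) || hr <= 0) {
    stop_polyhaz("hr must be a single positive number")
  }
  assert_prob(curve, "curve")
  1 - (1 - curve)^hr
}

#' Build the full set of genetic-risk-adjusted incidence curves
#'
#' Combines a baseline population curve, a significance split, and the mean
#' HR80/50 / HR95/50 from the evaluated endpoint-specific hazard-ratio
#' reports into adjusted curves for the top 20% and top 5% of genetic risk,
#' for clinically significant and non-significant disease.
#'
#' @param baseline data.frame from [load_incidence()].
#' @param fraction significance fraction (see [split_by_significance()]).
#' @param hr_significant named vector with `hr_80_50` and `hr_95_50` for
#'   the clinically significant endpoint (e.g. `hr_report(...)$hr`).
#' @param hr_nonsignificant same two entries for non-significant disease
#'   (defaults to the significant ones if omitted).
#' @return an `incidence_curve_set` data.frame: age, baseline curves, and
#'   one column per band x significance combination, with the HRs used in
#'   the `hr_used` attribute. Invariants (monotone curves in \[0, 1\],
#'   significant + nonsignificant = baseline) are asserted on construction.
#' @export
incidence_curve_set <- function(baseline, fraction, hr_significant,
                                hr_nonsignificant = hr_significant) {
  split <- split_by_significance(baseline, fraction)
  need <- c("hr_80_50", "hr_95_50")
  for (h in list(hr_significant, hr_nonsignificant)) {
    if (!all(need %in% names(h))) {
      stop_polyhaz("HR input must contain hr_80_50 and hr_95_50")
    }
  }
  out <- data.frame(
    age = baseline$age,
    baseline_any = baseline$cumulative_incidence,
    baseline_significant = split$significant,
    baseline_nonsignificant = split$nonsignificant,
    top20_significant = risk_adjust(split$significant,
                                    hr_significant[["hr_80_50"]]),
    top5_significant = risk_adjust(split$significant,
                                   hr_significant[["hr_95_50"]]),
    top20_nonsignificant = risk_adjust(split$nonsignificant,
                                       hr_nonsignificant[["hr_80_50"]]),
    top5_nonsignificant = risk_adjust(split$nonsignificant,
                                      hr_nonsignificant[["hr_95_50"]]))
  for (cl in names(out)[-1L]) {
    if (any(out[[cl]] < 0 | out[[cl]] > 1)) {
      stop_polyhaz("curve ", cl, " leaves [0, 1]")
    }
    if (any(diff(out[[cl]]) < -1e-12)) {
      stop_polyhaz("curve ", cl, " is not non-decreasing")
    }
  }
  if (any(abs(out$baseline_significant + out$baseline_nonsignificant -
                out$baseline_any) > 1e-9)) {
    stop_polyhaz("significance split does not sum to the baseline")
  }
  attr(out, "hr_used") <- list(significant = hr_significant[need],
                               nonsignificant = hr_nonsignificant[need])
  class(out) <- c("incidence_curve_set", "data.frame")
  out
}
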