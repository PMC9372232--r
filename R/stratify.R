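# Sample-weight-corrected percentile hazard ratios and the family-history
# comparison.  All Cox fits use the continuous PHS; band HRs are derived
# from the fitted coefficient and the young-control band means, which makes
# HR80/20 = HR80/50 / HR20/50 an exact identity within every bootstrap
# replicate.

#' Inverse-probability sample weights for case-enriched cohorts
#'
#' Controls get weight 1; cases get
#' `w = (pi / (1 - pi)) * (N_controls / N_cases)`, so the weighted case
#' fraction equals the population prevalence `pi` exactly. This removes the
#' bias that case oversampling would otherwise induce in hazard estimates.
#'
#' @param phen a [cohort_phenotype()].
#' @param target_prevalence population case probability in (0, 1); default
#'   the cohort's `prevalence` attribute.
#' @return numeric weight per subject.
#' @export
sample_weights <- function(phen, target_prevalence = attr(phen, "prevalence")) {
  if (is.null(target_prevalence)) {
    stop_polyhaz("no target prevalence supplied or attached to the cohort")
  }
  assert_prob(target_prevalence, "target_prevalence", open = TRUE)
  n_case <- sum(phen$status == "case")
  n_ctrl <- sum(phen$status == "control")
  if (n_case == 0L || n_ctrl == 0L) {
    stop_polyhaz("need both cases and controls to compute sample weights")
  }
  w_case <- (target_prevalence / (1 - target_prevalence)) * n_ctrl / n_case
  ifelse(phen$status == "case", w_case, 1)
}

#' Weighted Cox coefficient for the continuous PHS
#'
#' Fits a weighted Cox proportional hazards model of the requested endpoint
#' on the continuous PHS (Breslow ties). Endpoint conventions: `any` —
#' cases are events at diagnosis age; `significant` — clinically
#' significant cases are events at diagnosis age, everything else censored;
#' `fatal` — prostate cancer deaths are events at death age, everyone else
#' censored at last contact.
#'
#' @param scores per-subject PHS (aligned with `phen`).
#' @param phen a [cohort_phenotype()].
#' @param endpoint one of `"any"`, `"significant"`, `"fatal"`.
#' @param weights per-subject sample weights (default unit).
#' @return list with `beta`, `se`, `z`, `p` (Wald, two-sided, floored at
#'   1e-16), `loglik`, `n_events`.
#' @export
cox_beta_phs <- function(scores, phen, endpoint = "any", weights = NULL) {
  sv <- endpoint_survival(phen, endpoint)
  x <- scores[sv$keep]
  if (is.null(weights)) weights <- rep(1, nrow(phen))
  w <- weights[sv$keep]
  fit <- survival::coxph(survival::Surv(sv$time, sv$event) ~ x,
                         weights = w, ties = "breslow")
  if (anyNA(coef(fit))) {
    stop_polyhaz("degenerate PHS (constant score?): Cox fit undefined")
  }
  sm <- summary(fit)$coefficients
  list(beta = unname(coef(fit)[1L]), se = sm[1L, "se(coef)"],
       z = sm[1L, "z"], p = truncate_pvalue(sm[1L, "Pr(>|z|)"]),
       loglik = fit$loglik[2L], n_events = sum(sv$event))
}

#' Hazard ratio between two percentile bands
#'
#' `HR = exp(beta * (m_A - m_B))` using the young-control reference band
#' means, so e.g. `HR_80/20 = HR_80/50 / HR_20/50` holds exactly.
#'
#' @param beta continuous-PHS Cox coefficient.
#' @param ref a `phs_reference`.
#' @param bandA,bandB band names among `"bottom20"`, `"mid"`, `"top20"`,
#'   `"top5"`.
#' @return the hazard ratio.
#' @export
band_hr <- function(beta, ref, bandA, bandB) {
  key <- c(bottom20 = "m20", mid = "m50", top20 = "m80", top5 = "m95")
  if (!bandA %in% names(key) || !bandB %in% names(key)) {
    stop_polyhaz("bands must be one of: ", paste(names(key), collapse = ", "))
  }
  mA <- ref$interval_means[[key[[bandA]]]]
  mB <- ref$interval_means[[key[[bandB]]]]
  if (mA == mB && bandA != bandB) {
    warning("degenerate reference: equal band means, HR = 1", call. = FALSE)
  }
  exp(beta * (mA - mB))
}

band_hrs_from_beta <- function(beta, ref) {
  c(hr_20_50 = band_hr(beta, ref, "bottom20", "mid"),
    hr_80_50 = band_hr(beta, ref, "top20", "mid"),
    hr_95_50 = band_hr(beta, ref, "top5", "mid"),
    hr_80_20 = band_hr(beta, ref, "top20", "bottom20"))
}

#' Bootstrapped sample-weight-corrected percentile hazard ratios
#'
#' For each bootstrap replicate, subjects are resampled with replacement
#' stratified by case status (preserving the design ratio), sample weights
#' are recomputed, the weighted continuous-PHS Cox model is refit, and all
#' four band HRs (HR20/50, HR80/50, HR95/50, HR80/20) are derived from the
#' replicate coefficient. Reported values are the replicate mean and the
#' 2.5–97.5 percentile confidence interval. Replicates without events are
#' redrawn up to a retry cap.
#'
#' @param scores per-subject PHS.
#' @param phen a [cohort_phenotype()].
#' @param ref a `phs_reference`.
#' @param endpoint `"any"`, `"significant"` or `"fatal"`.
#' @param target_prevalence population prevalence for the weights.
#' @param n_boot number of bootstrap replicates (default 1000).
#' @param seed integer seed (replicates are deterministic given it).
#' @param max_retries redraw cap for event-free replicates.
#' @return an object of class `hr_report`: per-HR mean and CI, the full
#'   replicate matrix, the point (full-sample) estimates, `n_boot`, `seed`.
#' @export
hr_report <- function(scores, phen, ref, endpoint = "any",
                      target_prevalence = attr(phen, "prevalence"),
                      n_boot = 1000L, seed = 1L, max_retries = 100L) {
  n_boot <- assert_count(n_boot, "n_boot")
  cases <- which(phen$status == "case")
  controls <- which(phen$status == "control")
  point_w <- sample_weights(phen, target_prevalence)
  point_fit <- cox_beta_phs(scores, phen, endpoint, point_w)
  point_hrs <- band_hrs_from_beta(point_fit$beta, ref)
  reps <- matrix(NA_real_, n_boot, 4L,
                 dimnames = list(NULL, names(point_hrs)))
  betas <- numeric(n_boot)
  with_seed(seed, {
    for (b in seq_len(n_boot)) {
      fit_b <- NULL
      for (r in seq_len(max_retries)) {
        idx <- c(sample(cases, length(cases), replace = TRUE),
                 sample(controls, length(controls), replace = TRUE))
        # resampled replicate: plain subset, ids intentionally repeat
        ph_b <- as.data.frame(phen)[idx, , drop = FALSE]
        w_b <- sample_weights(ph_b, target_prevalence)
        fit_b <- tryCatch(
          cox_beta_phs(scores[idx], ph_b, endpoint, w_b),
          error = function(e) NULL)
        if (!is.null(fit_b)) break
      }
      if (is.null(fit_b)) {
        stop_polyhaz("bootstrap replicate without events after ",
                     max_retries, " redraws")
      }
      betas[b] <- fit_b$beta
      reps[b, ] <- band_hrs_from_beta(fit_b$beta, ref)
    }
  })
  ci <- apply(reps, 2L, quantile, probs = c(0.025, 0.975), names = FALSE)
  structure(list(endpoint = endpoint,
                 hr = colMeans(reps),
                 ci_low = ci[1L, ], ci_high = ci[2L, ],
                 point = point_hrs, beta_point = point_fit$beta,
                 replicates = reps, betas = betas,
                 n_boot = n_boot, seed = seed,
                 target_prevalence = target_prevalence),
            class = "hr_report")
}

#' @export
print.hr_report <- function(x, ...) {
  cat(sprintf("hr_report (endpoint: %s, %d bootstrap replicates)\n",
              x$endpoint, x$n_boot))
  for (k in seq_along(x$hr)) {
    cat(sprintf("  %s: %.2f [%.2f-%.2f]\n", names(x$hr)[k], x$hr[k],
                x$ci_low[k], x$ci_high[k]))
  }
  invisible(x)
}

#' Compare PHS plus family history against family history alone
#'
#' Restricted to subjects with known family history (presence/absence of a
#' first-degree relative diagnosed with prostate cancer), fits the reduced
#' Cox model (endpoint ~ FH) and the full model (endpoint ~ FH + PHS), and
#' compares them with a log-likelihood ratio test (1 df, alpha = 0.01). The
#' PHS hazard ratio is reported as `exp(beta_phs * (m80 - m20))` (top vs
#' bottom quintile); the family-history HR is `exp(beta_fh)`. All p-values
#' are two-sided and truncated at 1e-16.
#'
#' @param scores per-subject PHS.
#' @param phen a [cohort_phenotype()].
#' @param ref a `phs_reference` (for the PHS HR contrast).
#' @param endpoint `"any"`, `"significant"` or `"fatal"`.
#' @param weights optional per-subject sample weights.
#' @param alpha significance level of the comparison (default 0.01).
#' @return an object of class `fh_comparison` with the full-model
#'   coefficients, z-scores, truncated p-values, HRs, the LRT statistic and
#'   p-value, and `n_used`.
#' @export
family_history_comparison <- function(scores, phen, ref, endpoint = "any",
                                      weights = NULL, alpha = 0.01) {
  known <- phen$family_history %in% c("yes", "no")
  if (!any(known)) stop_polyhaz("no subjects with known family history")
  if (is.null(weights)) weights <- rep(1, nrow(phen))
  ph <- cohort_phenotype(phen[known, , drop = FALSE],
                         prevalence = attr(phen, "prevalence"))
  sc <- scores[known]
  w <- weights[known]
  sv <- endpoint_survival(ph, endpoint)
  fh <- as.integer(ph$family_history == "yes")[sv$keep]
  x <- sc[sv$keep]
  ww <- w[sv$keep]
  y <- survival::Surv(sv$time, sv$event)
  reduced <- suppressWarnings(
    survival::coxph(y ~ fh, weights = ww, ties = "breslow"))
  full <- suppressWarnings(
    survival::coxph(y ~ fh + x, weights = ww, ties = "breslow"))
  sm <- summary(full)$coefficients
  # a degenerate (e.g. constant) PHS column contributes nothing: report a
  # null association rather than NA
  coef_row <- function(nm) {
    if (nm %in% rownames(sm) && !is.na(sm[nm, "coef"])) {
      c(beta = unname(sm[nm, "coef"]), z = unname(sm[nm, "z"]),
        p = unname(sm[nm, "Pr(>|z|)"]))
    } else c(beta = 0, z = 0, p = 1)
  }
  phs_row <- coef_row("x")
  fh_row <- coef_row("fh")
  lrt_stat <- 2 * (full$loglik[2L] - reduced$loglik[2L])
  lrt_p <- truncate_pvalue(pchisq(lrt_stat, df = 1L, lower.tail = FALSE))
  m80 <- ref$interval_means[["m80"]]
  m20 <- ref$interval_means[["m20"]]
  structure(list(
    endpoint = endpoint,
    beta_phs = phs_row[["beta"]], z_phs = phs_row[["z"]],
    p_phs = truncate_pvalue(phs_row[["p"]]),
    p_phs_label = format_pvalue(phs_row[["p"]]),
    hr_phs = exp(phs_row[["beta"]] * (m80 - m20)),
    beta_fh = fh_row[["beta"]], z_fh = fh_row[["z"]],
    p_fh = truncate_pvalue(fh_row[["p"]]),
    p_fh_label = format_pvalue(fh_row[["p"]]),
    hr_fh = exp(fh_row[["beta"]]),
    loglik_full = full$loglik[2L], loglik_reduced = reduced$loglik[2L],
    lrt_stat = lrt_stat, lrt_p = lrt_p,
    lrt_p_label = format_pvalue(pchisq(lrt_stat, 1L, lower.tail = FALSE)),
    reject = lrt_p < alpha, alpha = alpha,
    n_used = sum(sv$keep)), class = "fh_comparison")
}

#' @export
print.fh_comparison <- function(x, ...) {
  cat(sprintf("fh_comparison (endpoint: %s, n = %d)\n", x$endpoint, x$n_used))
  cat(sprintf("  PHS: beta %.2f, z %.1f, p %s, HR80/20 %.2f\n",
              x$beta_phs, x$z_phs, x$p_phs_label, x$hr_phs))
  cat(sprintf("  FH : beta %.2f, z %.1f, p %s, HR %.2f\n",
              x$beta_fh, x$z_fh, x$p_fh_label, x$hr_fh))
  cat(sprintf("  LRT (PHS+FH vs FH): stat %.2f, p %s (alpha %.2g -> %s)\n",
              x$lrt_stat, x$lrt_p_label, x$alpha,
              if (x$reject) "reject" else "retain"))
  invisible(x)
}
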