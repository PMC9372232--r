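# Sample weights, continuous-PHS Cox fits, band hazard ratios, the
# bootstrap report and the family-history comparison.

test_that("sample weights reweight cases to the population prevalence", {
  # equal numbers and pi = 0.5: no-op
  ph <- make_phen(runif(100, 50, 80), rep(c(TRUE, FALSE), 50))
  expect_true(all(sample_weights(ph, 0.5) == 1))
  # N_case = 2 N_control, pi = 0.2 -> w = (0.25)(0.5) = 0.125
  ph2 <- make_phen(runif(300, 50, 80), rep(c(TRUE, FALSE), c(200, 100)))
  w2 <- sample_weights(ph2, 0.2)
  expect_equal(unique(w2[ph2$status == "case"]), 0.125)
  # weighted case fraction equals pi exactly, any configuration
  for (pi0 in c(0.05, 0.3, 0.7)) {
    w <- sample_weights(ph2, pi0)
    expect_equal(sum(w[ph2$status == "case"]) / sum(w), pi0)
  }
  expect_error(sample_weights(make_phen(runif(5, 50, 80), rep(TRUE, 5)),
                              0.1), "both cases and controls")
})

test_that("cox_beta_phs is null-calibrated and recovers a known effect", {
  set.seed(201)
  s <- rnorm(5000)
  phen <- simulate_ph_cohort(rep(0, 5000), seed = 202)
  nullfit <- cox_beta_phs(s, phen, "any")
  expect_lt(abs(nullfit$beta), 3 * nullfit$se)
  set.seed(203)
  s2 <- rnorm(10000)
  phen2 <- simulate_ph_cohort(0.8 * s2, seed = 204)
  fit2 <- cox_beta_phs(s2, phen2, "any")
  expect_lt(abs(fit2$beta - 0.8), 3 * fit2$se)
  # rescaling all weights leaves the estimate unchanged
  w <- rep(2, 10000)
  fit2w <- cox_beta_phs(s2, phen2, "any", weights = w)
  expect_equal(fit2w$beta, fit2$beta, tolerance = 1e-8)
})

test_that("endpoint conventions censor the right subjects", {
  phen <- make_phen(time = c(55, 60, 65, 70),
                    case = c(TRUE, TRUE, FALSE, FALSE),
                    significant = c(TRUE, FALSE, NA, NA),
                    fatal = c(TRUE, FALSE, FALSE, FALSE),
                    death_age = c(62, NA, NA, NA))
  sv_any <- polyhaz:::endpoint_survival(phen, "any")
  expect_equal(sv_any$event, c(1L, 1L, 0L, 0L))
  sv_sig <- polyhaz:::endpoint_survival(phen, "significant")
  expect_equal(sv_sig$event, c(1L, 0L, 0L, 0L))
  sv_fat <- polyhaz:::endpoint_survival(phen, "fatal")
  expect_equal(sv_fat$event, c(1L, 0L, 0L, 0L))
  expect_equal(sv_fat$time, c(62, 60, 65, 70))  # death age for the death
})

test_that("band HRs follow the multiplicative mean-contrast structure", {
  ref <- normal_reference()
  m <- ref$interval_means
  expect_equal(band_hr(log(2), ref, "top20", "bottom20"),
               2^(m[["m80"]] - m[["m20"]]))
  expect_equal(band_hr(0.7, ref, "top20", "top20"), 1.0)
  # exact ratio identity
  b <- 0.61
  expect_equal(band_hr(b, ref, "top20", "bottom20"),
               band_hr(b, ref, "top20", "mid") /
                 band_hr(b, ref, "bottom20", "mid"))
})

test_that("hr_report is deterministic, internally consistent and weight-sane", {
  set.seed(211)
  s <- rnorm(2000)
  phen <- simulate_ph_cohort(0.5 * s, seed = 212)
  ref <- normal_reference()
  pi0 <- attr(phen, "prevalence")
  rep1 <- hr_report(s, phen, ref, "any", pi0, n_boot = 25, seed = 5)
  rep2 <- hr_report(s, phen, ref, "any", pi0, n_boot = 25, seed = 5)
  expect_identical(rep1$replicates, rep2$replicates)
  # HR80/20 = HR80/50 / HR20/50 within every replicate, machine precision
  expect_equal(rep1$replicates[, "hr_80_20"],
               rep1$replicates[, "hr_80_50"] /
                 rep1$replicates[, "hr_20_50"])
  # HR95/50 >= HR80/50 whenever beta > 0
  pos <- rep1$betas > 0
  expect_true(all(rep1$replicates[pos, "hr_95_50"] >=
                    rep1$replicates[pos, "hr_80_50"]))
  # n_boot = 1: mean equals the single replicate, CI degenerate
  rep3 <- hr_report(s, phen, ref, "any", pi0, n_boot = 1, seed = 5)
  expect_equal(unname(rep3$hr), unname(rep3$replicates[1, ]))
  expect_equal(rep3$ci_low, rep3$ci_high)
  # with prevalence equal to the sample case fraction all weights are 1,
  # so the point estimate matches an unweighted Cox fit
  fit_unw <- cox_beta_phs(s, phen, "any")
  expect_equal(rep1$beta_point, fit_unw$beta, tolerance = 1e-10)
})

test_that("family-history comparison nests and reports correctly", {
  set.seed(221)
  n <- 4000
  s <- rnorm(n)
  fh_true <- runif(n) < plogis(-2 + 0.5 * s)
  phen <- simulate_ph_cohort(0.6 * s + 0.3 * fh_true, seed = 222)
  phen$family_history <- ifelse(fh_true, "yes", "no")
  phen$family_history[1:400] <- "unknown"
  ref <- normal_reference()
  cmp <- family_history_comparison(s, phen, ref, "any")
  # only known-FH subjects used
  expect_equal(cmp$n_used, n - 400)
  # nesting: the full model cannot have lower likelihood
  expect_gte(cmp$loglik_full, cmp$loglik_reduced)
  expect_equal(cmp$lrt_stat,
               2 * (cmp$loglik_full - cmp$loglik_reduced))
  expect_equal(cmp$hr_fh, exp(cmp$beta_fh))
  m <- ref$interval_means
  expect_equal(cmp$hr_phs, exp(cmp$beta_phs * (m[["m80"]] - m[["m20"]])))
  # reported LRT p matches the chi-square CDF mapping
  expect_equal(cmp$lrt_p,
               max(pchisq(cmp$lrt_stat, 1, lower.tail = FALSE), 1e-16))
})

test_that("a zero PHS column collapses the comparison to the reduced model", {
  set.seed(231)
  phen <- simulate_ph_cohort(rnorm(800) * 0.3, seed = 232)
  phen$family_history <- sample(c("yes", "no"), 800, TRUE, c(0.15, 0.85))
  ref <- normal_reference()
  cmp <- family_history_comparison(rep(0, 800), phen, ref, "any")
  expect_equal(cmp$loglik_full, cmp$loglik_reduced, tolerance = 1e-9)
  expect_equal(cmp$lrt_stat, 0, tolerance = 1e-9)
  expect_equal(cmp$lrt_p, 1, tolerance = 1e-6)
  expect_equal(cmp$hr_phs, 1)
})

test_that("p-values are truncated at 1e-16 with the printed label", {
  expect_equal(format_pvalue(1e-30), "<1e-16")
  expect_equal(format_pvalue(0.04), "0.04")
  set.seed(241)
  s <- rnorm(15000)
  phen <- simulate_ph_cohort(1.2 * s, seed = 242)
  phen$family_history <- sample(c("yes", "no"), 15000, TRUE, c(0.1, 0.9))
  ref <- normal_reference()
  cmp <- family_history_comparison(s, phen, ref, "any")
  expect_equal(cmp$p_phs, 1e-16)
  expect_equal(cmp$p_phs_label, "<1e-16")
  expect_equal(cmp$lrt_p_label, "<1e-16")
})
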