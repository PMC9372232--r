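# Synthetic cohort generator: marginal genotype laws, duplicate-pair
# construction, the Weibull onset model, sub-phenotypes, sampling and the
# screening layer.

test_that("genotypes follow Hardy-Weinberg moments", {
  cfg <- sim_config(n_subjects = 10000, n_snps = 3,
                    allele_freqs = c(0.5, 0.2, 0.8), n_causal = 0,
                    ld_dup_pairs = 0, seed = 11)
  g <- simulate_genotypes(cfg)
  for (j in 1:3) {
    f <- cfg$allele_freqs[j]
    x <- g$counts[, j]
    se_mean <- sqrt(2 * f * (1 - f) / length(x))
    expect_lt(abs(mean(x) - 2 * f), 3 * se_mean)
    # homozygote frequency ~ f^2 within 4 SEs
    p2 <- mean(x == 2)
    se_p2 <- sqrt(f^2 * (1 - f^2) / length(x))
    expect_lt(abs(p2 - f^2), 4 * se_p2)
  }
})

test_that("duplicate pairs have the designed correlation structure", {
  cfg <- sim_config(n_subjects = 5000, n_snps = 10, n_causal = 0,
                    ld_dup_pairs = 2, ld_fidelity = 1.0, seed = 3)
  g <- simulate_genotypes(cfg)
  lp <- attr(g, "ld_pairs")
  expect_equal(nrow(lp), 2L)
  # fidelity 1 -> identical columns, sample r^2 exactly 1
  for (k in 1:2) {
    expect_identical(g$counts[, lp$source[k]], g$counts[, lp$duplicate[k]])
    expect_equal(pairwise_r2(g, lp$source[k], lp$duplicate[k]), 1.0)
  }
})

test_that("constructed duplicate pairs exceed r2 = 0.95 in nearly all runs", {
  hits <- vapply(1:20, function(r) {
    cfg <- sim_config(n_subjects = 5000, n_snps = 6, n_causal = 0,
                      ld_dup_pairs = 1, ld_fidelity = 0.99, seed = 100 + r)
    g <- simulate_genotypes(cfg)
    lp <- attr(g, "ld_pairs")
    pairwise_r2(g, lp$source[1], lp$duplicate[1]) > 0.95
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("simulation is deterministic given the seed", {
  cfg <- sim_config(n_subjects = 500, n_snps = 20,
                    case_control_ratio = 0.5, seed = 99)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$genotypes$counts, b$genotypes$counts)
  expect_identical(as.data.frame(a$phen), as.data.frame(b$phen))
})

test_that("config validation rejects out-of-range parameters", {
  expect_error(sim_config(allele_freqs = c(0, rep(0.5, 99))), "\\(0, 1\\)")
  expect_error(sim_config(n_causal = 200), "n_causal")
  expect_error(sim_config(target_prevalence = 1.2), "\\(0, 1\\)")
  expect_error(sim_config(ld_fidelity = 0.9), "ld_fidelity")
  expect_error(sim_config(case_control_ratio = -1), "ratio")
})

test_that("null-effect onset ages match the Weibull closed-form median", {
  # no censoring (bounds far beyond any onset), betas all zero
  cfg <- sim_config(n_subjects = 20000, n_snps = 5, n_causal = 0,
                    ld_dup_pairs = 0, censor_min = 1e5, censor_max = 2e5,
                    baseline_shape = 4.5, baseline_scale = 140, seed = 21)
  g <- simulate_genotypes(cfg)
  phen <- simulate_onset(g, cfg)
  expect_true(all(phen$status == "case"))
  med_theory <- 140 * log(2)^(1 / 4.5)
  # Monte-Carlo tolerance: asymptotic SE of the sample median
  dens <- stats::dweibull(med_theory, 4.5, 140)
  se_med <- 1 / (2 * dens * sqrt(nrow(phen)))
  expect_lt(abs(median(phen$event_age) - med_theory), 4 * se_med)
})

test_that("a univariable Cox fit recovers a causal SNP effect", {
  cfg <- sim_config(n_subjects = 20000, n_snps = 5, n_causal = 1,
                    causal_betas = 0.3, ld_dup_pairs = 0, seed = 31)
  g <- simulate_genotypes(cfg)
  phen <- simulate_onset(g, cfg)
  fit <- survival::coxph(
    survival::Surv(phen$event_age, phen$status == "case") ~ g$counts[, 1],
    ties = "breslow")
  est <- unname(coef(fit)[1])
  se <- sqrt(diag(fit$var))[1]
  expect_lt(abs(est - 0.3), 3 * se)
})

test_that("sub-phenotypes respect their construction invariants", {
  cfg <- sim_config(n_subjects = 8000, seed = 41)
  g <- simulate_genotypes(cfg)
  phen <- simulate_onset(g, cfg)
  # death age present => case with significant disease
  dead <- !is.na(phen$death_age)
  expect_true(any(dead))
  expect_true(all(phen$status[dead] == "case"))
  expect_true(all(phen$significant[dead]))
  expect_true(all(phen$death_age[dead] >= phen$event_age[dead]))
  # significance only defined for cases
  expect_true(all(is.na(phen$significant[phen$status == "control"])))
  # PCs standardized
  expect_equal(unname(colMeans(phen[, c("pc1", "pc2", "pc3", "pc4")])),
               rep(0, 4), tolerance = 1e-8)
  expect_equal(unname(apply(phen[, c("pc1", "pc2", "pc3", "pc4")], 2, sd)),
               rep(1, 4), tolerance = 1e-8)
})

test_that("family history is positively associated with genetic burden", {
  cfg <- sim_config(n_subjects = 20000, fh_slope = 0.8, fh_missing = 0,
                    seed = 51)
  g <- simulate_genotypes(cfg)
  phen <- simulate_onset(g, cfg)
  lp <- attr(phen, "true_lp")
  q <- quantile(lp, c(0.2, 0.8))
  top <- phen$family_history[lp >= q[2]] == "yes"
  bot <- phen$family_history[lp <= q[1]] == "yes"
  or <- (mean(top) / (1 - mean(top))) / (mean(bot) / (1 - mean(bot)))
  expect_gt(or, 1)
  # overall positive-FH rate in the configured single-digit range
  expect_gt(mean(phen$family_history == "yes"), 0.05)
  expect_lt(mean(phen$family_history == "yes"), 0.25)
})

test_that("classify_significance applies each criterion inclusively", {
  rec <- function(gleason = 6, psa = 4, t_stage = "T1", node = FALSE,
                  met = FALSE) {
    data.frame(gleason = gleason, psa = psa, t_stage = t_stage,
               node_positive = node, metastatic = met)
  }
  expect_false(classify_significance(rec(6, 4, "T2")))
  expect_true(classify_significance(rec(gleason = 7)))
  expect_true(classify_significance(rec(psa = 10.0)))  # boundary inclusive
  expect_true(classify_significance(rec(t_stage = "T3")))
  expect_true(classify_significance(rec(node = TRUE)))
  expect_true(classify_significance(rec(met = TRUE)))
  expect_error(classify_significance(rec(psa = NA)), "missing")
  expect_error(classify_significance(rec(gleason = 1)), "gleason")
})

test_that("clinical records hit the configured significance rate", {
  set.seed(61)
  rec <- simulate_clinical_records(20000, 0.55)
  rate <- mean(classify_significance(rec))
  expect_lt(abs(rate - 0.55), 4 * sqrt(0.55 * 0.45 / 20000))
})

test_that("case-control sampling realizes the requested ratio", {
  phen <- make_phen(time = runif(6300, 50, 80),
                    case = rep(c(TRUE, FALSE), c(300, 6000)))
  out <- apply_case_control_sampling(phen, 0.5, seed = 5)
  expect_equal(sum(out$phen$status == "case"), 300)
  expect_equal(sum(out$phen$status == "control"), 600)
  # prevalence link retained
  expect_equal(attr(out$phen, "prevalence"), 300 / 6300)
  # ratio equal to the population ratio: a no-op up to shuffling
  same <- apply_case_control_sampling(phen, 300 / 6000, seed = 5)
  expect_equal(nrow(same$phen), 6300)
  expect_setequal(same$phen$subject_id, phen$subject_id)
  # determinism
  out2 <- apply_case_control_sampling(phen, 0.5, seed = 5)
  expect_identical(out$phen$subject_id, out2$phen$subject_id)
  # unattainable ratio
  tiny <- make_phen(runif(3, 50, 80), c(TRUE, FALSE, FALSE))
  expect_error(apply_case_control_sampling(tiny, 1e-4, seed = 1),
               "unattainable")
})

test_that("screening layer realizes the screen-positive design exactly", {
  cfg <- sim_config(n_subjects = 4000, screen_ratio = 0.5, seed = 71)
  phen <- make_phen(time = runif(900, 50, 80),
                    case = rep(c(TRUE, FALSE), c(200, 700)),
                    significant = c(rep(c(TRUE, FALSE), 100),
                                    rep(NA, 700)))
  scr <- simulate_screening(phen, cfg)
  pos <- scr$psa_positive %in% TRUE
  expect_equal(sum(pos & scr$status == "case"), 200)
  expect_equal(sum(pos & scr$status == "control"), 400)  # exactly 1:2
  # biopsy outcome equals significance for cases, negative for controls
  expect_identical(scr$biopsy_significant[pos & scr$status == "case"],
                   scr$significant[pos & scr$status == "case"] %in% TRUE)
  expect_true(all(scr$biopsy_significant[pos & scr$status == "control"]
                  == FALSE))
  expect_true(all(is.na(scr$biopsy_significant[!pos])))
  # not enough controls -> error
  few <- make_phen(runif(250, 50, 80), rep(c(TRUE, FALSE), c(200, 50)))
  expect_error(simulate_screening(few, cfg), "not enough controls")
})
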