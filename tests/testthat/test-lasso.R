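# Penalized Cox machinery: the weighted Breslow partial likelihood, the
# solution path, KKT verification, cross-validation and weight export.

test_that("partial log-likelihood matches closed forms", {
  # one event among k at risk, all betas zero -> -ln(k)
  for (k in c(2, 5, 9)) {
    X <- matrix(rnorm(k), k, 1)
    ll <- cox_partial_loglik(0, X, event_ages = seq_len(k),
                             event_flags = c(1, rep(0, k - 1)))
    expect_equal(ll, -log(k))
  }
  # two subjects, both events at distinct times, x = (1, 0), beta = 0
  ll2 <- cox_partial_loglik(0, matrix(c(1, 0), 2, 1),
                            event_ages = c(1, 2), event_flags = c(1, 1))
  expect_equal(ll2, -log(2))
})

test_that("partial log-likelihood matches a brute-force oracle with ties and weights", {
  set.seed(101)
  for (r in 1:10) {
    n <- sample(4:10, 1)
    p <- sample(1:3, 1)
    X <- matrix(rnorm(n * p), n, p)
    time <- sample(1:4, n, replace = TRUE)  # heavy ties
    status <- rbinom(n, 1, 0.7)
    if (sum(status) == 0) status[1] <- 1
    w <- runif(n, 0.2, 3)
    beta <- rnorm(p, sd = 0.5)
    expect_equal(cox_partial_loglik(beta, X, time, status, w),
                 brute_breslow_loglik(beta, X, time, status, w),
                 tolerance = 1e-12)
  }
})

test_that("degenerate likelihood inputs are rejected", {
  X <- matrix(rnorm(5), 5, 1)
  expect_error(cox_partial_loglik(0, X, 1:5, rep(0, 5)), "all-censored")
  expect_error(cox_partial_loglik(0, X, c(-1, 2:5), c(1, rep(0, 4))),
               "positive")
  expect_error(cox_partial_loglik(c(0, 0), X, 1:5, c(1, rep(0, 4))),
               "match")
})

make_fit_data <- function(n = 200, p = 5, seed = 111, beta1 = 0.4) {
  set.seed(seed)
  X <- matrix(rbinom(n * p, 2, 0.3), n, p,
              dimnames = list(NULL, sprintf("snp%03d", 1:p)))
  phen <- simulate_ph_cohort(beta1 * (X[, 1] - mean(X[, 1])), seed = seed + 1,
                             censor = c(50, 110))
  list(X = X, phen = phen)
}

test_that("every penalized coefficient is zero at lambda_max", {
  d <- make_fit_data()
  Xp <- cbind(d$X, pc = rnorm(nrow(d$X)))
  path <- fit_lasso_path(Xp, d$phen, penalty_mask = c(rep(1, 5), 0))
  expect_true(all(path$beta[1:5, 1] == 0))
  # the unpenalized column is not thresholded anywhere on the path
  expect_true(all(path$beta[6, ] != 0))
})

test_that("the path solution approaches the unpenalized Cox fit as lambda -> 0", {
  d <- make_fit_data()
  lmax <- fit_lasso_path(d$X, d$phen)$lambda[1]
  lams <- exp(seq(log(lmax), log(lmax * 1e-9), length.out = 80))
  path <- fit_lasso_path(d$X, d$phen, lambda = lams, thresh = 1e-16)
  cph <- survival::coxph(
    survival::Surv(d$phen$event_age, d$phen$status == "case") ~ d$X,
    ties = "breslow")
  expect_lt(max(abs(path$beta[, ncol(path$beta)] - unname(coef(cph)))),
            1e-4)
})

test_that("KKT conditions hold along the default path", {
  d <- make_fit_data()
  Xp <- cbind(d$X, pc = rnorm(nrow(d$X)))
  path <- fit_lasso_path(Xp, d$phen, penalty_mask = c(rep(1, 5), 0),
                         thresh = 1e-16)
  kkt <- kkt_check(path)
  expect_lt(max(kkt$max_violation), 1e-6)
  expect_lt(max(kkt$max_unpenalized_grad), 1e-6)
})

test_that("the penalized objective beats the zero vector at every lambda", {
  d <- make_fit_data()
  path <- fit_lasso_path(d$X, d$phen, thresh = 1e-12)
  sv <- survival::Surv(d$phen$event_age, d$phen$status == "case")
  W <- nrow(d$X)
  ll0 <- cox_partial_loglik(rep(0, ncol(d$X)), path$Xs,
                            d$phen$event_age,
                            as.integer(d$phen$status == "case"))
  for (k in seq_along(path$lambda)) {
    b <- path$beta_std[, k]
    ll <- cox_partial_loglik(b, path$Xs, d$phen$event_age,
                             as.integer(d$phen$status == "case"))
    obj <- ll / W - path$lambda[k] * sum(abs(b))
    obj0 <- ll0 / W
    expect_gte(obj, obj0 - 1e-10)
  }
  # and the fitted log-likelihood increases monotonely along the path
  lls <- vapply(seq_along(path$lambda), function(k) {
    cox_partial_loglik(path$beta_std[, k], path$Xs, d$phen$event_age,
                       as.integer(d$phen$status == "case"))
  }, numeric(1))
  expect_true(all(diff(lls) > -1e-8))
})

test_that("cross-validation is deterministic and respects fold structure", {
  d <- make_fit_data(n = 150)
  fit1 <- cross_validate(d$X, d$phen, k = 5, seed = 42, n_lambda = 30)
  fit2 <- cross_validate(d$X, d$phen, k = 5, seed = 42, n_lambda = 30)
  expect_identical(fit1$folds, fit2$folds)
  expect_identical(fit1$lambda_min, fit2$lambda_min)
  expect_identical(fit1$betas, fit2$betas)
  # every fold contains at least one event
  ev <- d$phen$status == "case"
  expect_true(all(tapply(ev, fit1$folds, sum) > 0))
  expect_true(fit1$lambda_min %in% fit1$lambda)
  # CV deviance decreases from lambda_max toward the optimum
  expect_lt(fit1$cv_deviance[fit1$index_min], fit1$cv_deviance[1])
})

test_that("leave-one-out cross-validation runs on n = 30", {
  set.seed(131)
  X <- matrix(rbinom(30 * 3, 2, 0.4), 30, 3,
              dimnames = list(NULL, c("a", "b", "c")))
  # fully observed onsets so every leave-one-out training set has events
  phen <- make_phen(time = 70 * rexp(30)^(1 / 4.5), case = rep(TRUE, 30))
  fit <- cross_validate(X, phen, k = 30, seed = 7, n_lambda = 20)
  expect_true(fit$lambda_min %in% fit$lambda)
})

test_that("pure-noise predictors select a near-maximal penalty", {
  hits <- vapply(1:20, function(r) {
    set.seed(300 + r)
    n <- 4000
    X <- matrix(rbinom(n * 10, 2, 0.3), n, 10,
                dimnames = list(NULL, sprintf("s%02d", 1:10)))
    phen <- simulate_ph_cohort(rep(0, n), seed = 400 + r,
                               censor = c(50, 110))
    fit <- cross_validate(X, phen, k = 10, seed = r, n_lambda = 30,
                          thresh = 1e-9)
    which(fit$lambda == fit$lambda_min) <= 2
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("weight export keeps exactly the non-zero SNP coefficients", {
  d <- make_fit_data(n = 400, seed = 121)
  Xp <- cbind(d$X, pc = rnorm(nrow(d$X)))
  meta <- data.frame(id = colnames(d$X), chrom = "1", pos = 1:5,
                     effect_allele = "A", other_allele = "G", freq = 0.3)
  fit <- cross_validate(Xp, d$phen, penalty_mask = c(rep(1, 5), 0),
                        k = 5, seed = 9, n_lambda = 40)
  w <- export_weights(fit, meta)
  nz <- fit$betas[1:5][fit$betas[1:5] != 0]
  expect_equal(nrow(w), length(nz))
  expect_false("pc" %in% w$snp_id)
  expect_equal(w$beta, unname(nz))
  # round trip through the TSV writer
  path <- withr::local_tempfile(fileext = ".tsv")
  write_weights(w, path)
  expect_identical(read_weights(path)$beta, w$beta)
})
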