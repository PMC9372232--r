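# L1-regularized Cox model over candidate SNPs plus (unpenalized) ancestry
# principal components.  The solution path is computed with glmnet's
# coordinate descent (the standard solver for this model); the weighted
# Breslow partial log-likelihood, the cross-validation machinery
# (Verweij-Van Houwelingen out-of-fold deviance) and the KKT verifier are
# implemented here and serve as independent checks on the solver output.

#' Weighted Breslow partial log-likelihood
#'
#' Cox partial log-likelihood with the Breslow treatment of tied event
#' times and per-subject case weights. With unit weights it reduces to the
#' classical partial likelihood.
#'
#' @param betas coefficient vector.
#' @param X design matrix (subjects x predictors).
#' @param event_ages positive event/censoring times.
#' @param event_flags 1 for an event, 0 for censored.
#' @param weights non-negative per-subject weights (default all 1).
#' @return the log partial likelihood (a scalar).
#' @export
cox_partial_loglik <- function(betas, X, event_ages, event_flags,
                               weights = NULL) {
  X <- as.matrix(X)
  if (ncol(X) != length(betas)) {
    stop_polyhaz("length(betas) must match ncol(X)")
  }
  eta <- drop(X %*% betas)
  cox_loglik_eta(eta, event_ages, event_flags, weights)
}

# Core: partial log-likelihoods for a matrix of linear predictors (one
# column per lambda), sorting the risk set once.
cox_loglik_eta_mat <- function(etas, time, status, weights = NULL) {
  etas <- as.matrix(etas)
  n <- length(time)
  if (is.null(weights)) weights <- rep(1, n)
  status <- as.integer(status)
  if (sum(status) == 0L) stop_polyhaz("all-censored input: no events")
  od <- order(time, decreasing = TRUE)
  R <- weights * exp(etas)
  cumR <- apply(R[od, , drop = FALSE], 2L, cumsum)
  ta <- sort(time)
  ut <- sort(unique(time[status == 1L]))
  n_ge <- n - findInterval(ut, ta, left.open = TRUE)
  ev <- status == 1L
  grp <- match(time[ev], ut)
  d <- vapply(split(weights[ev], grp), sum, numeric(1))
  term1 <- colSums(weights[ev] * etas[ev, , drop = FALSE])
  term2 <- colSums(d * log(cumR[n_ge, , drop = FALSE]))
  term1 - term2
}

# Core: partial log-likelihood given the linear predictor.
cox_loglik_eta <- function(eta, time, status, weights = NULL) {
  n <- length(time)
  if (is.null(weights)) weights <- rep(1, n)
  if (any(weights < 0)) stop_polyhaz("weights must be non-negative")
  if (any(!is.finite(time)) || any(time <= 0)) {
    stop_polyhaz("event ages must be positive")
  }
  status <- as.integer(status)
  if (sum(status) == 0L) stop_polyhaz("all-censored input: no events")
  r <- weights * exp(eta)
  ta <- sort(time)                        # ascending
  cum_r <- cumsum((r[order(time)])[n:1])  # cumulative risk from largest time
  ut <- sort(unique(time[status == 1L]))
  # number of subjects with time >= t, exact under shared float values
  n_ge <- n - findInterval(ut, ta, left.open = TRUE)
  s0 <- cum_r[n_ge]
  d <- vapply(split(weights[status == 1L], match(time[status == 1L], ut)),
              sum, numeric(1))
  sum(weights[status == 1L] * eta[status == 1L]) - sum(d * log(s0))
}

#' Assemble the model design matrix from genotypes and phenotypes
#'
#' SNP allele counts with missing entries mean-imputed as twice the
#' effect-allele frequency (computed from the stored metadata, falling back
#' to the observed training frequency), followed by the four ancestry
#' principal components. The returned penalty mask penalizes SNPs and
#' leaves the PCs unpenalized.
#'
#' @param g a [genotype_matrix()].
#' @param phen the matching [cohort_phenotype()] providing `pc1`..`pc4`.
#' @param use_pcs include the principal components (default TRUE).
#' @return list with `X`, `penalty_mask` (1 = penalized), `snp_ids`.
#' @export
build_design <- function(g, phen, use_pcs = TRUE) {
  counts <- g$counts
  freq <- g$snp_meta$freq
  obs_freq <- colMeans(counts, na.rm = TRUE) / 2
  freq[is.na(freq)] <- obs_freq[is.na(freq)]
  for (j in seq_len(ncol(counts))) {
    nas <- is.na(counts[, j])
    if (any(nas)) counts[nas, j] <- 2 * freq[j]
  }
  X <- counts
  mask <- rep(1, ncol(X))
  if (use_pcs) {
    pcs <- as.matrix(phen[, c("pc1", "pc2", "pc3", "pc4")])
    colnames(pcs) <- c("pc1", "pc2", "pc3", "pc4")
    X <- cbind(X, pcs)
    mask <- c(mask, rep(0, 4L))
  }
  list(X = X, penalty_mask = mask, snp_ids = g$snp_meta$id)
}

#' Fit the L1-penalized Cox solution path
#'
#' Maximizes the weighted Breslow partial log-likelihood minus
#' `lambda * sum(penalized |beta_j|)` along a log-spaced path from
#' `lambda_max` (the smallest lambda at which every penalized coefficient
#' is zero) downward. Predictors are standardized internally; coefficients
#' are reported on the original (allele-count) scale. Predictors with
#' `penalty_mask == 0` (the principal components) are never thresholded.
#'
#' @param X design matrix from [build_design()].
#' @param phen a [cohort_phenotype()]; age at diagnosis is the time to
#'   event, controls censored at last follow-up.
#' @param penalty_mask per-column 0/1 penalty indicator (1 = penalized).
#' @param n_lambda path length (default 100).
#' @param lambda_min_ratio smallest lambda as a fraction of lambda_max.
#' @param weights optional per-subject sample weights.
#' @param lambda optional explicit lambda sequence (overrides the above).
#' @param thresh coordinate-descent convergence threshold.
#' @param polish refine each path point with damped Newton steps on the
#'   active set (fixed signs), sharpening the solver output to
#'   near-machine-precision stationarity (default TRUE; disable for large
#'   fits where path-level precision is not needed).
#' @return an object of class `phs_lasso_path` with the lambda sequence,
#'   standardized and original-scale coefficient matrices, and the
#'   standardization constants.
#' @export
fit_lasso_path <- function(X, phen, penalty_mask = NULL, n_lambda = 100L,
                           lambda_min_ratio = 1e-4, weights = NULL,
                           lambda = NULL, thresh = 1e-12, polish = TRUE) {
  X <- as.matrix(X)
  if (is.null(penalty_mask)) penalty_mask <- rep(1, ncol(X))
  if (length(penalty_mask) != ncol(X)) {
    stop_polyhaz("penalty_mask must have one entry per column")
  }
  sds <- apply(X, 2L, sd)
  if (any(sds == 0)) {
    stop_polyhaz("constant predictor column(s): ",
                 paste(colnames(X)[sds == 0], collapse = ", "))
  }
  centers <- colMeans(X)
  Xs <- scale(X, center = centers, scale = sds)
  sv <- endpoint_survival(phen, "any")
  y <- survival::Surv(sv$time, sv$event)
  if (is.null(weights)) weights <- rep(1, nrow(X))
  fit <- glmnet::glmnet(Xs, y, family = "cox", weights = weights,
                        standardize = FALSE,
                        penalty.factor = penalty_mask,
                        nlambda = n_lambda,
                        lambda.min.ratio = lambda_min_ratio,
                        lambda = lambda, thresh = thresh, maxit = 1e6)
  if (!is.null(fit$jerr) && fit$jerr > 0) {
    # positive error codes are fatal; negative ones mean the path was
    # truncated early, and the returned prefix is a valid solution path
    stop_polyhaz("penalized Cox fit failed to converge at lambda index ",
                 fit$dim[2L], " (jerr = ", fit$jerr, ")")
  }
  beta_std <- as.matrix(fit$beta)
  if (polish && sum(penalty_mask) > 0) {
    pfin <- penalty_mask * length(penalty_mask) / sum(penalty_mask)
    for (k in seq_along(fit$lambda)) {
      beta_std[, k] <- polish_active_set(beta_std[, k], fit$lambda[k], Xs,
                                         sv$time, sv$event, weights, pfin)
    }
  }
  beta_orig <- beta_std / sds
  structure(list(
    lambda = fit$lambda,
    beta = beta_orig,
    beta_std = beta_std,
    Xs = Xs,
    centers = centers, sds = sds,
    penalty_mask = penalty_mask,
    col_names = colnames(X),
    weights = weights,
    time = sv$time, event = sv$event,
    glmnet_fit = fit), class = "phs_lasso_path")
}

#' @export
print.phs_lasso_path <- function(x, ...) {
  cat(sprintf("phs_lasso_path: %d lambdas over %d predictors (%d penalized)\n",
              length(x$lambda), nrow(x$beta), sum(x$penalty_mask > 0)))
  invisible(x)
}

#' Verify the Karush-Kuhn-Tucker conditions along the path
#'
#' Independent check of solver output: at each lambda the gradient of the
#' weighted Breslow partial log-likelihood (on the standardized predictor
#' scale) must satisfy `|g_j| <= lambda * W * v_j` for penalized
#' coefficients at zero and `g_j = lambda * W * v_j * sign(beta_j)` for
#' active ones, where `W` is the total weight and `v_j` the penalty factor
#' (rescaled to average 1, matching the solver's objective); unpenalized
#' coefficients must have zero gradient.
#'
#' @param path a `phs_lasso_path`.
#' @return data.frame with one row per lambda: the largest relative
#'   violation among penalized coordinates and the largest absolute
#'   gradient among unpenalized ones.
#' @export
kkt_check <- function(path) {
  stopifnot(inherits(path, "phs_lasso_path"))
  Xs <- path$Xs
  w <- path$weights
  W <- sum(w)
  pf <- path$penalty_mask
  pfin <- pf * length(pf) / sum(pf)
  out <- data.frame(lambda = path$lambda,
                    max_violation = NA_real_,
                    max_unpenalized_grad = NA_real_)
  for (k in seq_along(path$lambda)) {
    b <- path$beta_std[, k]
    g <- cox_score_gradient(b, Xs, path$time, path$event, w)
    lam <- path$lambda[k]
    viol <- 0
    for (j in which(pf > 0)) {
      bound <- lam * W * pfin[j]
      viol <- if (b[j] != 0) {
        max(viol, abs(g[j] / bound - sign(b[j])))
      } else {
        max(viol, max(0, (abs(g[j]) - bound) / bound))
      }
    }
    out$max_violation[k] <- viol
    out$max_unpenalized_grad[k] <- if (any(pf == 0)) {
      max(abs(g[pf == 0])) / W
    } else 0
  }
  out
}

# Gradient of the weighted Breslow partial log-likelihood, computed with
# reverse cumulative sums over the ordered risk sets (O(n p + n log n)).
cox_score_gradient <- function(beta, X, time, status, w) {
  n <- length(time)
  eta <- drop(X %*% beta)
  r <- w * exp(eta)
  od <- order(time, decreasing = TRUE)
  cr <- cumsum(r[od])
  crX <- apply(r[od] * X[od, , drop = FALSE], 2L, cumsum)
  ta <- sort(time)
  ut <- sort(unique(time[status == 1L]))
  n_ge <- n - findInterval(ut, ta, left.open = TRUE)
  s0 <- cr[n_ge]
  s1 <- crX[n_ge, , drop = FALSE]
  ev <- status == 1L
  d <- vapply(split(w[ev], match(time[ev], ut)), sum, numeric(1))
  colSums(w[ev] * X[ev, , drop = FALSE]) - colSums(d * s1 / s0)
}

# Newton refinement of the solver's solution at one lambda: with the active
# set and signs fixed, the exact optimum satisfies
#   grad_j(beta) = lambda * W * v_j * sign(beta_j)   (penalized active)
#   grad_j(beta) = 0                                 (unpenalized),
# a smooth root-finding problem solved here with damped Newton steps using
# finite-difference Jacobians of the analytic gradient. Falls back to the
# input if the active set's signs are not preserved.
polish_active_set <- function(beta, lam, Xs, time, status, w, pfin,
                              max_iter = 12L, tol = 1e-9) {
  W <- sum(w)
  act <- which(beta != 0 | pfin == 0)
  if (!length(act)) return(beta)
  s <- sign(beta[act])
  target <- lam * W * pfin[act] * s
  Xa <- Xs[, act, drop = FALSE]
  b <- beta[act]
  gfun <- function(bb) cox_score_gradient(bb, Xa, time, status, w) - target
  g <- gfun(b)
  scale <- lam * W * max(pfin[act], 1e-12) + sqrt(W)
  for (it in seq_len(max_iter)) {
    if (max(abs(g)) < tol * scale) break
    h <- 1e-6 * pmax(abs(b), 1e-3)
    J <- vapply(seq_along(b), function(j) {
      bj <- b; bj[j] <- bj[j] + h[j]
      (gfun(bj) - g) / h[j]
    }, numeric(length(b)))
    step <- tryCatch(solve(J, -g), error = function(e) NULL)
    if (is.null(step)) return(beta)
    for (damp in c(1, 0.5, 0.25)) {
      bn <- b + damp * step
      gn <- gfun(bn)
      if (max(abs(gn)) < max(abs(g))) break
    }
    if (max(abs(gn)) >= max(abs(g))) break
    b <- bn; g <- gn
  }
  # keep the refinement only if the sign pattern survived
  if (any(sign(b) != s & pfin[act] > 0)) return(beta)
  out <- beta
  out[act] <- b
  out
}

#' Seeded cross-validation folds with events in every fold
#'
#' Folds are drawn by seeded permutation and redrawn until every fold
#' contains at least one event (when the event count makes that feasible,
#' i.e. at least `k` events) or, in boundary configurations such as
#' leave-one-out, until every fold's *complement* — the set the model is
#' actually fit on — contains at least one event.
#'
#' @param n number of subjects.
#' @param k number of folds.
#' @param events 0/1 event indicator.
#' @param seed integer seed.
#' @param max_retries redraw limit before giving up.
#' @return integer fold assignment of length `n`.
#' @export
make_cv_folds <- function(n, k, events, seed, max_retries = 100L) {
  if (n < k) stop_polyhaz("need n >= k")
  per_fold <- sum(events) >= k
  base <- rep(seq_len(k), length.out = n)
  seeds <- derive_seeds(seed, max_retries)
  for (r in seq_len(max_retries)) {
    folds <- with_seed(seeds[r], base[sample.int(n)])
    in_fold <- vapply(seq_len(k), function(f) sum(events[folds == f]),
                      numeric(1))
    ok <- if (per_fold) all(in_fold > 0) else all(sum(events) - in_fold > 0)
    if (ok) return(folds)
  }
  stop_polyhaz("could not build ", k, " folds with events after ",
               max_retries, " attempts")
}

#' Cross-validated lambda selection for the penalized Cox model
#'
#' Subjects are partitioned into `k` seeded folds (redrawn if a fold lacks
#' events). For each fold the path is refit without it and the
#' out-of-fold partial-likelihood deviance is measured as
#' `-2 * (loglik(all subjects) - loglik(training subjects))` at the
#' held-in coefficients (the Verweij-Van Houwelingen construction, which
#' avoids unstable small-fold partial likelihoods). The returned model is
#' the full-data fit at the lambda minimizing the mean cross-validated
#' deviance.
#'
#' @inheritParams fit_lasso_path
#' @param k number of folds (default 10).
#' @param seed integer seed controlling the fold assignment.
#' @return an object of class `phs_cox_fit`: the full path, per-lambda CV
#'   deviance mean and SE, `lambda_min`, coefficients at `lambda_min` on
#'   the allele-count scale, and `n_nonzero_snps`.
#' @export
cross_validate <- function(X, phen, penalty_mask = NULL, k = 10L, seed = 1L,
                           n_lambda = 100L, lambda_min_ratio = 1e-4,
                           weights = NULL, thresh = 1e-12) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (is.null(weights)) weights <- rep(1, n)
  # the path is scored unpolished (CV deviance is insensitive to
  # sub-tolerance refinements); the selected solution is polished below
  full <- fit_lasso_path(X, phen, penalty_mask, n_lambda = n_lambda,
                         lambda_min_ratio = lambda_min_ratio,
                         weights = weights, thresh = thresh,
                         polish = FALSE)
  lam <- full$lambda
  sv <- endpoint_survival(phen, "any")
  folds <- make_cv_folds(n, k, sv$event, seed)
  Xs <- full$Xs
  dev <- matrix(NA_real_, k, length(lam))
  for (f in seq_len(k)) {
    tr <- folds != f
    fit_f <- glmnet::glmnet(Xs[tr, , drop = FALSE],
                            survival::Surv(sv$time[tr], sv$event[tr]),
                            family = "cox", weights = weights[tr],
                            standardize = FALSE,
                            penalty.factor = full$penalty_mask,
                            lambda = lam, thresh = thresh, maxit = 1e6)
    bmat <- as.matrix(fit_f$beta)
    # glmnet may return a truncated path; only the shared head is scored
    got <- ncol(bmat)
    eta_all <- Xs %*% bmat
    ll_all <- cox_loglik_eta_mat(eta_all, sv$time, sv$event, weights)
    ll_tr <- cox_loglik_eta_mat(eta_all[tr, , drop = FALSE], sv$time[tr],
                                sv$event[tr], weights[tr])
    dev[f, seq_len(got)] <- -2 * (ll_all - ll_tr)
  }
  keep <- colSums(is.na(dev)) == 0L
  cvm <- colMeans(dev[, keep, drop = FALSE])
  cvse <- apply(dev[, keep, drop = FALSE], 2L, sd) / sqrt(k)
  lam_keep <- lam[keep]
  i_min <- which.min(cvm)
  lambda_min <- lam_keep[i_min]
  idx_full <- match(lambda_min, lam)
  beta_std_min <- full$beta_std[, idx_full]
  if (sum(full$penalty_mask) > 0) {
    pfin <- full$penalty_mask * length(full$penalty_mask) /
      sum(full$penalty_mask)
    beta_std_min <- polish_active_set(beta_std_min, lambda_min, Xs,
                                      sv$time, sv$event, weights, pfin)
  }
  betas <- beta_std_min / full$sds
  names(betas) <- full$col_names
  n_nonzero_snps <- sum(betas != 0 & full$penalty_mask == 1)
  structure(list(path = full, lambda = lam_keep, cv_deviance = cvm,
                 cv_se = cvse, lambda_min = lambda_min,
                 index_min = i_min, betas = betas,
                 penalty_mask = full$penalty_mask,
                 n_nonzero_snps = n_nonzero_snps,
                 folds = folds, seed = seed), class = "phs_cox_fit")
}

#' @export
print.phs_cox_fit <- function(x, ...) {
  cat(sprintf(paste0("phs_cox_fit: lambda_min = %.5g (index %d of %d), ",
                     "%d non-zero SNP coefficients\n"),
              x$lambda_min, x$index_min, length(x$lambda),
              x$n_nonzero_snps))
  invisible(x)
}

#' Export the fitted model as a SNP weight table
#'
#' The table contains exactly the SNPs with non-zero coefficients at the
#' selected lambda; principal-component coefficients are excluded from the
#' score.
#'
#' @param fit a `phs_cox_fit` (or `phs_lasso_path` plus `lambda`).
#' @param snp_meta SNP metadata supplying effect alleles (from the
#'   [genotype_matrix()] used to build the design).
#' @return a `snp_weight_table` data.frame (`snp_id`, `effect_allele`,
#'   `beta`).
#' @export
export_weights <- function(fit, snp_meta) {
  stopifnot(inherits(fit, "phs_cox_fit"))
  betas <- fit$betas
  snp <- fit$penalty_mask == 1
  nz <- snp & betas != 0
  ids <- names(betas)[nz]
  idx <- match(ids, snp_meta$id)
  if (anyNA(idx)) {
    stop_polyhaz("SNP(s) absent from metadata: ",
                 paste(ids[is.na(idx)], collapse = ", "))
  }
  validate_weights(data.frame(snp_id = ids,
                              effect_allele = snp_meta$effect_allele[idx],
                              beta = unname(betas[nz]),
                              stringsAsFactors = FALSE))
}
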