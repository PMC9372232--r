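# Shared fixture builders and independent oracles.  Everything is generated
# in code under fixed seeds; no data files.

# Minimal valid phenotype table from survival components.
make_phen <- function(time, case, significant = NULL, fatal = NULL,
                      death_age = NULL, family_history = NULL,
                      psa_positive = NULL, biopsy_significant = NULL,
                      prevalence = mean(case)) {
  n <- length(time)
  if (is.null(significant)) {
    significant <- rep(NA, n)
    significant[case] <- TRUE
  }
  df <- data.frame(
    subject_id = sprintf("s%05d", seq_len(n)),
    status = ifelse(case, "case", "control"),
    event_age = time,
    significant = significant,
    fatal = if (is.null(fatal)) rep(FALSE, n) else fatal,
    death_age = if (is.null(death_age)) rep(NA_real_, n) else death_age,
    family_history = if (is.null(family_history)) rep("no", n) else
      family_history,
    psa_positive = if (is.null(psa_positive)) rep(NA, n) else psa_positive,
    biopsy_significant = if (is.null(biopsy_significant)) rep(NA, n) else
      biopsy_significant,
    pc1 = 0, pc2 = 0, pc3 = 0, pc4 = 0,
    stringsAsFactors = FALSE)
  cohort_phenotype(df, prevalence = prevalence)
}

# Weibull proportional-hazards cohort driven by a given linear predictor.
simulate_ph_cohort <- function(lp, seed, shape = 4.5, scale = 140,
                               censor = c(55, 85)) {
  set.seed(seed)
  n <- length(lp)
  tt <- scale * (rexp(n) / exp(lp))^(1 / shape)
  cc <- runif(n, censor[1], censor[2])
  case <- tt <= cc
  make_phen(pmin(tt, cc), case)
}

# Independent brute-force weighted Breslow partial log-likelihood, written
# directly from the defining sum (nested loops, no sharing with the
# package implementation).
brute_breslow_loglik <- function(beta, X, time, status, w) {
  eta <- as.numeric(X %*% beta)
  ll <- 0
  for (t in unique(time[status == 1])) {
    d_idx <- which(status == 1 & time == t)
    denom <- 0
    for (j in seq_along(time)) {
      if (time[j] >= t) denom <- denom + w[j] * exp(eta[j])
    }
    for (i in d_idx) ll <- ll + w[i] * eta[i]
    ll <- ll - sum(w[d_idx]) * log(denom)
  }
  ll
}

# Tiny genotype matrix from an explicit count matrix.
make_geno <- function(counts, freq = NULL, ids = NULL) {
  counts <- as.matrix(counts)
  p <- ncol(counts)
  if (is.null(freq)) freq <- pmin(pmax(colMeans(counts, na.rm = TRUE) / 2,
                                       0.01), 0.99)
  meta <- data.frame(id = if (is.null(ids)) sprintf("snp%03d", seq_len(p))
                     else ids,
                     chrom = "1", pos = 1000L * seq_len(p),
                     effect_allele = "A", other_allele = "G", freq = freq,
                     stringsAsFactors = FALSE)
  genotype_matrix(counts, meta, sprintf("s%05d", seq_len(nrow(counts))))
}

# Large standard-normal percentile reference shared by evaluation tests
# (built once per test run).
normal_reference <- local({
  ref <- NULL
  function() {
    if (is.null(ref)) {
      set.seed(424242)
      ref <<- build_percentile_reference(rnorm(200000))
    }
    ref
  }
})
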