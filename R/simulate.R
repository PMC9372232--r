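#' Configuration for the synthetic cohort generator
#'
#' The generator emulates the statistical structure of a case-enriched
#' genotyped cohort for age-at-onset modelling: Hardy-Weinberg allele counts
#' with configurable frequencies, near-duplicate SNP pairs, Weibull
#' proportional-hazards onset driven by a sparse set of causal SNPs,
#' uniform censoring of controls at last follow-up, case oversampling
#' relative to population prevalence, a clinical-significance sub-phenotype,
#' prostate cancer death ages for a subset of significant cases, family
#' history positively associated with true genetic burden, and a PSA
#' screening layer with a configurable case:control ratio among
#' screen-positives.
#'
#' @param n_subjects number of subjects in the population cohort.
#' @param n_snps number of SNPs (including the duplicate companions).
#' @param allele_freqs per-SNP effect-allele frequencies strictly inside
#'   (0, 1); default is an even grid over \[0.1, 0.9\].
#' @param n_causal number of causal SNPs (the first `n_causal` columns);
#'   default one per five SNPs, capped at 20.
#' @param causal_betas per-allele log-hazard effects for the causal SNPs;
#'   default an even grid over \[0.1, 0.5\] with alternating sign on every
#'   fifth SNP.
#' @param ld_dup_pairs number of near-duplicate SNP pairs: the last
#'   `ld_dup_pairs` SNPs are per-allele copies of the first `ld_dup_pairs`;
#'   default one pair per twenty SNPs, capped at 5.
#' @param ld_fidelity per-allele copy fidelity in (0.95, 1\]; fidelity f
#'   yields population r-squared f^2 between the pair members.
#' @param baseline_shape,baseline_scale Weibull baseline-hazard parameters
#'   (shape > 1 mimics incidence rising steeply with age; scale in years).
#' @param censor_min,censor_max uniform bounds (years) for the control
#'   last-follow-up age.
#' @param target_prevalence population lifetime case probability in (0, 1),
#'   carried on the cohort so sample weights are computable downstream.
#' @param case_control_ratio cases per control after case-control sampling
#'   (2 emulates a training set with cases oversampled 2:1).
#' @param p_significant probability that a case is clinically significant.
#' @param p_fatal probability that a significant case is fatal.
#' @param fatal_mean_survival mean years from diagnosis to prostate cancer
#'   death for fatal cases (exponential).
#' @param fh_intercept,fh_slope logistic model linking family history to the
#'   standardized true genetic linear predictor.
#' @param fh_missing fraction of subjects with family history missing
#'   completely at random.
#' @param screen_ratio cases per control among PSA-positive subjects
#'   (0.5 encodes the 1:2 case:control screening design).
#' @param seed integer master seed; every simulation step derives its own
#'   sub-seed from it, so equal configs give byte-identical outputs.
#' @return a `sim_config` list, validated.
#' @export
sim_config <- function(n_subjects = 10000L,
                       n_snps = 100L,
                       allele_freqs = NULL,
                       n_causal = NULL,
                       causal_betas = NULL,
                       ld_dup_pairs = NULL,
                       ld_fidelity = 0.99,
                       baseline_shape = 4.5,
                       baseline_scale = 140,
                       censor_min = 55,
                       censor_max = 85,
                       target_prevalence = 0.12,
                       case_control_ratio = 2,
                       p_significant = 0.55,
                       p_fatal = 0.15,
                       fatal_mean_survival = 5,
                       fh_intercept = qlogis(0.10),
                       fh_slope = 0.8,
                       fh_missing = 0.2,
                       screen_ratio = 0.5,
                       seed = 1L) {
  n_subjects <- assert_count(n_subjects, "n_subjects")
  n_snps <- assert_count(n_snps, "n_snps")
  # defaults scale with the panel: 1 causal SNP per 5, up to 20; 1
  # duplicate pair per 20 SNPs, up to 5
  if (is.null(n_causal)) n_causal <- min(20L, max(1L, n_snps %/% 5L))
  if (is.null(ld_dup_pairs)) ld_dup_pairs <- min(5L, n_snps %/% 20L)
  n_causal <- assert_count(n_causal, "n_causal", positive = FALSE)
  ld_dup_pairs <- assert_count(ld_dup_pairs, "ld_dup_pairs", positive = FALSE)
  if (is.null(allele_freqs)) {
    allele_freqs <- seq(0.1, 0.9, length.out = n_snps)
  }
  if (length(allele_freqs) != n_snps) {
    stop_polyhaz("allele_freqs must have length n_snps")
  }
  assert_prob(allele_freqs, "allele_freqs", open = TRUE)
  if (n_causal > n_snps) stop_polyhaz("n_causal must not exceed n_snps")
  if (is.null(causal_betas)) {
    causal_betas <- if (n_causal > 0) {
      b <- seq(0.1, 0.5, length.out = max(n_causal, 2L))[seq_len(n_causal)]
      b * ifelse(seq_len(n_causal) %% 5L == 0L, -1, 1)
    } else numeric(0)
  }
  if (length(causal_betas) != n_causal) {
    stop_polyhaz("causal_betas must have length n_causal")
  }
  if (anyNA(causal_betas) || any(!is.finite(causal_betas))) {
    stop_polyhaz("causal_betas must be finite")
  }
  if (2L * ld_dup_pairs > n_snps) {
    stop_polyhaz("too many duplicate pairs for n_snps")
  }
  if (!(ld_fidelity > 0.95 && ld_fidelity <= 1)) {
    stop_polyhaz("ld_fidelity must lie in (0.95, 1]")
  }
  if (baseline_shape <= 0 || baseline_scale <= 0) {
    stop_polyhaz("Weibull parameters must be positive")
  }
  if (!(censor_min > 0 && censor_max > censor_min)) {
    stop_polyhaz("need 0 < censor_min < censor_max")
  }
  assert_prob(target_prevalence, "target_prevalence", open = TRUE)
  if (case_control_ratio <= 0) stop_polyhaz("case_control_ratio must be > 0")
  assert_prob(p_significant, "p_significant")
  assert_prob(p_fatal, "p_fatal")
  if (fatal_mean_survival <= 0) stop_polyhaz("fatal_mean_survival must be > 0")
  assert_prob(fh_missing, "fh_missing")
  if (screen_ratio <= 0) stop_polyhaz("screen_ratio must be > 0")
  structure(list(
    n_subjects = n_subjects, n_snps = n_snps, allele_freqs = allele_freqs,
    n_causal = n_causal, causal_betas = causal_betas,
    ld_dup_pairs = ld_dup_pairs, ld_fidelity = ld_fidelity,
    baseline_shape = baseline_shape, baseline_scale = baseline_scale,
    censor_min = censor_min, censor_max = censor_max,
    target_prevalence = target_prevalence,
    case_control_ratio = case_control_ratio,
    p_significant = p_significant, p_fatal = p_fatal,
    fatal_mean_survival = fatal_mean_survival,
    fh_intercept = fh_intercept, fh_slope = fh_slope,
    fh_missing = fh_missing, screen_ratio = screen_ratio,
    seed = as.integer(seed)), class = "sim_config")
}

#' Simulate Hardy-Weinberg genotypes with near-duplicate SNP pairs
#'
#' Allele counts are drawn as Binomial(2, freq) per SNP. For each configured
#' duplicate pair, the companion SNP (one of the last `ld_dup_pairs`
#' columns) copies each of its partner's two alleles with probability
#' `ld_fidelity`, redrawing from the population frequency otherwise, which
#' guarantees pairs with r-squared above 0.95 exist in the panel.
#'
#' @param config a [sim_config()].
#' @return a [genotype_matrix()]; the duplicate pairing is recorded in the
#'   `ld_pairs` attribute.
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  seeds <- derive_seeds(config$seed, 10L)
  n <- config$n_subjects
  p <- config$n_snps
  freq <- config$allele_freqs
  with_seed(seeds[1L], {
    a1 <- matrix(rbinom(n * p, 1L, rep(freq, each = n)), n, p)
    a2 <- matrix(rbinom(n * p, 1L, rep(freq, each = n)), n, p)
    if (config$ld_dup_pairs > 0L) {
      src <- seq_len(config$ld_dup_pairs)
      dst <- p - config$ld_dup_pairs + src
      for (k in seq_along(src)) {
        keep1 <- rbinom(n, 1L, config$ld_fidelity) == 1L
        keep2 <- rbinom(n, 1L, config$ld_fidelity) == 1L
        a1[, dst[k]] <- ifelse(keep1, a1[, src[k]],
                               rbinom(n, 1L, freq[src[k]]))
        a2[, dst[k]] <- ifelse(keep2, a2[, src[k]],
                               rbinom(n, 1L, freq[src[k]]))
        freq[dst[k]] <- freq[src[k]]
      }
    }
    counts <- a1 + a2
  })
  meta <- data.frame(
    id = sprintf("snp%04d", seq_len(p)),
    chrom = "1",
    pos = 10000L * seq_len(p),
    effect_allele = "A",
    other_allele = "G",
    freq = freq,
    stringsAsFactors = FALSE)
  g <- genotype_matrix(counts, meta,
                       sprintf("subj%06d", seq_len(n)))
  if (config$ld_dup_pairs > 0L) {
    attr(g, "ld_pairs") <- data.frame(
      source = meta$id[seq_len(config$ld_dup_pairs)],
      duplicate = meta$id[p - config$ld_dup_pairs + seq_len(config$ld_dup_pairs)],
      fidelity = config$ld_fidelity)
  }
  g
}

#' Draw a table of clinical records for cases
#'
#' With probability `p_significant` a record is drawn from the
#' "significant-type" mixture (at least one of: Gleason 7-10, PSA above 10
#' ng/mL, stage T3/T4, nodal or distant metastases), otherwise from a benign
#' profile (Gleason 6, PSA below 10, stage T1/T2, no metastases), so the
#' realized clinical-significance rate among cases is Bernoulli with the
#' configured probability.
#'
#' @param n number of records.
#' @param p_significant probability of a significant-type record.
#' @return data.frame with columns `gleason`, `psa`, `t_stage`,
#'   `node_positive`, `metastatic`.
#' @export
simulate_clinical_records <- function(n, p_significant) {
  assert_prob(p_significant, "p_significant")
  sig <- runif(n) < p_significant
  gleason <- ifelse(sig & runif(n) < 0.8, sample(7:10, n, TRUE,
                                                 prob = c(0.5, 0.3, 0.15, 0.05)),
                    6L)
  psa <- exp(rnorm(n, log(5), 0.5))
  psa <- pmin(psa, 9.9)
  hi_psa <- sig & runif(n) < 0.4
  psa[hi_psa] <- 10 + rexp(sum(hi_psa), 1 / 15)
  t_stage <- ifelse(runif(n) < 0.6, "T1", "T2")
  hi_stage <- sig & runif(n) < 0.3
  t_stage[hi_stage] <- sample(c("T3", "T4"), sum(hi_stage), TRUE,
                              prob = c(0.8, 0.2))
  node_positive <- sig & runif(n) < 0.1
  metastatic <- sig & runif(n) < 0.08
  # ensure every significant-type record meets at least one criterion
  none <- sig & gleason < 7 & psa < 10 & !(t_stage %in% c("T3", "T4")) &
    !node_positive & !metastatic
  gleason[none] <- 7L
  data.frame(gleason = as.integer(gleason), psa = psa, t_stage = t_stage,
             node_positive = node_positive, metastatic = metastatic,
             stringsAsFactors = FALSE)
}

#' Classify a clinical record as clinically significant
#'
#' A prostate cancer case is clinically significant when any of the
#' following holds: Gleason score >= 7, PSA >= 10 ng/mL, stage T3-T4,
#' nodal metastases, or distant metastases.
#'
#' @param rec data.frame with columns `gleason` (integer in 2..10), `psa`
#'   (ng/mL, non-negative), `t_stage` ("T1".."T4"), `node_positive`,
#'   `metastatic` (logical). Missing values in any field are an error; no
#'   silent default is applied.
#' @return logical vector, one entry per record row.
#' @export
#' @examples
#' classify_significance(data.frame(gleason = 7, psa = 4, t_stage = "T1",
#'                                  node_positive = FALSE, metastatic = FALSE))
classify_significance <- function(rec) {
  need <- c("gleason", "psa", "t_stage", "node_positive", "metastatic")
  miss <- setdiff(need, names(rec))
  if (length(miss)) {
    stop_polyhaz("clinical record missing fields: ",
                 paste(miss, collapse = ", "))
  }
  if (anyNA(rec[need])) {
    stop_polyhaz("clinical record contains missing values; ",
                 "significance cannot be classified")
  }
  if (any(rec$gleason < 2 | rec$gleason > 10)) {
    stop_polyhaz("gleason must lie in [2, 10]")
  }
  if (any(rec$psa < 0)) stop_polyhaz("psa must be non-negative")
  if (!all(rec$t_stage %in% c("T1", "T2", "T3", "T4"))) {
    stop_polyhaz("t_stage must be one of T1-T4")
  }
  rec$gleason >= 7 | rec$psa >= 10 | rec$t_stage %in% c("T3", "T4") |
    rec$node_positive | rec$metastatic
}

# Inverse-CDF draw from the Weibull proportional-hazards model:
# S(t | lp) = exp(-(t/scale)^shape * exp(lp)).
weibull_ph_onset <- function(lp, shape, scale) {
  scale * (rexp(length(lp)) / exp(lp))^(1 / shape)
}

#' Simulate age-at-onset phenotypes from genotypes
#'
#' Latent onset ages follow a Weibull proportional-hazards model with linear
#' predictor `sum(beta_i x_i)` over the causal SNPs (centered at its
#' expectation `sum(2 freq_i beta_i)` so the configured baseline governs
#' marginal risk). A subject is a case if onset precedes the uniform
#' censoring age, otherwise a control censored at last follow-up. Clinical
#' significance is assigned to cases via [simulate_clinical_records()] and
#' [classify_significance()]; fatal outcomes (diagnosis age plus an
#' exponential survival time) are drawn only among significant cases; family
#' history follows a logistic model in the standardized true linear
#' predictor, with a configurable fraction missing completely at random;
#' the four ancestry principal components are the first four left singular
#' vectors of the column-centered genotype matrix, scaled to unit variance.
#'
#' @param genotypes a [genotype_matrix()].
#' @param config the [sim_config()] used to generate them.
#' @return a [cohort_phenotype()]; the true linear predictor and the drawn
#'   clinical records are attached as attributes `true_lp` and
#'   `clinical_records`.
#' @export
simulate_onset <- function(genotypes, config) {
  stopifnot(inherits(genotypes, "genotype_matrix"),
            inherits(config, "sim_config"))
  counts <- genotypes$counts
  n <- nrow(counts)
  if (config$n_causal > ncol(counts)) {
    stop_polyhaz("genotype matrix has fewer SNPs than n_causal")
  }
  seeds <- derive_seeds(config$seed, 10L)
  causal <- seq_len(config$n_causal)
  betas <- config$causal_betas
  lp <- if (length(causal)) {
    drop(counts[, causal, drop = FALSE] %*% betas) -
      sum(2 * genotypes$snp_meta$freq[causal] * betas)
  } else rep(0, n)

  with_seed(seeds[2L], {
    onset <- weibull_ph_onset(lp, config$baseline_shape,
                              config$baseline_scale)
    censor <- runif(n, config$censor_min, config$censor_max)
    is_case <- onset <= censor
    event_age <- ifelse(is_case, onset, censor)

    rec <- simulate_clinical_records(sum(is_case), config$p_significant)
    significant <- rep(NA, n)
    significant[is_case] <- classify_significance(rec)

    fatal <- rep(FALSE, n)
    death_age <- rep(NA_real_, n)
    sig_idx <- which(significant %in% TRUE)
    if (length(sig_idx)) {
      is_fatal <- runif(length(sig_idx)) < config$p_fatal
      fatal[sig_idx[is_fatal]] <- TRUE
      death_age[sig_idx[is_fatal]] <-
        event_age[sig_idx[is_fatal]] +
        rexp(sum(is_fatal), 1 / config$fatal_mean_survival)
    }

    lp_std <- if (sd(lp) > 0) (lp - mean(lp)) / sd(lp) else lp
    fh_yes <- runif(n) < plogis(config$fh_intercept + config$fh_slope * lp_std)
    family_history <- ifelse(fh_yes, "yes", "no")
    family_history[runif(n) < config$fh_missing] <- "unknown"
  })

  pcs <- genotype_pcs(counts, 4L)
  phen <- cohort_phenotype(data.frame(
    subject_id = genotypes$subject_ids,
    status = ifelse(is_case, "case", "control"),
    event_age = event_age,
    significant = significant,
    fatal = fatal,
    death_age = death_age,
    family_history = family_history,
    psa_positive = NA,
    biopsy_significant = NA,
    pc1 = pcs[, 1L], pc2 = pcs[, 2L], pc3 = pcs[, 3L], pc4 = pcs[, 4L],
    stringsAsFactors = FALSE), prevalence = mean(is_case))
  attr(phen, "true_lp") <- setNames(lp, genotypes$subject_ids)
  attr(phen, "clinical_records") <- rec
  phen
}

# First k left singular vectors of the column-centered genotype matrix,
# scaled to unit variance (the standard ancestry-PC construction).
genotype_pcs <- function(counts, k = 4L) {
  x <- counts
  x[is.na(x)] <- 0
  x <- scale(x, center = TRUE, scale = FALSE)
  k_eff <- min(k, nrow(x) - 1L, ncol(x))
  sv <- svd(x, nu = k_eff, nv = 0)
  u <- sv$u
  keep <- sv$d[seq_len(k_eff)] > 1e-8
  u[, keep] <- scale(u[, keep, drop = FALSE])
  if (k_eff < k) u <- cbind(u, matrix(0, nrow(x), k - k_eff))
  u[, seq_len(k)]
}

#' Subsample a population cohort to a target case:control ratio
#'
#' All cases are retained when possible (controls are subsampled), emulating
#' a case-enriched study assembled from a population. The population
#' prevalence travels with the result (attribute `prevalence`) so sample
#' weights remain computable downstream.
#'
#' @param phen a population [cohort_phenotype()].
#' @param config a [sim_config()] supplying `case_control_ratio` (cases per
#'   control) and the seed, or a bare numeric ratio.
#' @param seed optional seed override.
#' @return list with elements `phen` (the sampled `cohort_phenotype`) and
#'   `subject_ids` (kept ids, usable to subset the genotype matrix).
#' @export
apply_case_control_sampling <- function(phen, config, seed = NULL) {
  ratio <- if (inherits(config, "sim_config")) config$case_control_ratio else config
  if (is.null(seed)) {
    seed <- if (inherits(config, "sim_config")) derive_seeds(config$seed, 10L)[3L] else
      stop_polyhaz("seed required when config is a bare ratio")
  }
  if (!is.numeric(ratio) || ratio <= 0) stop_polyhaz("ratio must be > 0")
  cases <- which(phen$status == "case")
  controls <- which(phen$status == "control")
  if (!length(cases) || !length(controls)) {
    stop_polyhaz("need both cases and controls to subsample")
  }
  n_case_keep <- min(length(cases), floor(ratio * length(controls)))
  n_ctrl_keep <- min(length(controls), round(n_case_keep / ratio))
  if (n_case_keep < 1L || n_ctrl_keep < 1L) {
    stop_polyhaz("requested case:control ratio unattainable from ",
                 length(cases), " cases / ", length(controls), " controls")
  }
  keep <- with_seed(seed, {
    sort(c(sample(cases, n_case_keep), sample(controls, n_ctrl_keep)))
  })
  out <- phen[keep, , drop = FALSE]
  prev <- attr(phen, "prevalence")
  out <- cohort_phenotype(out, prevalence = prev)
  attr(out, "true_lp") <- attr(phen, "true_lp")[keep]
  list(phen = out, subject_ids = out$subject_id)
}

#' Attach a PSA screening and biopsy layer to a cohort
#'
#' All cases are PSA-positive (>= 3 ng/mL by construction); enough controls
#' are flagged PSA-positive to realize the configured case:control ratio
#' among screen-positives (1:2 by default). Biopsy outcome equals clinical
#' significance for cases and is negative for screened controls; unscreened
#' subjects keep missing biopsy fields.
#'
#' @param phen a [cohort_phenotype()].
#' @param config a [sim_config()] supplying `screen_ratio` (cases per
#'   control among screen-positives) and the seed.
#' @param seed optional seed override.
#' @return the cohort with `psa_positive` and `biopsy_significant` filled in.
#' @export
simulate_screening <- function(phen, config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(seed)) seed <- derive_seeds(config$seed, 10L)[4L]
  cases <- which(phen$status == "case")
  controls <- which(phen$status == "control")
  n_pos_ctrl <- round(length(cases) / config$screen_ratio)
  if (n_pos_ctrl > length(controls)) {
    stop_polyhaz("not enough controls to realize screen-positive ratio 1:",
                 round(1 / config$screen_ratio))
  }
  pos_ctrl <- with_seed(seed, sample(controls, n_pos_ctrl))
  phen$psa_positive <- FALSE
  phen$psa_positive[cases] <- TRUE
  phen$psa_positive[pos_ctrl] <- TRUE
  phen$biopsy_significant <- NA
  phen$biopsy_significant[cases] <- phen$significant[cases] %in% TRUE
  phen$biopsy_significant[pos_ctrl] <- FALSE
  cohort_phenotype(phen, prevalence = attr(phen, "prevalence"))
}

#' Simulate a complete cohort (genotypes, onset, sampling, screening)
#'
#' Convenience wrapper running [simulate_genotypes()], [simulate_onset()],
#' [apply_case_control_sampling()] and [simulate_screening()] in sequence.
#'
#' @param config a [sim_config()].
#' @param sample_cases whether to apply case-control subsampling.
#' @param screening whether to attach the PSA screening layer.
#' @return list with `genotypes` (restricted to sampled subjects) and
#'   `phen`.
#' @export
simulate_cohort <- function(config, sample_cases = TRUE, screening = TRUE) {
  g <- simulate_genotypes(config)
  phen <- simulate_onset(g, config)
  if (sample_cases) {
    samp <- apply_case_control_sampling(phen, config)
    phen <- samp$phen
    idx <- match(samp$subject_ids, g$subject_ids)
    g <- genotype_matrix(g$counts[idx, , drop = FALSE], g$snp_meta,
                         g$subject_ids[idx])
  }
  if (screening) phen <- simulate_screening(phen, config)
  list(genotypes = g, phen = phen)
}
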