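#' Run the full PHS development-and-evaluation pipeline
#'
#' End-to-end driver: simulate a training cohort (genotypes + phenotypes,
#' case-enriched), prune correlated SNPs, fit the cross-validated LASSO Cox
#' model, export the SNP weight table, build the young-control percentile
#' reference, simulate an independent testing cohort, estimate bootstrap
#' band hazard ratios for every endpoint with events, run the
#' family-history comparison, estimate screening PPVs, and produce
#' risk-adjusted incidence curves from the bundled synthetic population
#' tables. All artifacts are plain text and fully determined by `seed` and
#' the configs, so two runs with equal arguments are byte-identical.
#'
#' @param seed master integer seed.
#' @param out_dir directory for artifacts (created if needed); `NULL`
#'   skips writing.
#' @param train_config,test_config [sim_config()]s for the training and
#'   testing cohorts (seeds are derived from `seed`, overriding theirs).
#' @param n_boot bootstrap replicates for HR and PPV reports.
#' @param n_lambda,lambda_min_ratio LASSO path controls.
#' @param incidence_path,fraction_path CSV inputs for the incidence module;
#'   defaults are the package's bundled synthetic tables.
#' @return (invisibly) a list with every intermediate object.
#' @export
run_phs_pipeline <- function(seed = 1L, out_dir = NULL,
                             train_config = sim_config(),
                             test_config = sim_config(n_subjects = 8000L,
                                                      case_control_ratio = 0.5),
                             n_boot = 500L, n_lambda = 100L,
                             lambda_min_ratio = 1e-4,
                             incidence_path = system.file(
                               "extdata", "synthetic_uk_incidence.csv",
                               package = "polyhaz"),
                             fraction_path = system.file(
                               "extdata", "synthetic_significant_fraction.csv",
                               package = "polyhaz")) {
  seeds <- derive_seeds(seed, 6L)
  train_config$seed <- seeds[1L]
  test_config$seed <- seeds[2L]

  # -- training data ---------------------------------------------------
  train <- simulate_cohort(train_config, sample_cases = TRUE,
                           screening = FALSE)

  # -- SNP pruning -----------------------------------------------------
  pr <- prune(train$genotypes, train$phen, threshold = 0.95)

  # -- penalized Cox fit with 10-fold CV -------------------------------
  des <- build_design(pr$kept, train$phen)
  fit <- cross_validate(des$X, train$phen, des$penalty_mask, k = 10L,
                        seed = seeds[3L], n_lambda = n_lambda,
                        lambda_min_ratio = lambda_min_ratio)
  weights_tab <- export_weights(fit, pr$kept$snp_meta)

  # -- scoring and percentile reference --------------------------------
  train_scores <- compute_phs(train$genotypes, weights_tab)
  young_controls <- train$phen$status == "control" &
    train$phen$event_age < 70
  ref <- build_percentile_reference(train_scores[young_controls])

  # -- testing cohort evaluation ---------------------------------------
  test <- simulate_cohort(test_config, sample_cases = TRUE,
                          screening = TRUE)
  test_scores <- compute_phs(test$genotypes, weights_tab)
  pi0 <- test_config$target_prevalence
  hr <- list()
  for (ep in c("any", "significant", "fatal")) {
    hr[[ep]] <- tryCatch(
      hr_report(test_scores, test$phen, ref, endpoint = ep,
                target_prevalence = pi0, n_boot = n_boot,
                seed = seeds[4L]),
      error = function(e) NULL)
  }
  fh <- family_history_comparison(test_scores, test$phen, ref,
                                  endpoint = "any",
                                  weights = sample_weights(test$phen, pi0))

  # -- screening PPV ---------------------------------------------------
  ppv <- ppv_bootstrap(test_scores, test$phen, ref, n_boot = n_boot,
                       ratio = test_config$screen_ratio, seed = seeds[5L])

  # -- incidence curves ------------------------------------------------
  baseline <- load_incidence(incidence_path)
  fraction <- read.table(fraction_path, header = TRUE, sep = ",")
  curves <- incidence_curve_set(
    baseline, fraction,
    hr_significant = if (!is.null(hr$significant)) hr$significant$hr else
      hr$any$hr,
    hr_nonsignificant = hr$any$hr)

  res <- list(train = train, pruning = pr, fit = fit,
              weights = weights_tab, reference = ref,
              train_scores = train_scores, test = test,
              test_scores = test_scores, hr = hr, fh = fh, ppv = ppv,
              curves = curves, seed = seed)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    fp <- function(x) file.path(out_dir, x)
    write_genotypes(train$genotypes, fp("train.vcf"), "vcf")
    write_phenotypes(train$phen, fp("train_phen.tsv"))
    write.table(pr$report, fp("pruning_report.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write_weights(weights_tab, fp("weights.tsv"))
    jsonlite::write_json(list(
      lambda = fit$lambda, cv_deviance = fit$cv_deviance,
      lambda_min = fit$lambda_min,
      n_nonzero_snps = fit$n_nonzero_snps), fp("model.json"),
      digits = NA, auto_unbox = TRUE)
    jsonlite::write_json(list(
      thresholds = as.list(ref$thresholds),
      interval_means = as.list(ref$interval_means),
      mid_band = ref$mid_band, n_reference = ref$n_reference,
      source = ref$source), fp("reference.json"),
      digits = NA, auto_unbox = TRUE)
    write_phenotypes(test$phen, fp("test_phen.tsv"))
    write.table(data.frame(subject_id = names(test_scores),
                           phs = sprintf("%.17g", test_scores)),
                fp("test_scores.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    hr_json <- lapply(hr[!vapply(hr, is.null, logical(1))], function(h) {
      list(endpoint = h$endpoint, hr = as.list(h$hr),
           ci_low = as.list(h$ci_low), ci_high = as.list(h$ci_high),
           n_boot = h$n_boot)
    })
    jsonlite::write_json(hr_json, fp("hr_reports.json"), digits = NA,
                         auto_unbox = TRUE)
    jsonlite::write_json(list(
      ppv = as.list(ppv$ppv), ci_low = as.list(ppv$ci_low),
      ci_high = as.list(ppv$ci_high), plug_in = as.list(ppv$plug_in),
      n_psa_positive = ppv$n_psa_positive, n_boot = ppv$n_boot,
      ratio = ppv$ratio), fp("ppv.json"), digits = NA, auto_unbox = TRUE)
    write.table(format(as.data.frame(curves), digits = 15),
                fp("incidence_curves.csv"), sep = ",", quote = FALSE,
                row.names = FALSE)
  }
  invisible(res)
}
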