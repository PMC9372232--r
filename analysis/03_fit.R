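#!/usr/bin/env Rscript
# Fit the LASSO-regularized Cox model (SNP allele counts + four ancestry
# PCs, PCs unpenalized) with lambda chosen by 10-fold cross-validation,
# and export the non-zero SNP weights.

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(FALSE), value = TRUE))), "00_config.R"))

g <- read_genotypes(file.path(DATA_DIR, "train.vcf"), "vcf")
phen <- read_phenotypes(file.path(DATA_DIR, "train_phen.tsv"))
kept <- readLines(file.path(RESULTS, "kept_snps.txt"))
g <- subset_snps(g, kept)

des <- build_design(g, phen)
fit <- cross_validate(des$X, phen, des$penalty_mask, k = 10L,
                      seed = seeds[3], n_lambda = 100L)
w <- export_weights(fit, g$snp_meta)
write_weights(w, file.path(RESULTS, "weights.tsv"))
jsonlite::write_json(list(lambda = fit$lambda,
                          cv_deviance = fit$cv_deviance,
                          cv_se = fit$cv_se,
                          lambda_min = fit$lambda_min,
                          n_nonzero_snps = fit$n_nonzero_snps),
                     file.path(RESULTS, "model.json"),
                     auto_unbox = TRUE, digits = NA)

message(sprintf("lambda_min %.5g (path index %d of %d); %d SNPs with non-zero coefficients",
                fit$lambda_min, fit$index_min, length(fit$lambda),
                fit$n_nonzero_snps))
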