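#!/usr/bin/env Rscript
# Simulate the training and testing cohorts and write them in the
# pipeline's interchange formats (VCF + phenotype TSV).

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(FALSE), value = TRUE))), "00_config.R"))

train <- simulate_cohort(train_config, sample_cases = TRUE, screening = FALSE)
test <- simulate_cohort(test_config, sample_cases = TRUE, screening = TRUE)

write_genotypes(train$genotypes, file.path(DATA_DIR, "train.vcf"), "vcf")
write_phenotypes(train$phen, file.path(DATA_DIR, "train_phen.tsv"))
write_genotypes(test$genotypes, file.path(DATA_DIR, "test.vcf"), "vcf")
write_phenotypes(test$phen, file.path(DATA_DIR, "test_phen.tsv"))

message(sprintf("training cohort: %d subjects (%d cases), prevalence link %.3f",
                nrow(train$phen), sum(train$phen$status == "case"),
                attr(train$phen, "prevalence")))
message(sprintf("testing cohort: %d subjects (%d cases), %d PSA-positive",
                nrow(test$phen), sum(test$phen$status == "case"),
                sum(test$phen$psa_positive, na.rm = TRUE)))
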