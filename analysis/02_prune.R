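#!/usr/bin/env Rscript
# Remove one member of each highly correlated SNP pair (r^2 > 0.95),
# keeping the member with the stronger univariable association with age
# at diagnosis.

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(FALSE), value = TRUE))), "00_config.R"))

g <- read_genotypes(file.path(DATA_DIR, "train.vcf"), "vcf")
phen <- read_phenotypes(file.path(DATA_DIR, "train_phen.tsv"))

pr <- prune(g, phen, threshold = 0.95)
write.table(pr$report, file.path(RESULTS, "pruning_report.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
writeLines(pr$kept_ids, file.path(RESULTS, "kept_snps.txt"))

message(sprintf("flagged pairs removed: %d; candidates kept: %d of %d",
                nrow(pr$report), length(pr$kept_ids), ncol(g$counts)))
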