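#!/usr/bin/env Rscript
# Score every subject with the fitted PHS and build the percentile
# reference from training controls younger than 70.

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(FALSE), value = TRUE))), "00_config.R"))

w <- read_weights(file.path(RESULTS, "weights.tsv"))
train_g <- read_genotypes(file.path(DATA_DIR, "train.vcf"), "vcf")
train_phen <- read_phenotypes(file.path(DATA_DIR, "train_phen.tsv"))
test_g <- read_genotypes(file.path(DATA_DIR, "test.vcf"), "vcf")

train_scores <- compute_phs(train_g, w)
test_scores <- compute_phs(test_g, w)

young <- train_phen$status == "control" & train_phen$event_age < 70
ref <- build_percentile_reference(train_scores[young])
jsonlite::write_json(list(thresholds = as.list(ref$thresholds),
                          interval_means = as.list(ref$interval_means),
                          mid_band = ref$mid_band,
                          n_reference = ref$n_reference,
                          source = ref$source),
                     file.path(RESULTS, "reference.json"),
                     auto_unbox = TRUE, digits = NA)
write.table(data.frame(subject_id = names(test_scores),
                       phs = sprintf("%.17g", test_scores)),
            file.path(RESULTS, "test_scores.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

message(sprintf("reference built on %d young controls; thresholds p20 %.3f / p80 %.3f / p95 %.3f",
                ref$n_reference, ref$thresholds[["p20"]],
                ref$thresholds[["p80"]], ref$thresholds[["p95"]]))
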