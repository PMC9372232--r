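#!/usr/bin/env Rscript
# Positive predictive value of PSA testing for clinically significant
# disease, overall and within the top 20% / top 5% of PHS.

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(FALSE), value = TRUE))), "00_config.R"))

phen <- read_phenotypes(file.path(DATA_DIR, "test_phen.tsv"))
sc_tab <- read.table(file.path(RESULTS, "test_scores.tsv"), header = TRUE,
                     sep = "\t")
scores <- setNames(sc_tab$phs, sc_tab$subject_id)[phen$subject_id]
refj <- jsonlite::read_json(file.path(RESULTS, "reference.json"),
                            simplifyVector = TRUE)
ref <- structure(list(thresholds = unlist(refj$thresholds),
                      interval_means = unlist(refj$interval_means),
                      mid_band = refj$mid_band,
                      n_reference = refj$n_reference,
                      source = refj$source), class = "phs_reference")

ppv <- ppv_bootstrap(scores, phen, ref, n_boot = N_BOOT,
                     ratio = test_config$screen_ratio, seed = seeds[5])
jsonlite::write_json(list(ppv = as.list(ppv$ppv),
                          ci_low = as.list(ppv$ci_low),
                          ci_high = as.list(ppv$ci_high),
                          plug_in = as.list(ppv$plug_in),
                          n_psa_positive = ppv$n_psa_positive,
                          n_boot = ppv$n_boot, ratio = ppv$ratio),
                     file.path(RESULTS, "ppv.json"),
                     auto_unbox = TRUE, digits = NA)
print(ppv)
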