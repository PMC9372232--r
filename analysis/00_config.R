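# Shared settings for the analysis workflow.  Each numbered script is a
# thin driver over the polyhaz package; all outputs land under results/.

library(polyhaz)

SEED <- 20260920L
RESULTS <- "results"
DATA_DIR <- file.path(RESULTS, "data")
dir.create(DATA_DIR, recursive = TRUE, showWarnings = FALSE)

seeds <- polyhaz:::derive_seeds(SEED, 10L)

# Training cohort: large population, cases oversampled 2:1 (consortium-like
# enrichment). Testing cohort: population-based with a screening layer at
# a 1:2 case:control ratio among PSA-positives.
train_config <- sim_config(n_subjects = 40000L, n_snps = 100L,
                           case_control_ratio = 2, seed = seeds[1])
test_config <- sim_config(n_subjects = 10000L, n_snps = 100L,
                          case_control_ratio = 0.5, seed = seeds[2])

N_BOOT <- 1000L
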