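# Correlation pruning: the r-squared primitive, the univariable Cox screen,
# and the greedy larger-p elimination rule.

test_that("pairwise_r2 matches the Pearson formula", {
  g <- make_geno(cbind(c(0, 1, 2, 0), c(0, 1, 1, 1)))
  expect_equal(pairwise_r2(g, 1, 2), 3 / 11)
  # identical columns and perfect anticorrelation both square to 1
  g2 <- make_geno(cbind(c(0, 1, 2, 0), c(0, 1, 2, 0), 2 - c(0, 1, 2, 0)))
  expect_equal(pairwise_r2(g2, 1, 2), 1.0)
  expect_equal(pairwise_r2(g2, 1, 3), 1.0)
})

test_that("pairwise_r2 rejects degenerate inputs", {
  g <- make_geno(cbind(c(1, 1, 1, 1), c(0, 1, 2, 0)))
  expect_error(pairwise_r2(g, 1, 2), "zero variance")
  g3 <- make_geno(cbind(c(0, NA, NA, NA), c(0, 1, 2, NA)))
  expect_error(pairwise_r2(g3, 1, 2), "pairwise-complete")
})

test_that("univariable Cox p-values are calibrated under the null", {
  # 200 independent null SNPs against one outcome: p ~ Uniform(0,1)
  set.seed(81)
  n <- 5000
  phen <- simulate_ph_cohort(rep(0, n), seed = 82)
  pvals <- vapply(1:200, function(j) {
    x <- rbinom(n, 2, 0.3)
    univariable_cox_p(x, phen)
  }, numeric(1))
  frac <- mean(pvals < 0.05)
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / 200))
})

test_that("univariable Cox detects a strong causal SNP", {
  set.seed(83)
  x <- rbinom(5000, 2, 0.3)
  phen <- simulate_ph_cohort(0.5 * (x - mean(x)), seed = 84)
  expect_lt(univariable_cox_p(x, phen), 1e-6)
})

test_that("degenerate fits raise a convergence error rather than passing silently", {
  phen <- make_phen(time = c(50, 60), case = c(TRUE, FALSE))
  expect_error(univariable_cox_p(c(2, 0), phen), "converge")
})

test_that("prune removes exactly one member of a duplicate pair", {
  cfg <- sim_config(n_subjects = 1500, n_snps = 12, n_causal = 3,
                    causal_betas = c(0.4, 0.3, 0.2), ld_dup_pairs = 0,
                    seed = 91)
  g <- simulate_genotypes(cfg)
  phen <- simulate_onset(g, cfg)
  # append an exact duplicate of snp0001
  counts <- cbind(g$counts, dup = g$counts[, 1])
  meta <- rbind(g$snp_meta,
                data.frame(id = "snp_dup", chrom = "1", pos = 999999L,
                           effect_allele = "A", other_allele = "G",
                           freq = g$snp_meta$freq[1]))
  g2 <- genotype_matrix(counts, meta, g$subject_ids)
  pr <- prune(g2, phen)
  expect_equal(nrow(pr$report), 1L)
  expect_setequal(c(pr$report$removed_id, pr$report$kept_id),
                  c("snp0001", "snp_dup"))
  expect_equal(length(pr$kept_ids), 12L)
})

test_that("the larger-p member of each flagged pair is removed", {
  cfg <- sim_config(n_subjects = 2000, n_snps = 20, n_causal = 5,
                    ld_dup_pairs = 3, ld_fidelity = 0.99, seed = 92)
  g <- simulate_genotypes(cfg)
  phen <- simulate_onset(g, cfg)
  pr <- prune(g, phen)
  expect_gt(nrow(pr$report), 0L)
  expect_true(all(pr$report$p_removed >= pr$report$p_kept))
  expect_true(all(pr$report$r2 > 0.95))
  expect_length(intersect(pr$report$removed_id, pr$kept_ids), 0L)
})

test_that("chained pairs follow the greedy min-p ordering", {
  # construction (fixed seed): r2(A,B) > 0.95, r2(B,C) > 0.95,
  # r2(A,C) <= 0.95 and p_A < p_B < p_C, so processing (A,B) first
  # removes B, and the (B,C) pair can no longer remove C.
  set.seed(16)
  n <- 800
  A <- rbinom(n, 2, 0.4)
  flip <- function(x, k) { i <- sample(n, k); x[i] <- rbinom(k, 2, 0.4); x }
  B <- flip(A, 16); C <- flip(B, 16)
  phen <- simulate_ph_cohort(0.6 * (A - mean(A)), seed = 16,
                             censor = c(45, 95))
  g <- make_geno(cbind(A, B, C), ids = c("snpA", "snpB", "snpC"))
  # verify the construction's preconditions before asserting the outcome
  expect_gt(pairwise_r2(g, "snpA", "snpB"), 0.95)
  expect_gt(pairwise_r2(g, "snpB", "snpC"), 0.95)
  expect_lte(pairwise_r2(g, "snpA", "snpC"), 0.95)
  ps <- vapply(1:3, function(j) univariable_cox_p(g$counts[, j], phen),
               numeric(1))
  expect_true(ps[1] < ps[2] && ps[2] < ps[3])
  pr <- prune(g, phen)
  expect_setequal(pr$kept_ids, c("snpA", "snpC"))
})

test_that("pruning is invariant to SNP input order for distinct p-values", {
  cfg <- sim_config(n_subjects = 1200, n_snps = 15, n_causal = 4,
                    ld_dup_pairs = 2, ld_fidelity = 0.99, seed = 93)
  g <- simulate_genotypes(cfg)
  phen <- simulate_onset(g, cfg)
  pr1 <- prune(g, phen)
  set.seed(935)
  perm <- sample(seq_len(ncol(g$counts)))
  g2 <- genotype_matrix(g$counts[, perm], g$snp_meta[perm, ],
                        g$subject_ids)
  pr2 <- prune(g2, phen)
  expect_setequal(pr1$kept_ids, pr2$kept_ids)
})

test_that("no kept pair exceeds the threshold (brute force)", {
  cfg <- sim_config(n_subjects = 1000, n_snps = 30, n_causal = 5,
                    ld_dup_pairs = 5, ld_fidelity = 0.99, seed = 94)
  g <- simulate_genotypes(cfg)
  phen <- simulate_onset(g, cfg)
  pr <- prune(g, phen)
  kept <- pr$kept_ids
  for (i in seq_along(kept)) {
    for (j in seq_len(i - 1L)) {
      expect_lte(pairwise_r2(pr$kept, kept[i], kept[j]), 0.95)
    }
  }
})
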