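# Correlation-based SNP pruning: among highly correlated SNP pairs
# (genotypic r-squared above a threshold, computed on the training cohort),
# the member with the weaker univariable association with age at diagnosis
# is eliminated; all unpaired SNPs stay candidates.

#' Squared Pearson correlation between two SNP columns
#'
#' Computed over pairwise-complete subjects on the allele-count scale
#' (genotypic, not haplotypic, correlation).
#'
#' @param g a [genotype_matrix()].
#' @param i,j SNP ids or column indices.
#' @return r-squared in \[0, 1\].
#' @export
pairwise_r2 <- function(g, i, j) {
  idx <- function(k) if (is.character(k)) match(k, g$snp_meta$id) else k
  xi <- g$counts[, idx(i)]
  xj <- g$counts[, idx(j)]
  ok <- !is.na(xi) & !is.na(xj)
  if (sum(ok) < 3L) {
    stop_polyhaz("need at least 3 pairwise-complete subjects")
  }
  xi <- xi[ok]; xj <- xj[ok]
  if (sd(xi) == 0 || sd(xj) == 0) {
    stop_polyhaz("undefined correlation: zero variance in a SNP column")
  }
  cor(xi, xj)^2
}

#' Univariable Cox p-value for one SNP
#'
#' Two-sided Wald p-value for the allele-count coefficient in a Cox
#' proportional hazards model of age at diagnosis (cases are events at
#' `event_age`; controls are censored there). Breslow tie handling.
#'
#' @param genotype_column numeric vector of allele counts.
#' @param phen a [cohort_phenotype()].
#' @return the p-value.
#' @export
univariable_cox_p <- function(genotype_column, phen) {
  sv <- endpoint_survival(phen, "any")
  x <- genotype_column
  ok <- !is.na(x)
  if (sd(x[ok]) == 0) stop_polyhaz("constant genotype column")
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(sv$time[ok], sv$event[ok]) ~ x[ok],
                    ties = "breslow"),
    warning = function(w) {
      if (grepl("infinite|converge|singular", conditionMessage(w))) {
        stop_polyhaz("univariable Cox fit did not converge: ",
                     conditionMessage(w))
      }
      invokeRestart("muffleWarning")
    })
  summary(fit)$coefficients[1L, "Pr(>|z|)"]
}

#' Prune highly correlated SNP pairs
#'
#' Every SNP pair with r-squared above `threshold` is flagged; pairs are
#' processed greedily in ascending order of the smaller univariable Cox
#' p-value of their members, and within each surviving pair the member with
#' the larger p-value is removed (ties keep the lexicographically smaller
#' SNP id). A SNP that has already been removed cannot cause further
#' removals. Unpaired SNPs are always kept.
#'
#' @param g a [genotype_matrix()] (training cohort).
#' @param phen the matching [cohort_phenotype()].
#' @param threshold r-squared threshold (default 0.95).
#' @return list with `kept` (the pruned `genotype_matrix`), `kept_ids`, and
#'   `report` (data.frame: `removed_id`, `kept_id`, `r2`, `p_removed`,
#'   `p_kept`).
#' @export
prune <- function(g, phen, threshold = 0.95) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (!(threshold > 0 && threshold < 1)) {
    stop_polyhaz("threshold must lie in (0, 1)")
  }
  ids <- g$snp_meta$id
  cc <- suppressWarnings(cor(g$counts, use = "pairwise.complete.obs"))
  if (anyNA(cc)) {
    stop_polyhaz("undefined pairwise correlation (monomorphic SNP?)")
  }
  r2 <- cc^2
  hits <- which(upper.tri(r2) & r2 > threshold, arr.ind = TRUE)
  if (!nrow(hits)) {
    return(list(kept = g, kept_ids = ids,
                report = data.frame(removed_id = character(0),
                                    kept_id = character(0),
                                    r2 = numeric(0), p_removed = numeric(0),
                                    p_kept = numeric(0))))
  }
  involved <- sort(unique(c(hits[, 1L], hits[, 2L])))
  pvals <- setNames(rep(NA_real_, length(ids)), ids)
  for (k in involved) {
    pvals[k] <- univariable_cox_p(g$counts[, k], phen)
  }
  pairs <- data.frame(a = ids[hits[, 1L]], b = ids[hits[, 2L]],
                      r2 = r2[hits],
                      pa = pvals[hits[, 1L]], pb = pvals[hits[, 2L]],
                      stringsAsFactors = FALSE)
  pairs$pmin <- pmin(pairs$pa, pairs$pb)
  pairs$pmax <- pmax(pairs$pa, pairs$pb)
  ord <- order(pairs$pmin, pairs$pmax, pairs$a, pairs$b)
  pairs <- pairs[ord, ]
  removed <- character(0)
  rep_rows <- list()
  for (k in seq_len(nrow(pairs))) {
    pr <- pairs[k, ]
    if (pr$a %in% removed || pr$b %in% removed) next
    if (pr$pa > pr$pb) {
      drop_id <- pr$a; keep_id <- pr$b
    } else if (pr$pb > pr$pa) {
      drop_id <- pr$b; keep_id <- pr$a
    } else {  # tie: keep the lexicographically smaller id
      keep_id <- min(pr$a, pr$b); drop_id <- max(pr$a, pr$b)
    }
    removed <- c(removed, drop_id)
    rep_rows[[length(rep_rows) + 1L]] <- data.frame(
      removed_id = drop_id, kept_id = keep_id, r2 = pr$r2,
      p_removed = unname(pvals[drop_id]), p_kept = unname(pvals[keep_id]),
      stringsAsFactors = FALSE)
  }
  report <- do.call(rbind, rep_rows)
  kept_ids <- setdiff(ids, removed)
  list(kept = subset_snps(g, kept_ids), kept_ids = kept_ids,
       report = report)
}
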