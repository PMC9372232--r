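#' Construct a genotype matrix
#'
#' A `genotype_matrix` bundles a subjects-by-SNPs allele-count matrix
#' (entries 0, 1, 2 or `NA`) with per-SNP metadata. The counted (effect)
#' allele is the ALT allele under the VCF convention used throughout the
#' package.
#'
#' @param counts integer matrix, subjects in rows, SNPs in columns; entries
#'   must be 0, 1, 2 or `NA`.
#' @param snp_meta data.frame with columns `id`, `chrom`, `pos` (1-based),
#'   `effect_allele`, `other_allele`, `freq` (effect-allele frequency,
#'   strictly inside (0, 1) when present).
#' @param subject_ids character vector of unique subject identifiers.
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(counts, snp_meta, subject_ids = rownames(counts)) {
  counts <- as.matrix(counts)
  if (is.null(subject_ids)) {
    subject_ids <- sprintf("subj%05d", seq_len(nrow(counts)))
  }
  subject_ids <- as.character(subject_ids)
  if (anyDuplicated(subject_ids)) stop_polyhaz("duplicate subject ids")
  need <- c("id", "chrom", "pos", "effect_allele", "other_allele", "freq")
  miss <- setdiff(need, names(snp_meta))
  if (length(miss)) {
    stop_polyhaz("snp_meta is missing columns: ", paste(miss, collapse = ", "))
  }
  snp_meta <- as.data.frame(snp_meta)[, need]
  snp_meta$id <- as.character(snp_meta$id)
  if (anyDuplicated(snp_meta$id)) stop_polyhaz("duplicate SNP ids")
  if (nrow(snp_meta) != ncol(counts)) {
    stop_polyhaz("snp_meta rows must match count columns")
  }
  bad <- counts[!is.na(counts)]
  if (length(bad) && !all(bad %in% 0:2)) {
    stop_polyhaz("allele counts must be 0, 1, 2 or NA")
  }
  fr <- snp_meta$freq
  if (any(!is.na(fr) & (fr <= 0 | fr >= 1))) {
    stop_polyhaz("effect-allele frequencies must lie strictly inside (0, 1)")
  }
  dimnames(counts) <- list(subject_ids, snp_meta$id)
  structure(list(counts = counts, snp_meta = snp_meta,
                 subject_ids = subject_ids),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d subjects x %d SNPs (%d missing calls)\n",
              nrow(x$counts), ncol(x$counts), sum(is.na(x$counts))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$counts)

#' Subset a genotype matrix by SNP id
#'
#' @param g a [genotype_matrix()].
#' @param snp_ids character vector of SNP ids to keep, in the requested order.
#' @return a `genotype_matrix` restricted to `snp_ids`.
#' @export
subset_snps <- function(g, snp_ids) {
  idx <- match(snp_ids, g$snp_meta$id)
  if (anyNA(idx)) {
    stop_polyhaz("unknown SNP ids: ",
                 paste(snp_ids[is.na(idx)], collapse = ", "))
  }
  genotype_matrix(g$counts[, idx, drop = FALSE], g$snp_meta[idx, ],
                  g$subject_ids)
}
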