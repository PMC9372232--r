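# Readers and writers for the pipeline's file formats: VCF 4.2 and wide
# dosage TSV for genotypes, TSV with a fixed header for phenotypes, and a
# three-column TSV for SNP weight tables.  Missing values are coded "NA" in
# every TSV and "./." in VCF genotype fields.  Decimal points are always
# "." regardless of locale.

count_to_gt <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")

#' Write a genotype matrix to VCF 4.2 or a dosage TSV
#'
#' The VCF convention throughout the package is that ALT is the counted
#' (effect) allele; the effect-allele frequency is carried in the `AF` INFO
#' field. No file date is written, so equal inputs give byte-identical
#' output.
#'
#' @param g a [genotype_matrix()].
#' @param path output file path.
#' @param format `"vcf"` or `"dosage-tsv"` (wide: six metadata columns then
#'   one column per subject).
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(g, path, format = c("vcf", "dosage-tsv")) {
  format <- match.arg(format)
  stopifnot(inherits(g, "genotype_matrix"))
  meta <- g$snp_meta
  if (format == "vcf") {
    header <- c(
      "##fileformat=VCFv4.2",
      "##source=polyhaz",
      paste0("##INFO=<ID=AF,Number=A,Type=Float,Description=",
             "\"Effect (ALT) allele frequency\">"),
      "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
      paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
              "INFO", "FORMAT", g$subject_ids), collapse = "\t"))
    gt <- matrix(count_to_gt[as.character(g$counts)],
                 nrow = nrow(g$counts))
    gt[is.na(gt)] <- "./."
    info <- ifelse(is.na(meta$freq), ".",
                   sprintf("AF=%s", format(meta$freq, digits = 17,
                                           scientific = FALSE,
                                           trim = TRUE)))
    body <- paste(meta$chrom, meta$pos, meta$id, meta$other_allele,
                  meta$effect_allele, ".", "PASS", info, "GT",
                  apply(gt, 2L, paste, collapse = "\t"), sep = "\t")
    writeLines(c(header, body), path)
  } else {
    df <- cbind(meta, as.data.frame(t(g$counts)))
    names(df) <- c(names(meta), g$subject_ids)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                na = "NA")
  }
  invisible(path)
}

#' Read a genotype matrix from VCF or a dosage TSV
#'
#' For VCF, the allele count is the number of ALT alleles in the GT field
#' (`./.` becomes a missing entry); multi-allelic records are rejected by
#' id. For dosage TSVs the literal count column is used.
#'
#' @param path input file.
#' @param format `"vcf"` or `"dosage-tsv"`.
#' @return a [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("vcf", "dosage-tsv")) {
  format <- match.arg(format)
  if (format == "vcf") {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
    if (!nrow(fix)) stop_polyhaz("VCF contains no records")
    multi <- grepl(",", fix$ALT, fixed = TRUE)
    if (any(multi)) {
      stop_polyhaz("multi-allelic record(s): ",
                   paste(fix$ID[multi], collapse = ", "))
    }
    gt <- vcfR::extract.gt(v, element = "GT")
    count_allele <- function(x) {
      x[x %in% c("./.", ".|.", ".")] <- NA
      out <- rep(NA_integer_, length(x))
      ok <- !is.na(x)
      parts <- strsplit(x[ok], "[/|]")
      out[ok] <- vapply(parts, function(p) sum(p == "1"), integer(1))
      out
    }
    counts <- t(apply(gt, 1L, count_allele))
    colnames(counts) <- colnames(gt)
    af <- suppressWarnings(
      as.numeric(sub(".*AF=([0-9eE.+-]+).*", "\\1", fix$INFO)))
    meta <- data.frame(id = fix$ID, chrom = fix$CHROM,
                       pos = as.integer(fix$POS),
                       effect_allele = fix$ALT, other_allele = fix$REF,
                       freq = af, stringsAsFactors = FALSE)
    genotype_matrix(t(counts), meta, colnames(gt))
  } else {
    df <- read.table(path, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE, check.names = FALSE)
    metacols <- c("id", "chrom", "pos", "effect_allele", "other_allele",
                  "freq")
    miss <- setdiff(metacols, names(df))
    if (length(miss)) {
      stop_polyhaz("dosage TSV missing columns: ",
                   paste(miss, collapse = ", "))
    }
    subj <- setdiff(names(df), metacols)
    counts <- t(as.matrix(df[, subj, drop = FALSE]))
    meta <- df[, metacols]
    meta$chrom <- as.character(meta$chrom)
    genotype_matrix(counts, meta, subj)
  }
}

phen_columns <- c("subject_id", "status", "event_age", "significant",
                  "fatal", "death_age", "family_history", "psa_positive",
                  "biopsy_significant", "pc1", "pc2", "pc3", "pc4")

#' Write / read a phenotype table as TSV
#'
#' Fixed header, missing values coded `"NA"`. An unknown family history is
#' written as `NA` and read back as the explicit `"unknown"` state so that
#' family-history analyses can be limited to subjects with known family
#' history. Invariant violations on read are rejected with the offending
#' row number.
#'
#' @param phen a [cohort_phenotype()].
#' @param path file path.
#' @return `write_phenotypes`: `path` invisibly; `read_phenotypes`: a
#'   [cohort_phenotype()].
#' @export
write_phenotypes <- function(phen, path) {
  stopifnot(inherits(phen, "cohort_phenotype"))
  out <- as.data.frame(phen)[, phen_columns]
  out$family_history[out$family_history == "unknown"] <- NA
  for (cl in c("significant", "fatal", "psa_positive", "biopsy_significant")) {
    out[[cl]] <- ifelse(is.na(out[[cl]]), NA_integer_,
                        as.integer(out[[cl]]))
  }
  prev <- attr(phen, "prevalence")
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(prev)) {
    writeLines(sprintf("# prevalence=%s",
                       format(prev, digits = 17, scientific = FALSE)), con)
  }
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  first <- readLines(path, n = 1L)
  prev <- NULL
  skip <- 0L
  if (startsWith(first, "# prevalence=")) {
    prev <- as.numeric(sub("# prevalence=", "", first, fixed = TRUE))
    skip <- 1L
  }
  df <- read.table(path, header = TRUE, sep = "\t", skip = skip,
                   stringsAsFactors = FALSE, na.strings = "NA")
  miss <- setdiff(phen_columns, names(df))
  if (length(miss)) {
    stop_polyhaz("phenotype TSV missing columns: ",
                 paste(miss, collapse = ", "))
  }
  df$family_history[is.na(df$family_history)] <- "unknown"
  for (cl in c("significant", "fatal", "psa_positive", "biopsy_significant")) {
    df[[cl]] <- as.logical(df[[cl]])
  }
  df$fatal[is.na(df$fatal)] <- FALSE
  df$event_age <- as.numeric(df$event_age)
  df$death_age <- as.numeric(df$death_age)
  cohort_phenotype(df, prevalence = prev)
}

#' Write / read a SNP weight table
#'
#' Three tab-separated columns (`snp_id`, `effect_allele`, `beta`) with full
#' float precision, so a write/read round trip preserves each log-hazard
#' coefficient to within one ulp. Duplicate SNP ids and non-finite betas
#' are rejected.
#'
#' @param w data.frame with columns `snp_id`, `effect_allele`, `beta`.
#' @param path file path.
#' @return `write_weights`: `path` invisibly; `read_weights`: the validated
#'   weight table (class `snp_weight_table`).
#' @export
write_weights <- function(w, path) {
  w <- validate_weights(w)
  out <- data.frame(snp_id = w$snp_id, effect_allele = w$effect_allele,
                    beta = sprintf("%.17g", w$beta))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_weights
#' @export
read_weights <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE,
                   colClasses = c("character", "character", "numeric"))
  validate_weights(df)
}

validate_weights <- function(w) {
  need <- c("snp_id", "effect_allele", "beta")
  miss <- setdiff(need, names(w))
  if (length(miss)) {
    stop_polyhaz("weight table missing columns: ",
                 paste(miss, collapse = ", "))
  }
  w <- as.data.frame(w)[, need]
  if (anyDuplicated(w$snp_id)) stop_polyhaz("duplicate snp_id in weight table")
  if (nrow(w) && any(!is.finite(w$beta))) {
    stop_polyhaz("non-finite beta in weight table")
  }
  class(w) <- c("snp_weight_table", "data.frame")
  w
}
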