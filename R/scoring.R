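# Polygenic hazard score computation and the young-control percentile
# reference used for every band definition in the package.

#' Compute the polygenic hazard score
#'
#' `PHS_s = sum_i beta_i x_si` over the weight table's SNPs, where `x_si`
#' is the subject's effect-allele count. Every weight-table SNP must be
#' resolvable in the genotype data by id; when the weight table's effect
#' allele equals the genotype file's *other* allele the count is flipped to
#' `2 - x` (standard polygenic-score practice, preventing silent sign
#' errors), and any other allele mismatch is an error. Missing counts are
#' imputed as twice the effect-allele frequency.
#'
#' @param g a [genotype_matrix()].
#' @param w a `snp_weight_table` (see [read_weights()]).
#' @return named numeric vector of per-subject scores.
#' @export
compute_phs <- function(g, w) {
  w <- validate_weights(w)
  idx <- match(w$snp_id, g$snp_meta$id)
  if (anyNA(idx)) {
    stop_polyhaz("weight-table SNP(s) not present in genotypes: ",
                 paste(w$snp_id[is.na(idx)], collapse = ", "))
  }
  scores <- rep(0, nrow(g$counts))
  for (k in seq_len(nrow(w))) {
    j <- idx[k]
    x <- g$counts[, j]
    ga <- g$snp_meta$effect_allele[j]
    oa <- g$snp_meta$other_allele[j]
    wa <- w$effect_allele[k]
    freq <- g$snp_meta$freq[j]
    if (is.na(freq)) freq <- mean(x, na.rm = TRUE) / 2
    if (wa == ga) {
      # orientation matches
    } else if (wa == oa) {
      x <- 2 - x
      freq <- 1 - freq
    } else {
      stop_polyhaz("allele mismatch beyond flip for SNP ", w$snp_id[k],
                   ": weight allele ", wa, " vs genotype ", ga, "/", oa)
    }
    x[is.na(x)] <- 2 * freq
    scores <- scores + w$beta[k] * x
  }
  setNames(scores, g$subject_ids)
}

#' Build the percentile reference from young training controls
#'
#' Percentiles of genetic risk are determined within the training-set
#' controls younger than 70 years. Thresholds are inverse-empirical-CDF
#' (type 1) quantiles — the smallest observed score with at least the
#' target fraction of reference scores at or below it — so band counts are
#' exact for distinct scores. The reference also stores the mean PHS inside
#' each band (bottom 20%, the configurable middle band, top 20%, top 5%),
#' which turn a continuous-score Cox coefficient into percentile hazard
#' ratios via [band_hr()].
#'
#' @param scores numeric vector of reference scores (training controls with
#'   age below the cutoff).
#' @param mid_band lower/upper percentiles of the "middle 40%" band
#'   (default `c(30, 70)`).
#' @param source description of the reference population.
#' @return an object of class `phs_reference` with `thresholds` (named:
#'   p20, p_mid_lo, p_mid_hi, p80, p95) and `interval_means` (named: m20,
#'   m50, m80, m95).
#' @export
build_percentile_reference <- function(scores,
                                       mid_band = c(30, 70),
                                       source = "training controls, age < 70") {
  scores <- scores[!is.na(scores)]
  if (!length(scores)) stop_polyhaz("empty reference population")
  if (length(scores) < 100L) {
    warning("percentile reference built from fewer than 100 subjects",
            call. = FALSE)
  }
  if (!(length(mid_band) == 2L && mid_band[1] < mid_band[2])) {
    stop_polyhaz("mid_band must be increasing percentiles")
  }
  if (sd(scores) == 0) {
    warning("degenerate reference: all scores equal", call. = FALSE)
  }
  th <- c(p20 = quantile_type1(scores, 0.20),
          p_mid_lo = quantile_type1(scores, mid_band[1] / 100),
          p_mid_hi = quantile_type1(scores, mid_band[2] / 100),
          p80 = quantile_type1(scores, 0.80),
          p95 = quantile_type1(scores, 0.95))
  means <- c(
    m20 = mean(scores[scores < th["p20"]]),
    m50 = mean(scores[scores >= th["p_mid_lo"] & scores < th["p_mid_hi"]]),
    m80 = mean(scores[scores >= th["p80"]]),
    m95 = mean(scores[scores >= th["p95"]]))
  if (sd(scores) == 0) {
    means <- c(m20 = th[["p20"]], m50 = th[["p20"]], m80 = th[["p20"]],
               m95 = th[["p20"]])
  }
  structure(list(thresholds = th, interval_means = means,
                 mid_band = mid_band, n_reference = length(scores),
                 source = source), class = "phs_reference")
}

#' @export
print.phs_reference <- function(x, ...) {
  cat(sprintf("phs_reference (%s; n = %d)\n", x$source, x$n_reference))
  cat("  thresholds: ",
      paste(sprintf("%s=%.4g", names(x$thresholds), x$thresholds),
            collapse = ", "), "\n")
  cat("  band means: ",
      paste(sprintf("%s=%.4g", names(x$interval_means), x$interval_means),
            collapse = ", "), "\n")
  invisible(x)
}

#' Percentile band membership
#'
#' Bands are half-open `[low, high)` except the top band, which is closed
#' above; a score at or above the 95th-percentile threshold is
#' simultaneously in the top 20% and the top 5%. `phs_band_flags()` returns
#' the overlapping memberships; `assign_band()` returns a single label
#' ("top5" wins over "top20").
#'
#' @param score numeric vector of scores.
#' @param ref a `phs_reference`.
#' @return `phs_band_flags`: data.frame of logicals `bottom20`, `mid`,
#'   `top20`, `top5`; `assign_band`: character vector with levels
#'   `bottom20`, `mid40_60`, `top20`, `top5`, `other`.
#' @export
phs_band_flags <- function(score, ref) {
  th <- ref$thresholds
  data.frame(bottom20 = score < th[["p20"]],
             mid = score >= th[["p_mid_lo"]] & score < th[["p_mid_hi"]],
             top20 = score >= th[["p80"]],
             top5 = score >= th[["p95"]])
}

#' @rdname phs_band_flags
#' @export
assign_band <- function(score, ref) {
  fl <- phs_band_flags(score, ref)
  out <- rep("other", length(score))
  out[fl$bottom20] <- "bottom20"
  out[fl$mid] <- "mid40_60"
  out[fl$top20] <- "top20"
  out[fl$top5] <- "top5"
  out
}
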