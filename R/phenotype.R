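#' Construct and validate a cohort phenotype table
#'
#' Per-subject survival endpoint data used throughout the pipeline. Cases
#' carry their age at diagnosis in `event_age`; controls are censored at the
#' age of last follow-up (also stored in `event_age`). Clinical significance
#' is only defined for cases; fatal outcomes (with a prostate-cancer death
#' age) are a subset of significant cases. `family_history` distinguishes
#' "yes"/"no" from "unknown" so family-history models can be restricted to
#' subjects with known family history. `pc1`..`pc4` hold ancestry principal
#' components.
#'
#' @param df data.frame with columns `subject_id`, `status` ("case" or
#'   "control"), `event_age`, `significant`, `fatal`, `death_age`,
#'   `family_history` ("yes", "no", "unknown"), `psa_positive`,
#'   `biopsy_significant`, `pc1`, `pc2`, `pc3`, `pc4`.
#' @param prevalence optional population case probability attached as the
#'   `prevalence` attribute (used to compute sample weights downstream).
#' @return a `cohort_phenotype` data.frame.
#' @export
cohort_phenotype <- function(df, prevalence = attr(df, "prevalence")) {
  need <- c("subject_id", "status", "event_age", "significant", "fatal",
            "death_age", "family_history", "psa_positive",
            "biopsy_significant", "pc1", "pc2", "pc3", "pc4")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop_polyhaz("phenotype table missing columns: ",
                 paste(miss, collapse = ", "))
  }
  df <- as.data.frame(df)[, need]
  df$subject_id <- as.character(df$subject_id)
  if (anyDuplicated(df$subject_id)) stop_polyhaz("duplicate subject ids")
  if (!all(df$status %in% c("case", "control"))) {
    stop_polyhaz("status must be 'case' or 'control'")
  }
  if (!all(df$family_history %in% c("yes", "no", "unknown"))) {
    stop_polyhaz("family_history must be 'yes', 'no' or 'unknown'")
  }
  for (cl in c("significant", "fatal", "psa_positive", "biopsy_significant")) {
    df[[cl]] <- as.logical(df[[cl]])
  }
  validate_phenotype(df)
  rownames(df) <- NULL
  attr(df, "prevalence") <- prevalence
  class(df) <- c("cohort_phenotype", "data.frame")
  df
}

validate_phenotype <- function(df) {
  fail <- function(rows, msg) {
    stop_polyhaz(sprintf("phenotype validation failed (%s) at row(s) %s",
                         msg, paste(head(rows, 5L), collapse = ", ")))
  }
  is_case <- df$status == "case"
  bad <- which(!is.finite(df$event_age) | df$event_age <= 0)
  if (length(bad)) fail(bad, "event_age must be positive")
  bad <- which(!is_case & !is.na(df$significant))
  if (length(bad)) fail(bad, "significant defined for a control")
  bad <- which(df$fatal %in% TRUE & !is_case)
  if (length(bad)) fail(bad, "fatal flagged for a control")
  bad <- which(df$fatal %in% TRUE &
                 (is.na(df$death_age) | df$death_age < df$event_age))
  if (length(bad)) fail(bad, "fatal case needs death_age >= event_age")
  bad <- which(!is.na(df$death_age) & !(df$fatal %in% TRUE))
  if (length(bad)) fail(bad, "death_age present for a non-fatal subject")
  invisible(df)
}

#' @export
print.cohort_phenotype <- function(x, ...) {
  n_case <- sum(x$status == "case")
  cat(sprintf(paste0("cohort_phenotype: %d subjects (%d cases / %d controls",
                     "), %d significant, %d fatal\n"),
              nrow(x), n_case, nrow(x) - n_case,
              sum(x$significant %in% TRUE), sum(x$fatal %in% TRUE)))
  if (!is.null(attr(x, "prevalence"))) {
    cat(sprintf("  linked population prevalence: %.4f\n",
                attr(x, "prevalence")))
  }
  invisible(x)
}

# Endpoint coding shared by every Cox fit in the package:
#   any         - all cases are events at diagnosis age
#   significant - significant cases are events at diagnosis age; everything
#                 else (controls and, by default, non-significant cases) is
#                 censored at its event_age
#   fatal       - prostate cancer deaths are events at death age; everyone
#                 else is censored at last contact
endpoint_survival <- function(phen, endpoint = c("any", "significant",
                                                 "fatal"),
                              nonsignificant = c("censor", "drop")) {
  endpoint <- match.arg(endpoint)
  nonsignificant <- match.arg(nonsignificant)
  keep <- rep(TRUE, nrow(phen))
  is_case <- phen$status == "case"
  if (endpoint == "any") {
    time <- phen$event_age
    event <- as.integer(is_case)
  } else if (endpoint == "significant") {
    event <- as.integer(is_case & phen$significant %in% TRUE)
    time <- phen$event_age
    if (nonsignificant == "drop") keep <- !(is_case & !(phen$significant %in% TRUE))
  } else {
    event <- as.integer(phen$fatal %in% TRUE)
    time <- ifelse(phen$fatal %in% TRUE, phen$death_age, phen$event_age)
  }
  if (sum(event[keep]) == 0L) {
    stop_polyhaz(sprintf("no events for endpoint '%s'", endpoint))
  }
  list(time = time[keep], event = event[keep], keep = keep)
}
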